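#' Independent decision-table oracle for evidence aggregation
#'
#' A deliberately separate restatement of the aggregation rules as a flat
#' case analysis, used to cross-validate [aggregate_evidence()]. It shares
#' no code with the engine: levels are scored through a literal lookup
#' table, the branch structure is written out case by case, and the CIO
#' label is assembled by string concatenation rather than through the axes
#' model. Unlike the engine it takes the group's typality as an input
#' instead of computing it from the ECO.
#'
#' @param lines An evidence-line tibble (see [evidence_lines()]).
#' @param typality `"same"`, `"multiple"`, or `"unspecified"` (single line).
#' @param policy An [aggregation_policy()].
#' @return A list with `label`, `polarity` (`"positive"`, `"negative"` or
#'   `"undetermined"`), `level` (`NA` when the statement carries none) and
#'   `contributing`.
#' @export
decision_table_oracle <- function(lines, typality = "same",
                                  policy = aggregation_policy()) {
  score_of <- c(low = 1, medium = 2, high = 3)
  name_of <- c("low", "medium", "high")

  live_pol <- character(0)
  live_score <- numeric(0)
  for (i in seq_len(nrow(lines))) {
    if (isTRUE(lines$rejected[i])) next
    live_pol <- c(live_pol, lines$polarity[i])
    live_score <- c(live_score, score_of[[lines$level[i]]])
  }
  n <- length(live_pol)
  if (n == 0) stop("no assessable evidence: all lines are rejected", call. = FALSE)

  if (n == 1) {
    return(list(label = paste(name_of[live_score], "confidence from single evidence"),
                polarity = live_pol, level = name_of[live_score],
                contributing = 1L))
  }

  ty_word <- switch(typality, same = "same type", multiple = "multiple types",
                    stop("typality must be 'same' or 'multiple' for groups",
                         call. = FALSE))
  pos <- live_score[live_pol == "positive"]
  neg <- live_score[live_pol == "negative"]

  promoted <- function(scores) {
    total <- max(scores)
    if (typality == "multiple" && policy$multitype_promotion) total <- total + 1
    if (length(scores) >= policy$promote_count) total <- total + 1
    if (total > 3) total <- 3
    total
  }

  if (length(pos) > 0 && length(neg) > 0) {
    if (max(pos) == max(neg)) {
      return(list(
        label = paste0("confidence statement from strongly conflicting evidence lines of ",
                       ty_word),
        polarity = "undetermined", level = NA_character_, contributing = n
      ))
    }
    winner_pol <- if (max(pos) > max(neg)) "positive" else "negative"
    winner <- if (winner_pol == "positive") pos else neg
    total <- promoted(winner)
    if (policy$weak_conflict_demotion && total > 1) total <- total - 1
    return(list(
      label = paste0("confidence statement from weakly conflicting evidence lines of ",
                     ty_word, ", overall confidence ", name_of[total]),
      polarity = winner_pol, level = name_of[total], contributing = n
    ))
  }

  total <- promoted(live_score)
  list(
    label = paste0("confidence statement from congruent evidence lines of ",
                   ty_word, ", overall confidence ", name_of[total]),
    polarity = live_pol[1], level = name_of[total], contributing = n
  )
}
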