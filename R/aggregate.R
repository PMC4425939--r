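#' Aggregation policy
#'
#' The CIO literature deliberately leaves the quantitative aggregation rules
#' to the teams implementing it; this object holds the configurable knobs
#' with defaults chosen to reproduce the published worked examples.
#'
#' * `promote_count`: a side with at least this many congruent lines gains
#'   one confidence level (repeated confirmation by many lower-confidence
#'   lines can still yield high overall confidence). Default 3.
#' * `multitype_promotion`: congruent support from multiple evidence types
#'   gains one level (independent methods corroborate each other).
#'   Default `TRUE`.
#' * `weak_conflict_demotion`: demote the winning side one level under a
#'   weak conflict. Off by default, because the ontology itself provides
#'   "weakly conflicting ... overall confidence high" as a reachable
#'   statement.
#' * `legacy_default_level`: the single-evidence level imposed on legacy
#'   annotations that carry no confidence term (see
#'   [impute_legacy_confidence()]). Default `"medium"`.
#'
#' @param promote_count Integer >= 2.
#' @param multitype_promotion,weak_conflict_demotion Logical flags.
#' @param legacy_default_level One of [cio_levels()].
#' @return An object of class `aggregation_policy`.
#' @export
aggregation_policy <- function(promote_count = 3L,
                               multitype_promotion = TRUE,
                               weak_conflict_demotion = FALSE,
                               legacy_default_level = "medium") {
  promote_count <- as.integer(promote_count)
  if (is.na(promote_count) || promote_count < 2L) {
    stop("promote_count must be an integer >= 2", call. = FALSE)
  }
  .level_value(legacy_default_level)
  structure(
    list(promote_count = promote_count,
         multitype_promotion = isTRUE(multitype_promotion),
         weak_conflict_demotion = isTRUE(weak_conflict_demotion),
         legacy_default_level = legacy_default_level),
    class = "aggregation_policy"
  )
}

#' Construct evidence lines
#'
#' Builds the tibble of evidence lines consumed by [aggregate_evidence()].
#' Each line carries a polarity (`"negative"` for NOT-qualified
#' annotations), an ECO evidence term id, a single-evidence confidence
#' level, and a `rejected` flag; rejected lines carry no level.
#'
#' @param polarity Character vector, `"positive"` or `"negative"`.
#' @param evidence Character vector of ECO term ids.
#' @param level Character vector of [cio_levels()] values; `NA` exactly when
#'   `rejected` is `TRUE`.
#' @param rejected Logical vector.
#' @return A tibble with one row per evidence line.
#' @export
evidence_lines <- function(polarity, evidence, level, rejected = FALSE) {
  out <- tibble::tibble(
    polarity = polarity, evidence = evidence,
    level = as.character(level), rejected = rejected
  )
  if (!all(out$polarity %in% c("positive", "negative"))) {
    stop("polarity must be 'positive' or 'negative'", call. = FALSE)
  }
  if (any(out$rejected != is.na(out$level))) {
    stop("a line is rejected exactly when its level is absent", call. = FALSE)
  }
  .level_value(out$level[!out$rejected])
  out
}

#' Drop rejected evidence lines
#'
#' Evidence annotated `rejected` records retracted or invalidated results;
#' it is kept for traceability but never contributes to a summary
#' statement.
#'
#' @param lines An evidence-line tibble ([evidence_lines()]).
#' @return The non-rejected lines, input order preserved.
#' @export
filter_rejected <- function(lines) lines[!lines$rejected, , drop = FALSE]

#' Concordance of an evidence group
#'
#' A group of non-rejected evidence lines is `"conflicting"` when it mixes
#' positive and NOT-qualified annotations of the same assertion, and
#' `"congruent"` otherwise. What counts as a conflict is left to the
#' implementing resource; mixed polarity is the default predicate, and a
#' custom predicate can be supplied.
#'
#' @inheritParams filter_rejected
#' @param predicate Function taking the line tibble and returning `TRUE`
#'   when the group conflicts; the default tests for mixed polarity.
#' @return `"congruent"` or `"conflicting"`.
#' @export
detect_concordance <- function(lines, predicate = NULL) {
  if (nrow(lines) < 2L) {
    stop("concordance is only defined for groups of at least two lines",
         call. = FALSE)
  }
  conflicting <- if (is.null(predicate)) {
    length(unique(lines$polarity)) > 1L
  } else {
    isTRUE(predicate(lines))
  }
  if (conflicting) "conflicting" else "congruent"
}

#' Classify a conflict as weak or strong
#'
#' A contradiction is *strong* when the best evidence on each side reaches
#' the same confidence level (the evidence lines yield different
#' conclusions of similar confidence, so no consensus can be drawn), and
#' *weak* when one side is clearly better supported — e.g. a single
#' low-confidence line contradicting several high-confidence lines.
#'
#' @inheritParams filter_rejected
#' @return A list with `strength` (`"weak"` or `"strong"`) and, for weak
#'   conflicts, `winner` (`"positive"` or `"negative"`, the side with the
#'   higher best level; `NA` for strong).
#' @export
classify_conflict_strength <- function(lines) {
  if (detect_concordance(lines) != "conflicting") {
    stop("conflict strength is only defined for conflicting groups",
         call. = FALSE)
  }
  pos_max <- max(.level_value(lines$level[lines$polarity == "positive"]))
  neg_max <- max(.level_value(lines$level[lines$polarity == "negative"]))
  if (pos_max == neg_max) {
    list(strength = "strong", winner = NA_character_)
  } else {
    list(strength = "weak",
         winner = if (pos_max > neg_max) "positive" else "negative")
  }
}

#' Overall confidence level of a congruent side
#'
#' The base level is the best single-evidence level on the side; it is
#' promoted one step when the group draws on multiple evidence types
#' (independent corroboration) and one step when the side has at least
#' `promote_count` lines (repeated confirmation), saturating at `high`.
#'
#' @param side_lines Evidence-line tibble, non-empty, all levels present.
#' @param group_typality `"same"` or `"multiple"`.
#' @param policy An [aggregation_policy()].
#' @return One of [cio_levels()].
#' @export
overall_level <- function(side_lines, group_typality,
                          policy = aggregation_policy()) {
  if (nrow(side_lines) == 0L) {
    stop("overall level requires at least one evidence line", call. = FALSE)
  }
  vals <- .level_value(side_lines$level)
  if (anyNA(vals)) stop("all lines must carry a level", call. = FALSE)
  bump <- (group_typality == "multiple" && policy$multitype_promotion) +
    (nrow(side_lines) >= policy$promote_count)
  cio_levels()[min(3L, max(vals) + bump)]
}

#' Aggregate evidence lines into a summary confidence statement
#'
#' The core rule engine. Rejected lines are discarded first. A single
#' surviving line passes through as its own single-evidence statement. For
#' two or more lines, the ECO structure decides whether the group is of the
#' same or of multiple evidence types; mixed polarity makes the group
#' conflicting, and a conflict is strong when both sides' best levels tie.
#' Congruent groups (and the winning side of a weak conflict) receive an
#' overall level via [overall_level()]; strongly conflicting groups receive
#' no level and an undetermined polarity. The resulting axes are mapped to
#' the canonical CIO term.
#'
#' @inheritParams filter_rejected
#' @param eco ECO ontology used for typality (default [toy_eco()]).
#' @param type_policy An [evidence_type_policy()].
#' @param policy An [aggregation_policy()].
#' @param conflict_predicate Optional custom conflict predicate, passed to
#'   [detect_concordance()].
#' @return An object of class `cio_summary`: a list with `statement` (a
#'   `cio_statement`), `polarity` (`"positive"`, `"negative"` or
#'   `"undetermined"`), `contributing` (number of non-rejected lines) and
#'   `typality`.
#' @examples
#' eco <- toy_eco()
#' erg9 <- evidence_lines(c("positive", "positive"),
#'                        c("ECO:0000200", "ECO:0000015"),
#'                        c("high", "high"))
#' aggregate_evidence(erg9, eco)$statement$id  # CIO:0000012
#' @export
aggregate_evidence <- function(lines,
                               eco = toy_eco(),
                               type_policy = evidence_type_policy(),
                               policy = aggregation_policy(),
                               conflict_predicate = NULL) {
  if (nrow(lines) == 0L) stop("no evidence lines supplied", call. = FALSE)
  keep <- filter_rejected(lines)
  if (nrow(keep) == 0L) {
    stop("no assessable evidence: all lines are rejected", call. = FALSE)
  }
  if (anyNA(keep$level)) {
    stop("non-rejected lines must carry a level; impute legacy confidence first",
         call. = FALSE)
  }

  if (nrow(keep) == 1L) {
    axes <- cio_axes("single", level = keep$level[[1]])
    return(structure(
      list(statement = term_for_axes(axes), polarity = keep$polarity[[1]],
           contributing = 1L, typality = "unspecified"),
      class = "cio_summary"
    ))
  }

  typality <- group_typality(eco, keep$evidence, type_policy)
  concordance <- detect_concordance(keep, conflict_predicate)

  if (concordance == "congruent") {
    level <- overall_level(keep, typality, policy)
    axes <- cio_axes("multiple", typality, "congruent", level)
    polarity <- keep$polarity[[1]]
  } else {
    strength <- classify_conflict_strength(keep)
    if (strength$strength == "strong") {
      axes <- cio_axes("multiple", typality, "strongly_conflicting")
      polarity <- "undetermined"
    } else {
      side <- keep[keep$polarity == strength$winner, , drop = FALSE]
      level <- overall_level(side, typality, policy)
      if (policy$weak_conflict_demotion) level <- .level_step(level, -1L)
      axes <- cio_axes("multiple", typality, "weakly_conflicting", level)
      polarity <- strength$winner
    }
  }

  structure(
    list(statement = term_for_axes(axes), polarity = polarity,
         contributing = nrow(keep), typality = typality),
    class = "cio_summary"
  )
}

#' @export
print.cio_summary <- function(x, ...) {
  cat("<cio_summary> ", x$statement$label,
      " | polarity: ", x$polarity,
      " | contributing lines: ", x$contributing, "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a summary confidence statement
#'
#' @param x A `cio_summary` from [aggregate_evidence()].
#' @param ... Unused.
#' @return A one-row tibble with the statement label, official id, the five
#'   statement axes, the summary polarity and the contributing line count.
#' @export
tidy.cio_summary <- function(x, ...) {
  ax <- x$statement$axes
  tibble::tibble(
    label = x$statement$label,
    id = x$statement$id,
    arity = ax$arity,
    typality = ax$typality,
    concordance = ax$concordance,
    level = ax$level,
    rejected = ax$rejected,
    polarity = x$polarity,
    contributing = x$contributing
  )
}

#' @rdname tidy.cio_summary
#' @export
glance.cio_summary <- function(x, ...) {
  tibble::tibble(
    label = x$statement$label,
    polarity = x$polarity,
    contributing = x$contributing
  )
}
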