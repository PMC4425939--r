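#' Confidence levels
#'
#' The CIO rates confidence on a three-step ordinal scale,
#' `low < medium < high`.
#'
#' @return Character vector of the three level names, in increasing order.
#' @export
cio_levels <- function() c("low", "medium", "high")

.level_value <- function(level) {
  v <- match(level, cio_levels())
  if (anyNA(v) && !all(is.na(level))) {
    bad <- level[is.na(v) & !is.na(level)]
    stop("unknown confidence level: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  v
}

# step a level up/down the scale, saturating at the ends
.level_step <- function(level, by) {
  cio_levels()[max(1L, min(3L, .level_value(level) + by))]
}

#' Construct the semantic axes of a CIO statement
#'
#' A CIO confidence statement is determined by five coordinates: the
#' evidence **arity** (single evidence vs multiple evidence lines), the
#' evidence-type **typality** for multi-line statements (same type vs
#' multiple types), the **concordance** of the evidence group (congruent,
#' weakly conflicting or strongly conflicting), the overall confidence
#' **level**, and the **rejected** flag that tags retracted evidence.
#'
#' Invariants enforced here: a rejected statement carries no other
#' coordinates; a single-evidence statement has unspecified typality and
#' concordance and (unless rejected) a level; a multi-line statement has a
#' definite typality and concordance; strongly conflicting statements carry
#' no overall level (the evidence does not support a consensual conclusion),
#' while congruent and weakly conflicting ones always do.
#'
#' @param arity `"single"` or `"multiple"`.
#' @param typality `"same"`, `"multiple"` or `"unspecified"`.
#' @param concordance `"congruent"`, `"weakly_conflicting"`,
#'   `"strongly_conflicting"` or `"unspecified"`.
#' @param level One of [cio_levels()], or `NA`/`NULL` for absent.
#' @param rejected Logical flag for retracted evidence.
#' @return An object of class `cio_axes`.
#' @examples
#' cio_axes("single", level = "high")
#' cio_axes("multiple", "multiple", "congruent", "high")
#' @export
cio_axes <- function(arity,
                     typality = "unspecified",
                     concordance = "unspecified",
                     level = NULL,
                     rejected = FALSE) {
  level <- if (is.null(level) || is.na(level[1])) NA_character_ else level
  arity <- match.arg(arity, c("single", "multiple"))
  typality <- match.arg(typality, c("unspecified", "same", "multiple"))
  concordance <- match.arg(
    concordance,
    c("unspecified", "congruent", "weakly_conflicting", "strongly_conflicting")
  )
  if (!is.na(level)) .level_value(level)

  if (rejected) {
    if (arity != "single" || typality != "unspecified" ||
        concordance != "unspecified" || !is.na(level)) {
      stop("a rejected statement carries no other axes", call. = FALSE)
    }
  } else if (arity == "single") {
    if (typality != "unspecified" || concordance != "unspecified") {
      stop("single-evidence statements have unspecified typality and concordance",
           call. = FALSE)
    }
    if (is.na(level)) {
      stop("a non-rejected single-evidence statement requires a level",
           call. = FALSE)
    }
  } else {
    if (!typality %in% c("same", "multiple")) {
      stop("multi-line statements require typality 'same' or 'multiple'",
           call. = FALSE)
    }
    if (concordance == "unspecified") {
      stop("multi-line statements require a concordance", call. = FALSE)
    }
    if (concordance == "strongly_conflicting" && !is.na(level)) {
      stop("strongly conflicting statements carry no overall level",
           call. = FALSE)
    }
    if (concordance != "strongly_conflicting" && is.na(level)) {
      stop("congruent and weakly conflicting statements require an overall level",
           call. = FALSE)
    }
  }

  structure(
    list(arity = arity, typality = typality, concordance = concordance,
         level = level, rejected = rejected),
    class = "cio_axes"
  )
}

#' @export
print.cio_axes <- function(x, ...) {
  cat("<cio_axes> ", term_for_axes(x)$label, "\n", sep = "")
  invisible(x)
}

# label fragments used by the canonical naming pattern
.concordance_phrase <- c(
  congruent = "congruent",
  weakly_conflicting = "weakly conflicting",
  strongly_conflicting = "strongly conflicting"
)
.typality_phrase <- c(same = "same type", multiple = "multiple types")

.cio_cache <- new.env(parent = emptyenv())

.cio_leaf_table <- function() {
  if (!is.null(.cio_cache$leaves)) return(.cio_cache$leaves)
  single <- tibble::tibble(
    label = c(paste(cio_levels(), "confidence from single evidence"), "rejected"),
    id = c(NA_character_, NA_character_, "CIO:0000003", NA_character_),
    arity = "single",
    typality = "unspecified",
    concordance = "unspecified",
    level = c(cio_levels(), NA_character_),
    rejected = c(FALSE, FALSE, FALSE, TRUE)
  )
  multi <- tidyr::expand_grid(
    typality = c("same", "multiple"),
    concordance = c("congruent", "weakly_conflicting", "strongly_conflicting"),
    level = cio_levels()
  )
  multi <- dplyr::distinct(dplyr::mutate(
    multi,
    level = dplyr::if_else(.data$concordance == "strongly_conflicting",
                           NA_character_, .data$level)
  ))
  multi <- dplyr::mutate(
    multi,
    label = paste0(
      "confidence statement from ",
      .concordance_phrase[.data$concordance],
      " evidence lines of ",
      .typality_phrase[.data$typality],
      dplyr::if_else(is.na(.data$level), "",
                     paste0(", overall confidence ", .data$level))
    ),
    id = dplyr::if_else(
      .data$typality == "multiple" & .data$concordance == "congruent" &
        !is.na(.data$level) & .data$level == "high",
      "CIO:0000012", NA_character_
    ),
    arity = "multiple",
    rejected = FALSE
  )
  .cio_cache$leaves <- dplyr::bind_rows(
    single,
    multi[, c("label", "id", "arity", "typality", "concordance", "level",
              "rejected")]
  )
  .cio_cache$leaves
}

#' Assignable CIO statements
#'
#' Enumerates the leaf statements of the built-in CIO: the four
#' single-evidence statements (three levels plus `rejected`) and the
#' fourteen multiple-evidence-lines statements (two typalities times three
#' congruent levels, three weakly-conflicting levels, and one
#' strongly-conflicting leaf).
#'
#' @return A tibble with columns `label`, `id` (official CIO id where the
#'   literature fixes one, otherwise `NA`), `arity`, `typality`,
#'   `concordance`, `level`, `rejected`.
#' @export
cio_leaves <- function() .cio_leaf_table()

#' Map statement axes to the canonical CIO term
#'
#' @param axes A [cio_axes()] object.
#' @return An object of class `cio_statement`: a list with `label` (the
#'   canonical CIO term label), `id` (official CIO id or `NA`) and `axes`.
#' @examples
#' term_for_axes(cio_axes("single", level = "high"))$id     # CIO:0000003
#' term_for_axes(cio_axes("multiple", "multiple", "congruent", "high"))$id
#' @export
term_for_axes <- function(axes) {
  stopifnot(inherits(axes, "cio_axes"))
  tab <- .cio_leaf_table()
  hit <- which(
    tab$arity == axes$arity &
      tab$typality == axes$typality &
      tab$concordance == axes$concordance &
      (is.na(tab$level) == is.na(axes$level)) &
      (is.na(tab$level) | tab$level == axes$level) &
      tab$rejected == axes$rejected
  )
  if (length(hit) != 1L) {
    stop("axes do not identify a unique CIO statement", call. = FALSE)
  }
  structure(
    list(label = tab$label[hit], id = tab$id[hit], axes = axes),
    class = "cio_statement"
  )
}

#' @export
print.cio_statement <- function(x, ...) {
  cat("<cio_statement> ", x$label,
      if (!is.na(x$id)) paste0(" [", x$id, "]"), "\n", sep = "")
  invisible(x)
}

#' Map a CIO term label or id back to its axes
#'
#' The inverse of [term_for_axes()]. Labels are matched case-insensitively;
#' official ids (e.g. `CIO:0000003`) are accepted where known. Internal
#' (non-leaf) terms of the ontology are not assignable to annotations and
#' raise an error.
#'
#' @param x A CIO leaf term label or id.
#' @return A [cio_axes()] object.
#' @examples
#' axes_for_term("rejected")$rejected
#' axes_for_term("Low confidence from single evidence")$level
#' @export
axes_for_term <- function(x) {
  tab <- .cio_leaf_table()
  hit <- which(tolower(tab$label) == tolower(x) |
                 (!is.na(tab$id) & tab$id == x))
  if (!length(hit)) {
    cio <- builtin_cio()
    id <- ont_resolve(cio, x)
    if (!is.na(id)) {
      stop("'", x, "' is an internal CIO term, not an assignable leaf statement",
           call. = FALSE)
    }
    stop("unknown CIO term: '", x, "'", call. = FALSE)
  }
  row <- tab[hit[1], ]
  cio_axes(row$arity, row$typality, row$concordance,
           level = row$level, rejected = row$rejected)
}

#' The built-in Confidence Information Ontology
#'
#' Constructs the CIO term hierarchy without requiring the released OBO
#' file. The root `confidence information statement` branches into
#' `confidence statement from single evidence` (three level terms plus
#' `rejected`) and `confidence statement from multiple evidence lines`
#' (same-type and multiple-types branches, each splitting into congruent and
#' conflicting, conflicting into strongly and weakly conflicting, with
#' overall-confidence leaves under the congruent and weakly conflicting
#' nodes and none under strongly conflicting).
#'
#' Term ids are the canonical labels, except where the official numeric id
#' is fixed in the literature (`CIO:0000003`, `CIO:0000012`).
#'
#' @return A `cio_ontology`.
#' @export
builtin_cio <- function() {
  root <- "confidence information statement"
  single <- "confidence statement from single evidence"
  multi <- "confidence statement from multiple evidence lines"
  edges <- list()
  add <- function(child, parent) edges[[length(edges) + 1L]] <<- c(child, parent)

  add(single, root)
  add(multi, root)
  leaves <- .cio_leaf_table()
  for (i in which(leaves$arity == "single")) add(leaves$label[i], single)
  for (ty in c("same", "multiple")) {
    ty_node <- paste0("confidence statement from multiple evidence lines of ",
                      .typality_phrase[ty])
    add(ty_node, multi)
    congruent <- paste0("confidence statement from congruent evidence lines of ",
                        .typality_phrase[ty])
    conflicting <- paste0("confidence statement from conflicting evidence lines of ",
                          .typality_phrase[ty])
    add(congruent, ty_node)
    add(conflicting, ty_node)
    weak <- paste0("confidence statement from weakly conflicting evidence lines of ",
                   .typality_phrase[ty])
    strong <- paste0("confidence statement from strongly conflicting evidence lines of ",
                     .typality_phrase[ty])
    add(strong, conflicting)
    add(weak, conflicting)
    for (lv in cio_levels()) {
      add(paste0(congruent, ", overall confidence ", lv), congruent)
      add(paste0(weak, ", overall confidence ", lv), weak)
    }
  }

  labels <- unique(c(root, unlist(lapply(edges, identity))))
  ids <- labels
  known <- leaves[!is.na(leaves$id), ]
  ids[match(known$label, labels)] <- known$id
  id_of <- stats::setNames(ids, labels)

  parents <- stats::setNames(vector("list", length(labels)), ids)
  for (e in edges) {
    parents[[id_of[[e[1]]]]] <- c(parents[[id_of[[e[1]]]]], id_of[[e[2]]])
  }
  structure(
    list(
      terms = tibble::tibble(
        id = unname(id_of[labels]),
        name = labels,
        obsolete = FALSE,
        synonyms = rep(list(character(0)), length(labels))
      ),
      parents = parents
    ),
    class = "cio_ontology"
  )
}
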