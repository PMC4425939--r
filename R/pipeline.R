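#' Impute confidence on legacy annotation lines
#'
#' Legacy annotation files predate confidence curation; the CIO can still be
#' applied to them by imposing one arbitrary single-evidence confidence
#' statement on every line that carries none, after which summary
#' statements reflect at least the multiplicity and consistency of the
#' evidence. RAW lines lacking a confidence term receive the
#' single-evidence term for `default_level`; everything else is untouched.
#'
#' @param records An annotation-record tibble.
#' @param default_level One of [cio_levels()]; default `"medium"`.
#' @return The records with confidence filled in.
#' @export
impute_legacy_confidence <- function(records, default_level = "medium") {
  .level_value(default_level)
  fill <- paste(default_level, "confidence from single evidence")
  dplyr::mutate(
    records,
    confidence = dplyr::if_else(
      .data$line_kind == "RAW" & is.na(.data$confidence), fill, .data$confidence
    )
  )
}

# resolve a record's confidence field to axes, with the input row number in
# any error message
.axes_for_record <- function(confidence, row) {
  tryCatch(
    axes_for_term(confidence),
    error = function(e) {
      stop("annotation line ", row, ": ", conditionMessage(e), call. = FALSE)
    }
  )
}

.resolve_evidence <- function(eco, evidence, row) {
  parts <- strsplit(evidence, "|", fixed = TRUE)[[1]]
  ids <- vapply(parts, function(p) ont_resolve(eco, p), "")
  if (anyNA(ids)) {
    stop("annotation line ", row, ": unknown ECO term '",
         paste(parts[is.na(ids)], collapse = "', '"), "'", call. = FALSE)
  }
  unname(ids)
}

#' Append summary confidence rows to an annotation table
#'
#' Groups RAW records into assertions (by default on `subject` + `object`),
#' aggregates each group's evidence lines with [aggregate_evidence()], and
#' appends one SUMMARY record per assertion carrying the resulting CIO term,
#' the NOT qualifier when the evidence supports the negative assertion (an
#' empty qualifier when positive or undetermined), and the pipe-joined
#' evidence terms and references of the contributing lines. Pre-existing
#' SUMMARY rows are dropped and regenerated, so re-evaluated or retracted
#' single-evidence lines propagate to the summary; the operation is
#' idempotent.
#'
#' Groups in which every line is rejected yield no summary row (there is no
#' assessable evidence) and raise a warning.
#'
#' @param records An annotation-record tibble; every RAW row must carry
#'   evidence and confidence (run [impute_legacy_confidence()] first for
#'   legacy input).
#' @param eco ECO ontology used to resolve evidence terms and decide
#'   typality.
#' @param type_policy An [evidence_type_policy()].
#' @param policy An [aggregation_policy()].
#' @param group_by Column names forming the assertion key. References are
#'   deliberately not part of the key: evidence is aggregated across
#'   sources.
#' @return The RAW records followed by the generated SUMMARY records.
#' @export
summarize_annotations <- function(records,
                                  eco = toy_eco(),
                                  type_policy = evidence_type_policy(),
                                  policy = aggregation_policy(),
                                  group_by = c("subject", "object")) {
  raw <- records[records$line_kind == "RAW", , drop = FALSE]
  if (nrow(raw) == 0) return(raw)
  if (any(is.na(raw$confidence))) {
    stop("RAW lines without a confidence term; run impute_legacy_confidence() first",
         call. = FALSE)
  }
  if (any(is.na(raw$evidence))) {
    stop("annotation line ", which(is.na(raw$evidence))[1],
         ": RAW line without an evidence term", call. = FALSE)
  }

  axes <- purrr::map(seq_len(nrow(raw)),
                     function(i) .axes_for_record(raw$confidence[i], i))
  bad <- which(vapply(axes, function(a) a$arity != "single", TRUE))
  if (length(bad)) {
    stop("annotation line ", bad[1],
         ": RAW lines must carry a single-evidence confidence term",
         call. = FALSE)
  }
  evid_id <- vapply(seq_len(nrow(raw)),
                    function(i) .resolve_evidence(eco, raw$evidence[i], i)[1], "")

  key <- do.call(paste, c(unname(raw[group_by]), sep = "\r"))
  summaries <- list()
  for (k in unique(key)) {
    idx <- which(key == k)
    lines <- evidence_lines(
      polarity = raw$polarity[idx],
      evidence = evid_id[idx],
      level = vapply(axes[idx], function(a) a$level, ""),
      rejected = vapply(axes[idx], function(a) a$rejected, TRUE)
    )
    if (all(lines$rejected)) {
      warning("assertion '", sub("\r", " / ", k),
              "': all evidence lines rejected; no summary produced",
              call. = FALSE)
      next
    }
    s <- aggregate_evidence(lines, eco, type_policy, policy)
    live <- idx[!lines$rejected]
    summaries[[length(summaries) + 1L]] <- annotation_records(
      subject = raw$subject[idx[1]],
      object = raw$object[idx[1]],
      polarity = if (s$polarity == "negative") "negative" else "positive",
      evidence = paste(unique(evid_id[live]), collapse = "|"),
      confidence = s$statement$label,
      references = list(unique(unlist(raw$references[live]))),
      line_kind = "SUMMARY"
    )
  }
  dplyr::bind_rows(c(list(raw), summaries))
}

#' Validate an annotation table against the ECO and CIO
#'
#' Produces a report rather than throwing: each finding names the input row,
#' a severity and a message. Errors: a RAW line carrying a confidence term
#' but no evidence term (confidence must always be interpretable in the
#' light of its evidence source), an unknown or non-leaf CIO term, an
#' unknown ECO term, and `rejected` used on a SUMMARY line (rejected
#' evidence is excluded from aggregation, so no summary can be rejected).
#' Warnings: a single-evidence CIO term on a SUMMARY line that lists more
#' than one evidence term, and a legacy RAW line with no confidence term.
#'
#' @inheritParams summarize_annotations
#' @param cio The CIO ontology (used to distinguish internal terms from
#'   unknown ones); defaults to [builtin_cio()].
#' @return A tibble of class `cio_validation` with columns `line`,
#'   `severity` (`"error"` or `"warning"`) and `message`. Zero rows when
#'   the table is fully valid.
#' @export
validate_annotations <- function(records, eco = toy_eco(), cio = builtin_cio()) {
  findings <- list()
  note <- function(line, severity, message) {
    findings[[length(findings) + 1L]] <<- tibble::tibble(
      line = line, severity = severity, message = message
    )
  }

  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    ax <- NULL
    if (!is.na(r$confidence)) {
      ax <- tryCatch(axes_for_term(r$confidence), error = function(e) e)
      if (inherits(ax, "error")) {
        note(i, "error", conditionMessage(ax))
        ax <- NULL
      }
    } else if (r$line_kind == "RAW") {
      note(i, "warning", "legacy RAW line without a confidence term")
    }

    if (!is.na(r$evidence)) {
      parts <- strsplit(r$evidence, "|", fixed = TRUE)[[1]]
      unknown <- parts[vapply(parts, function(p) is.na(ont_resolve(eco, p)), TRUE)]
      if (length(unknown)) {
        note(i, "error",
             paste0("unknown ECO term '", paste(unknown, collapse = "', '"), "'"))
      }
    }

    if (r$line_kind == "RAW" && !is.na(r$confidence) && is.na(r$evidence)) {
      note(i, "error",
           "RAW line carries a confidence term but no evidence term")
    }
    if (r$line_kind == "SUMMARY" && !is.null(ax)) {
      if (ax$rejected) {
        note(i, "error", "'rejected' cannot appear on a SUMMARY line")
      } else if (ax$arity == "single" && !is.na(r$evidence) &&
                 grepl("|", r$evidence, fixed = TRUE)) {
        note(i, "warning",
             "single-evidence confidence term on a SUMMARY line with several evidence terms")
      }
    }
  }

  out <- if (length(findings)) dplyr::bind_rows(findings) else {
    tibble::tibble(line = integer(0), severity = character(0),
                   message = character(0))
  }
  class(out) <- c("cio_validation", class(out))
  out
}

#' Read a flat key=value policy configuration
#'
#' Recognised keys: `promote_count`, `multitype_promotion`,
#' `weak_conflict_demotion`, `legacy_default_level` (see
#' [aggregation_policy()]) and `type_mode` (see [evidence_type_policy()]).
#' Lines starting with `#` and blank lines are ignored; unknown keys raise
#' an error.
#'
#' @param path Path to the configuration file.
#' @return A list with `policy` (an `aggregation_policy`) and `type_policy`
#'   (an `evidence_type_policy`).
#' @export
read_policy_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lines[vapply(kv, length, 1L) != 2L]
  if (length(bad)) {
    stop("malformed policy line: '", bad[1], "'", call. = FALSE)
  }
  keys <- trimws(vapply(kv, `[[`, "", 1))
  vals <- trimws(vapply(kv, `[[`, "", 2))
  known <- c("promote_count", "multitype_promotion", "weak_conflict_demotion",
             "legacy_default_level", "type_mode")
  if (any(!keys %in% known)) {
    stop("unknown policy key: '", keys[!keys %in% known][1], "'", call. = FALSE)
  }
  get <- function(key, default) if (key %in% keys) vals[keys == key][1] else default
  as_flag <- function(x) tolower(x) %in% c("true", "yes", "1")
  list(
    policy = aggregation_policy(
      promote_count = as.integer(get("promote_count", "3")),
      multitype_promotion = as_flag(get("multitype_promotion", "true")),
      weak_conflict_demotion = as_flag(get("weak_conflict_demotion", "false")),
      legacy_default_level = get("legacy_default_level", "medium")
    ),
    type_policy = evidence_type_policy(get("type_mode", "subsumption"))
  )
}
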