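#' Construct annotation records
#'
#' The common record model shared by the GAF and Bgee dialects: one row per
#' annotation line.
#'
#' @param subject Annotated entity id (gene product id such as
#'   `"UniProtKB:Q9HGZ6"`, or an entity name such as `"Autopod"`).
#' @param object Annotation target (GO id, taxon name, ...).
#' @param polarity `"positive"` or `"negative"` (negative when the NOT
#'   qualifier applies).
#' @param evidence ECO term id or label; `NA` when absent. Summary lines
#'   may carry several values joined by `"|"`.
#' @param confidence CIO term label or id; `NA` for legacy lines.
#' @param references List of character vectors of reference ids (or a
#'   character vector, recycled into single-element lists).
#' @param line_kind `"RAW"` (a single-evidence annotation) or `"SUMMARY"`
#'   (an auto-generated overall statement).
#' @return A tibble with columns `subject`, `object`, `polarity`,
#'   `evidence`, `confidence`, `references` (list-column), `line_kind`.
#' @export
annotation_records <- function(subject = character(0),
                               object = character(0),
                               polarity = "positive",
                               evidence = NA_character_,
                               confidence = NA_character_,
                               references = list(),
                               line_kind = "RAW") {
  if (is.character(references)) references <- as.list(references)
  if (length(references) == 0 && length(subject) > 0) {
    references <- rep(list(character(0)), length(subject))
  }
  out <- tibble::tibble(
    subject = subject, object = object, polarity = polarity,
    evidence = as.character(evidence), confidence = as.character(confidence),
    references = references, line_kind = line_kind
  )
  stopifnot(all(out$polarity %in% c("positive", "negative")),
            all(out$line_kind %in% c("RAW", "SUMMARY")))
  out
}

.io_lines <- function(x) {
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else {
    unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  }
}

.split_cols <- function(line) strsplit(line, "\t", fixed = TRUE)[[1]]

# em-dash and hyphen are printed placeholders for an empty field
.blank_field <- function(x) is.na(x) | x %in% c("", "-", "—")

.split_refs <- function(x) {
  if (.blank_field(x)) character(0) else strsplit(x, "|", fixed = TRUE)[[1]]
}

.bgee_header <- c("Entity name", "Qualifier", "Taxon name", "Line type",
                  "Evidence term name", "Confidence term name", "Reference ID")

#' Read a Bgee anatomical-similarity TSV
#'
#' Seven tab-separated columns: entity name, qualifier (`NOT` or empty),
#' taxon name, line type (`RAW`/`SUMMARY`), evidence term name, confidence
#' term name, reference id (pipe-separated when several). An optional
#' header line is detected by its first field matching `header_token`
#' case-insensitively. Printed dash placeholders are read as empty fields.
#'
#' @param x File path or document text.
#' @param header_token Regular expression identifying the header line by
#'   its first field.
#' @return An annotation-record tibble (see [annotation_records()]).
#' @export
read_bgee_tsv <- function(x, header_token = "^entity") {
  lines <- .io_lines(x)
  lines <- lines[nzchar(trimws(lines))]
  recs <- list()
  for (i in seq_along(lines)) {
    f <- .split_cols(lines[i])
    if (i == 1 && length(f) >= 1 && grepl(header_token, f[1], ignore.case = TRUE)) next
    # trailing empty fields are dropped by the split, so 4..7 fields are valid
    if (length(f) > 7L || length(f) < 4L) {
      stop("Bgee TSV format error at line ", i, ": expected 7 columns, got ",
           length(f), call. = FALSE)
    }
    length(f) <- 7L
    f[is.na(f)] <- ""
    if (!f[4] %in% c("RAW", "SUMMARY")) {
      stop("Bgee TSV format error at line ", i, ": unknown line type '",
           f[4], "'", call. = FALSE)
    }
    recs[[length(recs) + 1L]] <- annotation_records(
      subject = f[1],
      object = f[3],
      polarity = if (trimws(f[2]) == "NOT") "negative" else "positive",
      evidence = if (.blank_field(f[5])) NA_character_ else f[5],
      confidence = if (.blank_field(f[6])) NA_character_ else f[6],
      references = list(.split_refs(f[7])),
      line_kind = f[4]
    )
  }
  if (!length(recs)) return(annotation_records())
  dplyr::bind_rows(recs)
}

#' Write a Bgee anatomical-similarity TSV
#'
#' Inverse of [read_bgee_tsv()]. SUMMARY rows are written with empty
#' evidence and reference fields, as in the published dialect: the overall
#' statement's supporting evidence is carried by the RAW rows above it.
#'
#' @param records An annotation-record tibble.
#' @param path Optional output file path.
#' @return The TSV document as a single string (invisibly when `path` is
#'   given).
#' @export
write_bgee_tsv <- function(records, path = NULL) {
  rows <- purrr::pmap_chr(records, function(subject, object, polarity,
                                            evidence, confidence, references,
                                            line_kind) {
    summary <- line_kind == "SUMMARY"
    paste(
      subject,
      if (polarity == "negative") "NOT" else "",
      object,
      line_kind,
      if (summary || is.na(evidence)) "" else evidence,
      if (is.na(confidence)) "" else confidence,
      if (summary) "" else paste(references, collapse = "|"),
      sep = "\t"
    )
  })
  doc <- paste(c(paste(.bgee_header, collapse = "\t"), rows), collapse = "\n")
  if (!is.null(path)) {
    writeLines(doc, path)
    return(invisible(doc))
  }
  doc
}

#' GO evidence-code to ECO mapping
#'
#' Built-in map restricted to codes with a published ECO correspondence;
#' extend it by concatenating a named character vector (names are GO codes,
#' values ECO ids).
#'
#' @return Named character vector, e.g. `c(ISA = "ECO:0000200")`.
#' @export
go_eco_codes <- function() {
  c(ISA = "ECO:0000200",
    IMP = "ECO:0000015",
    TAS = "ECO:0000033",
    IEA = "ECO:0000501")
}

.code_to_eco <- function(codes, code_map, line) {
  out <- character(length(codes))
  for (k in seq_along(codes)) {
    code <- codes[k]
    if (grepl("^[A-Za-z]+:", code)) {
      out[k] <- code  # already a prefixed ontology id
    } else if (code %in% names(code_map)) {
      out[k] <- unname(code_map[[code]])
    } else {
      stop("GAF format error at line ", line,
           ": unknown evidence code '", code, "'", call. = FALSE)
    }
  }
  out
}

.eco_to_code <- function(ids, code_map) {
  rev_map <- stats::setNames(names(code_map), unname(code_map))
  vapply(ids, function(id) {
    if (id %in% names(rev_map)) rev_map[[id]] else id
  }, "")
}

#' Read a GAF 2.0-style gene association file
#'
#' Standard GAF 2.0 column layout: lines starting with `!` are comments;
#' columns 1+2 form the subject (`DB:ID`), column 4 may carry the `NOT`
#' qualifier, column 5 is the annotation object, column 6 the pipe-separated
#' references, and column 7 the GO evidence code, translated to an ECO id
#' via `code_map`. This dialect additionally reads a confidence term from
#' trailing extension column 18 and a `SUMMARY` line-kind marker from
#' column 19; strict GAF consumers ignore both.
#'
#' @param x File path or document text.
#' @param code_map Named vector mapping GO evidence codes to ECO ids; see
#'   [go_eco_codes()].
#' @return An annotation-record tibble.
#' @export
read_gaf <- function(x, code_map = go_eco_codes()) {
  lines <- .io_lines(x)
  recs <- list()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln)) || startsWith(ln, "!")) next
    f <- .split_cols(ln)
    if (length(f) < 15L) {
      stop("GAF format error at line ", i, ": expected at least 15 columns, got ",
           length(f), call. = FALSE)
    }
    length(f) <- max(length(f), 19L)
    f[is.na(f)] <- ""
    codes <- .split_refs(f[7])
    evidence <- if (length(codes)) {
      paste(.code_to_eco(codes, code_map, i), collapse = "|")
    } else {
      NA_character_
    }
    qualifier_tokens <- strsplit(f[4], "|", fixed = TRUE)[[1]]
    recs[[length(recs) + 1L]] <- annotation_records(
      subject = paste0(f[1], ":", f[2]),
      object = f[5],
      polarity = if ("NOT" %in% qualifier_tokens) "negative" else "positive",
      evidence = evidence,
      confidence = if (.blank_field(f[18])) NA_character_ else f[18],
      references = list(.split_refs(f[6])),
      line_kind = if (identical(f[19], "SUMMARY")) "SUMMARY" else "RAW"
    )
  }
  if (!length(recs)) return(annotation_records())
  dplyr::bind_rows(recs)
}

#' Write a GAF 2.0-style gene association file
#'
#' Inverse of [read_gaf()]. Summary records keep their pipe-joined evidence
#' and reference lists; evidence ids with a GO code in `code_map` are
#' written as the code, others as the ECO id itself.
#'
#' @inheritParams write_bgee_tsv
#' @inheritParams read_gaf
#' @return The GAF document as a single string (invisibly when `path` is
#'   given).
#' @export
write_gaf <- function(records, path = NULL, code_map = go_eco_codes()) {
  rows <- purrr::pmap_chr(records, function(subject, object, polarity,
                                            evidence, confidence, references,
                                            line_kind) {
    db <- sub(":.*$", "", subject)
    id <- sub("^[^:]*:", "", subject)
    codes <- if (is.na(evidence)) "" else {
      paste(.eco_to_code(strsplit(evidence, "|", fixed = TRUE)[[1]], code_map),
            collapse = "|")
    }
    f <- c(db, id, id,
           if (polarity == "negative") "NOT" else "",
           object,
           paste(references, collapse = "|"),
           codes,
           "", "", "", "", "protein", "taxon:0", "", "ciotools", "", "",
           if (is.na(confidence)) "" else confidence,
           if (line_kind == "SUMMARY") "SUMMARY" else "")
    paste(f, collapse = "\t")
  })
  doc <- paste(c("!gaf-version: 2.0", rows), collapse = "\n")
  if (!is.null(path)) {
    writeLines(doc, path)
    return(invisible(doc))
  }
  doc
}
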