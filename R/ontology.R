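#' Parse an OBO-format ontology
#'
#' Reads an OBO 1.2/1.4 flat file into a lightweight ontology object that
#' keeps only the structure needed for subsumption queries: term identifiers,
#' labels, `is_a` parents, obsolescence flags and synonyms. All other tags and
#' non-`[Term]` stanzas are parsed and discarded; the downstream confidence
#' logic uses the `is_a` hierarchy only.
#'
#' @param x Path to an OBO file, or the document itself as a character vector
#'   (one string, or one element per line).
#' @return An object of class `cio_ontology`: a list with `terms` (a tibble
#'   with columns `id`, `name`, `obsolete` and list-column `synonyms`) and
#'   `parents` (named list mapping each id to its direct `is_a` parent ids).
#' @details Malformed stanzas (no `id`) raise an error naming the stanza
#'   index; an `is_a` target absent from the file and an `is_a` cycle are
#'   hard errors. Obsolete terms are retained in the term table but excluded
#'   from [ont_ancestors()] and [ont_subsumes()] results.
#' @examples
#' ont <- parse_obo(c("[Term]", "id: X:1", "name: root",
#'                    "[Term]", "id: X:2", "name: leaf", "is_a: X:1"))
#' ont_ancestors(ont, "X:2")
#' @export
parse_obo <- function(x) {
  lines <- if (length(x) == 1 && (file.exists(x) || !grepl("\n", x))) {
    if (file.exists(x)) readLines(x, warn = FALSE) else x
  } else {
    unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- sub("\\s+$", "", lines)

  # split into stanzas: a stanza starts at a line of the form [Name]
  stanza_start <- grepl("^\\[[^]]+\\]$", lines)
  stanza_id <- cumsum(stanza_start)
  term_ids <- character(0)
  term_names <- character(0)
  term_obs <- logical(0)
  parents <- list()
  synonyms <- list()

  n_term_stanza <- 0L
  for (s in split(seq_along(lines), stanza_id)) {
    if (!stanza_start[s[1]]) next            # header block before first stanza
    if (lines[s[1]] != "[Term]") next        # [Typedef] etc. ignored
    n_term_stanza <- n_term_stanza + 1L
    body <- lines[s[-1]]
    body <- body[nzchar(body) & !grepl("^\\[", body)]
    tag_match <- regmatches(body, regexec("^([A-Za-z_]+):\\s*(.*)$", body))
    tags <- vapply(tag_match, function(m) if (length(m)) m[2] else NA_character_, "")
    vals <- vapply(tag_match, function(m) if (length(m)) m[3] else NA_character_, "")
    id <- vals[tags == "id"][1]
    if (is.na(id) || !nzchar(id)) {
      stop("OBO parse error: [Term] stanza #", n_term_stanza, " has no id", call. = FALSE)
    }
    if (id %in% term_ids) {
      stop("OBO parse error: duplicate term id '", id, "'", call. = FALSE)
    }
    nm <- vals[tags == "name"][1]
    isa <- vals[tags == "is_a"]
    isa <- sub("\\s*!.*$", "", isa)          # strip trailing "! label" comments
    isa <- sub("\\s*\\{.*\\}\\s*$", "", isa) # strip trailer qualifiers
    isa <- trimws(isa)
    obs <- any(tags == "is_obsolete" & grepl("^true", vals))
    syn_raw <- vals[tags == "synonym"]
    syn <- sub('^"(.*)".*$', "\\1", syn_raw)

    term_ids <- c(term_ids, id)
    term_names <- c(term_names, if (is.na(nm)) "" else nm)
    term_obs <- c(term_obs, obs)
    parents[[id]] <- isa[nzchar(isa)]
    synonyms[[id]] <- syn
  }

  dangling <- setdiff(unlist(parents, use.names = FALSE), term_ids)
  if (length(dangling)) {
    stop("OBO parse error: is_a targets not defined in file: ",
         paste(dangling, collapse = ", "), call. = FALSE)
  }

  ont <- structure(
    list(
      terms = tibble::tibble(
        id = term_ids,
        name = term_names,
        obsolete = term_obs,
        synonyms = unname(synonyms[term_ids])
      ),
      parents = parents
    ),
    class = "cio_ontology"
  )
  if (.ont_has_cycle(ont)) {
    stop("OBO parse error: is_a graph contains a cycle", call. = FALSE)
  }
  ont
}

# Kahn's algorithm on the child->parent graph
.ont_has_cycle <- function(ont) {
  ids <- ont$terms$id
  npar <- vapply(ont$parents[ids], length, 1L)
  children <- split(
    rep(ids, npar[ids]),
    unlist(ont$parents[ids], use.names = FALSE)
  )
  indeg <- npar
  queue <- ids[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]; seen <- seen + 1L
    for (ch in children[[v]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  seen < length(ids)
}

#' @export
print.cio_ontology <- function(x, ...) {
  cat("<cio_ontology> ", nrow(x$terms), " terms, ",
      length(ont_roots(x)), " root(s), ",
      sum(x$terms$obsolete), " obsolete\n", sep = "")
  invisible(x)
}

.ont_check_id <- function(ont, id) {
  miss <- setdiff(id, ont$terms$id)
  if (length(miss)) {
    stop("unknown ontology term id(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  invisible(id)
}

#' Ontology structure queries
#'
#' `ont_roots()` returns ids with no `is_a` parent; `ont_children()` the
#' direct children of a term; `ont_ancestors()` every id reachable by
#' transitive `is_a` traversal (excluding the query term itself and any
#' obsolete term); `ont_subsumes()` tests whether `general` is `specific`
#' itself or one of its ancestors.
#'
#' @param ont A `cio_ontology` from [parse_obo()], [builtin_cio()] or
#'   [toy_eco()].
#' @param id,general,specific Term identifiers present in `ont`.
#' @return `ont_roots()`, `ont_children()` and `ont_ancestors()` return
#'   character vectors of term ids; `ont_subsumes()` a single logical.
#' @name ontology-queries
NULL

#' @rdname ontology-queries
#' @export
ont_roots <- function(ont) {
  ids <- ont$terms$id
  ids[vapply(ont$parents[ids], length, 1L) == 0L]
}

#' @rdname ontology-queries
#' @export
ont_children <- function(ont, id) {
  .ont_check_id(ont, id)
  ids <- ont$terms$id
  ids[vapply(ont$parents[ids], function(p) id %in% p, TRUE)]
}

#' @rdname ontology-queries
#' @export
ont_ancestors <- function(ont, id) {
  .ont_check_id(ont, id)
  out <- character(0)
  frontier <- ont$parents[[id]]
  while (length(frontier)) {
    new <- setdiff(frontier, out)
    out <- c(out, new)
    frontier <- unique(unlist(ont$parents[new], use.names = FALSE))
  }
  obsolete <- ont$terms$id[ont$terms$obsolete]
  setdiff(out, obsolete)
}

#' @rdname ontology-queries
#' @export
ont_subsumes <- function(ont, general, specific) {
  .ont_check_id(ont, c(general, specific))
  obs <- ont$terms$obsolete[match(c(general, specific), ont$terms$id)]
  if (any(obs)) return(FALSE)
  general == specific || general %in% ont_ancestors(ont, specific)
}

#' Look up a term id by id, label or synonym
#'
#' Matching is case-insensitive on labels and synonyms; an exact id match
#' wins. Returns `NA` when nothing matches.
#'
#' @inheritParams ontology-queries
#' @param x A term id, label or synonym.
#' @return The matching term id, or `NA_character_`.
#' @export
ont_resolve <- function(ont, x) {
  if (x %in% ont$terms$id) return(x)
  hit <- which(tolower(ont$terms$name) == tolower(x))
  if (length(hit)) return(ont$terms$id[hit[1]])
  syn_hit <- which(vapply(
    ont$terms$synonyms,
    function(s) any(tolower(s) == tolower(x)), TRUE
  ))
  if (length(syn_hit)) return(ont$terms$id[syn_hit[1]])
  NA_character_
}

#' Serialise an ontology to OBO format
#'
#' Writes `[Term]` stanzas with `id`, `name`, `is_a`, `synonym` and
#' `is_obsolete` tags. `parse_obo(write_obo(ont))` reproduces `ont`
#' term-for-term on those fields.
#'
#' @inheritParams ontology-queries
#' @param path Optional file path; when given the document is also written
#'   to disk.
#' @return The OBO document, invisibly when `path` is given, as a single
#'   string.
#' @export
write_obo <- function(ont, path = NULL) {
  header <- c("format-version: 1.2", "")
  stanzas <- purrr::pmap(ont$terms, function(id, name, obsolete, synonyms) {
    pn <- ont$parents[[id]]
    plabel <- ont$terms$name[match(pn, ont$terms$id)]
    c("[Term]",
      paste0("id: ", id),
      paste0("name: ", name),
      if (length(synonyms)) paste0("synonym: \"", synonyms, "\" EXACT []"),
      if (length(pn)) paste0("is_a: ", pn, " ! ", plabel),
      if (obsolete) "is_obsolete: true",
      "")
  })
  doc <- paste(c(header, unlist(stanzas)), collapse = "\n")
  if (!is.null(path)) {
    writeLines(doc, path)
    return(invisible(doc))
  }
  doc
}
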