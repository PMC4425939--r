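# Independent brute-force reachability on the child->parent map: iterate a
# fixed point over one-step parent expansion, never reusing ont_ancestors().
brute_ancestors <- function(ont, id) {
  reach <- character(0)
  frontier <- id
  repeat {
    step <- unique(unlist(lapply(frontier, function(x) ont$parents[[x]])))
    step <- setdiff(step, c(reach, id))
    if (!length(step)) break
    reach <- c(reach, step)
    frontier <- step
  }
  sort(setdiff(reach, ont$terms$id[ont$terms$obsolete]))
}

# random acyclic ontology: term i may only point at earlier terms
random_ontology <- function(n, p_edge = 0.4, p_obsolete = 0.1) {
  ids <- sprintf("X:%d", seq_len(n))
  stanzas <- character(0)
  for (i in seq_len(n)) {
    parents <- if (i > 1) ids[seq_len(i - 1)][runif(i - 1) < p_edge] else character(0)
    stanzas <- c(stanzas,
                 "[Term]",
                 paste0("id: ", ids[i]),
                 paste0("name: term ", i),
                 paste0("is_a: ", parents),
                 if (runif(1) < p_obsolete) "is_obsolete: true",
                 "")
  }
  parse_obo(c("format-version: 1.2", "", stanzas))
}

# the three evidence types used in exhaustive enumeration: A is a child of B
# in the toy ECO, C is unrelated to both
enum_types <- c(A = "ECO:0000033", B = "TOYECO:0000005", C = "ECO:0000015")

# typality decided from first principles: A and B are the same type
# (ancestor/descendant), C matches only itself
independent_typality <- function(type_keys) {
  if (all(type_keys %in% c("A", "B")) || all(type_keys == "C")) "same" else "multiple"
}

# all line kinds for enumeration: 3 levels x 2 polarities x 3 types, plus
# rejected x 2 polarities x 3 types
enum_line_kinds <- function() {
  live <- expand.grid(level = c("low", "medium", "high"),
                      polarity = c("positive", "negative"),
                      type = c("A", "B", "C"),
                      rejected = FALSE,
                      stringsAsFactors = FALSE)
  dead <- expand.grid(level = NA_character_,
                      polarity = c("positive", "negative"),
                      type = c("A", "B", "C"),
                      rejected = TRUE,
                      stringsAsFactors = FALSE)
  rbind(live, dead)
}

# all multisets of the given size over n kinds, as a matrix of sorted rows
enum_multisets <- function(n_kinds, size) {
  grids <- rep(list(seq_len(n_kinds)), size)
  g <- as.matrix(expand.grid(grids))
  g[apply(g, 1, function(r) all(diff(r) >= 0)), , drop = FALSE]
}

lines_from_kinds <- function(kinds, idx) {
  k <- kinds[idx, , drop = FALSE]
  evidence_lines(polarity = k$polarity,
                 evidence = unname(enum_types[k$type]),
                 level = k$level,
                 rejected = k$rejected)
}
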