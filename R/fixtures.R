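.pkg_extdata <- function(file) {
  path <- system.file("extdata", file, package = "ciotools")
  if (!nzchar(path)) {
    # during in-source development the package may not be installed yet
    path <- file.path("inst", "extdata", file)
  }
  path
}

#' Toy Evidence and Conclusion Ontology
#'
#' A 13-term miniature of the ECO covering every evidence type used in the
#' worked examples: experimental evidence (mutant phenotype, microarray),
#' similarity evidence (sequence alignment, protein BLAST, developmental
#' similarity), author statements (traceable, non-traceable), phylogenetic
#' distribution evidence and automatic assertion. Real ECO ids are used only
#' for terms whose id is fixed in the literature; invented grouping nodes
#' carry a `TOYECO:` prefix so they cannot masquerade as real ECO ids.
#'
#' @return A `cio_ontology` with 13 terms and one root.
#' @export
toy_eco <- function() parse_obo(.pkg_extdata("toy-eco.obo"))

#' Worked example: conflicting autopod homology annotations
#'
#' The two RAW rows of the published Bgee-style example: positive and
#' NOT-qualified annotations of autopod homology among Vertebrata, both
#' traceable author statements of medium confidence from the same
#' reference. Aggregating them yields a strongly-conflicting same-type
#' summary.
#'
#' @return An annotation-record tibble with two RAW rows.
#' @export
worked_example_bgee <- function() {
  recs <- read_bgee_tsv(.pkg_extdata("autopod-vertebrata.tsv"))
  recs[recs$line_kind == "RAW", , drop = FALSE]
}

#' Worked example: congruent ERG9 annotations of multiple types
#'
#' Two positive GO annotations of the Candida glabrata ERG9 gene product
#' (UniProtKB:Q9HGZ6) to squalene synthase activity (GO:0051996), one from
#' sequence alignment evidence (ECO:0000200, GO code ISA) and one from
#' mutant phenotype evidence (ECO:0000015, GO code IMP), both high
#' confidence from single evidence. Aggregating them yields CIO:0000012,
#' the highest confidence statement in the ontology.
#'
#' @return An annotation-record tibble with two RAW rows.
#' @export
worked_example_gaf <- function() read_gaf(.pkg_extdata("erg9.gaf"))

#' Generate synthetic ground-truth annotations
#'
#' Emulates a curated annotation file: assertions (subject-object pairs)
#' each supported by one or more single-evidence RAW lines with a polarity,
#' an ECO evidence term, a single-evidence confidence level or `rejected`,
#' and a reference id. Each assertion carries a latent truth label, and its
#' intended summary statement is computed with the independent
#' [decision_table_oracle()] so generated files double as ground truth for
#' the aggregation engine.
#'
#' @param seed Integer seed; output is reproducible bit-for-bit.
#' @param n_assertions Number of distinct subject-object assertions.
#' @param lines_per Integer vector of candidate evidence-line counts per
#'   assertion, sampled uniformly.
#' @param p_negative Probability that a line carries the NOT qualifier.
#' @param level_weights Non-negative sampling weights for the low, medium
#'   and high single-evidence levels.
#' @param p_rejected Probability that a line is tagged `rejected`.
#' @param type_pool ECO ids to draw evidence terms from; defaults to the
#'   nine assignable leaves of [toy_eco()].
#' @param policy,type_policy Policies used when computing the intended
#'   summaries.
#' @return A list with `annotations` (annotation-record tibble plus
#'   `assertion` and `truth` columns) and `intended` (one row per
#'   assertion: the oracle's summary label, polarity and level; `NA` label
#'   when every line of the assertion is rejected).
#' @export
generate_annotations <- function(seed,
                                 n_assertions = 20,
                                 lines_per = 1:4,
                                 p_negative = 0.25,
                                 level_weights = c(1, 1, 1),
                                 p_rejected = 0.05,
                                 type_pool = NULL,
                                 policy = aggregation_policy(),
                                 type_policy = evidence_type_policy()) {
  if (any(c(p_negative, p_rejected) < 0) || any(c(p_negative, p_rejected) > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (length(level_weights) != 3 || any(level_weights < 0) ||
      sum(level_weights) == 0) {
    stop("level_weights must be 3 non-negative values, not all zero",
         call. = FALSE)
  }
  lines_per <- as.integer(lines_per)
  if (anyNA(lines_per) || any(lines_per < 1)) {
    stop("lines_per must be positive integers", call. = FALSE)
  }
  eco <- toy_eco()
  if (is.null(type_pool)) {
    ids <- eco$terms$id
    type_pool <- ids[!vapply(ids, function(i) length(ont_children(eco, i)) > 0, TRUE)]
  }
  .ont_check_id(eco, type_pool)

  withr::with_seed(as.integer(seed), {
    ann <- list()
    intended <- list()
    for (a in seq_len(n_assertions)) {
      subject <- sprintf("GENE:%04d", a)
      object <- sprintf("TERM:%04d", a)
      truth <- sample(c(TRUE, FALSE), 1)
      n_lines <- if (length(lines_per) == 1) lines_per else sample(lines_per, 1)
      rejected <- stats::runif(n_lines) < p_rejected
      polarity <- ifelse(stats::runif(n_lines) < p_negative, "negative", "positive")
      level <- ifelse(rejected, NA_character_,
                      sample(cio_levels(), n_lines, replace = TRUE,
                             prob = level_weights))
      evid <- sample(type_pool, n_lines, replace = TRUE)
      ann[[a]] <- annotation_records(
        subject = rep(subject, n_lines),
        object = rep(object, n_lines),
        polarity = polarity,
        evidence = evid,
        confidence = ifelse(rejected, "rejected",
                            paste(level, "confidence from single evidence")),
        references = as.list(sprintf("REF:%04d-%d", a, seq_len(n_lines))),
        line_kind = "RAW"
      )
      ann[[a]]$assertion <- a
      ann[[a]]$truth <- truth

      lines <- evidence_lines(polarity, evid, level, rejected)
      live <- lines[!lines$rejected, , drop = FALSE]
      if (nrow(live) == 0) {
        intended[[a]] <- tibble::tibble(
          assertion = a, label = NA_character_,
          polarity = NA_character_, level = NA_character_
        )
      } else {
        typality <- if (nrow(live) >= 2) {
          group_typality(eco, live$evidence, type_policy)
        } else {
          "unspecified"
        }
        o <- decision_table_oracle(lines, typality, policy)
        intended[[a]] <- tibble::tibble(
          assertion = a, label = o$label,
          polarity = o$polarity, level = o$level
        )
      }
    }
    list(annotations = dplyr::bind_rows(ann),
         intended = dplyr::bind_rows(intended))
  })
}
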