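#' Evidence-type comparison policy
#'
#' The structure of the Evidence and Conclusion Ontology (ECO) is used to
#' decide whether evidence lines are of the same type. Under `"subsumption"`
#' (the default) two ECO terms are the same type when one is the other or an
#' ancestor/descendant of the other; under `"exact"` only identical terms
#' match. Exact mode is strictly stronger: everything it calls same-type,
#' subsumption mode does too.
#'
#' @param mode `"subsumption"` or `"exact"`.
#' @return An object of class `evidence_type_policy`.
#' @export
evidence_type_policy <- function(mode = c("subsumption", "exact")) {
  structure(list(mode = match.arg(mode)), class = "evidence_type_policy")
}

#' Are two evidence lines of the same type?
#'
#' @param eco A `cio_ontology` holding the ECO (e.g. [toy_eco()]).
#' @param a,b ECO term ids present in `eco`.
#' @param policy An [evidence_type_policy()].
#' @return Logical.
#' @examples
#' eco <- toy_eco()
#' same_type(eco, "ECO:0000033", "ECO:0000033")
#' same_type(eco, "ECO:0000200", "ECO:0000015")
#' @export
same_type <- function(eco, a, b, policy = evidence_type_policy()) {
  .ont_check_id(eco, c(a, b))
  if (a == b) return(TRUE)
  if (policy$mode == "exact") return(FALSE)
  ont_subsumes(eco, a, b) || ont_subsumes(eco, b, a)
}

#' Typality of a group of evidence lines
#'
#' A group is of the `"same"` type when every unordered pair of its ECO
#' terms is same-type under the policy, and of `"multiple"` types otherwise.
#' Typality is only defined for groups of at least two lines; the type
#' multiplicity of a single line is unspecified.
#'
#' @inheritParams same_type
#' @param terms Character vector of ECO term ids, length at least 2.
#' @return `"same"` or `"multiple"`.
#' @examples
#' eco <- toy_eco()
#' group_typality(eco, c("ECO:0000200", "ECO:0000015"))
#' @export
group_typality <- function(eco, terms, policy = evidence_type_policy()) {
  if (length(terms) < 2L) {
    stop("typality is only defined for groups of at least two evidence lines",
         call. = FALSE)
  }
  .ont_check_id(eco, unique(terms))
  uniq <- unique(terms)
  if (length(uniq) == 1L) return("same")
  if (policy$mode == "exact") return("multiple")
  for (i in seq_len(length(uniq) - 1L)) {
    for (j in seq(i + 1L, length(uniq))) {
      if (!same_type(eco, uniq[i], uniq[j], policy)) return("multiple")
    }
  }
  "same"
}
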