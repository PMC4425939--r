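test_that("the built-in CIO has the published branch structure", {
  cio <- builtin_cio()
  root <- ont_roots(cio)
  expect_equal(length(root), 1)
  branches <- ont_children(cio, root)
  expect_equal(length(branches), 2)

  single <- "confidence statement from single evidence"
  kids <- ont_children(cio, single)
  level_kids <- setdiff(kids, "rejected")
  expect_equal(length(level_kids), 3)       # three basic level terms
  expect_true("rejected" %in% kids)

  multi <- "confidence statement from multiple evidence lines"
  typality_nodes <- ont_children(cio, multi)
  expect_equal(length(typality_nodes), 2)   # same type / multiple types
  for (ty in typality_nodes) {
    sub <- ont_children(cio, ty)
    expect_equal(length(sub), 2)            # congruent / conflicting
    conflicting <- sub[grepl("from conflicting", sub)]
    congruent <- sub[grepl("congruent", sub)]
    expect_equal(length(ont_children(cio, congruent)), 3)
    strength <- ont_children(cio, conflicting)
    expect_equal(length(strength), 2)       # strongly / weakly
    weak <- strength[grepl("weakly", strength)]
    strong <- strength[grepl("strongly", strength)]
    expect_equal(length(ont_children(cio, weak)), 3)
    expect_equal(length(ont_children(cio, strong)), 0)  # no overall level
  }
})

test_that("leaf statements count 4 single-evidence and 14 multi-line", {
  leaves <- cio_leaves()
  expect_equal(nrow(leaves), 18)
  expect_equal(sum(leaves$arity == "single"), 4)
  expect_equal(sum(leaves$arity == "multiple"), 14)
  expect_equal(anyDuplicated(leaves$label), 0)
})

test_that("published term ids attach to the right labels", {
  high_single <- term_for_axes(cio_axes("single", level = "high"))
  expect_equal(high_single$id, "CIO:0000003")
  expect_equal(high_single$label, "high confidence from single evidence")

  top <- term_for_axes(cio_axes("multiple", "multiple", "congruent", "high"))
  expect_equal(top$id, "CIO:0000012")
  expect_equal(
    top$label,
    "confidence statement from congruent evidence lines of multiple types, overall confidence high"
  )

  strong_same <- term_for_axes(cio_axes("multiple", "same", "strongly_conflicting"))
  expect_equal(
    strong_same$label,
    "confidence statement from strongly conflicting evidence lines of same type"
  )
  expect_true(is.na(strong_same$id))
})

test_that("axes <-> term is a bijection over every leaf", {
  leaves <- cio_leaves()
  for (i in seq_len(nrow(leaves))) {
    ax <- axes_for_term(leaves$label[i])
    stmt <- term_for_axes(ax)
    expect_equal(stmt$label, leaves$label[i])
    expect_equal(stmt$id, leaves$id[i])
  }
  # ids resolve too
  expect_equal(axes_for_term("CIO:0000003")$level, "high")
  expect_equal(axes_for_term("CIO:0000012")$typality, "multiple")
})

test_that("the ten most-informative published labels all resolve", {
  labels <- c(
    "High confidence from single evidence",
    "Confidence statement from congruent evidence lines of same type, overall confidence high",
    "Confidence statement from congruent evidence lines of same type, overall confidence medium",
    "Confidence statement from congruent evidence lines of multiple types, overall confidence high",
    "Confidence statement from congruent evidence lines of multiple types, overall confidence medium",
    "Low confidence from single evidence",
    "Confidence statement from strongly conflicting evidence lines of same type",
    "Confidence statement from weakly conflicting evidence lines of same type, overall confidence low",
    "Confidence statement from strongly conflicting evidence lines of multiple types",
    "Confidence statement from weakly conflicting evidence lines of multiple types, overall confidence low"
  )
  for (lab in labels) expect_s3_class(axes_for_term(lab), "cio_axes")
})

test_that("rejected and single-level terms map to the expected axes", {
  rej <- axes_for_term("rejected")
  expect_true(rej$rejected)
  expect_true(is.na(rej$level))

  low <- axes_for_term("low confidence from single evidence")
  expect_equal(low$arity, "single")
  expect_equal(low$level, "low")
})

test_that("inconsistent axes and non-assignable terms are refused", {
  expect_error(cio_axes("multiple", "same", "strongly_conflicting", "high"),
               "strongly conflicting")
  expect_error(cio_axes("single"), "requires a level")
  expect_error(cio_axes("multiple", "same", "unspecified"), "concordance")
  expect_error(cio_axes("single", level = "high", rejected = TRUE), "rejected")
  expect_error(axes_for_term("confidence statement from multiple evidence lines"),
               "not an assignable leaf")
  expect_error(axes_for_term("certainly not a term"), "unknown CIO term")
})

test_that("the built-in CIO roundtrips through OBO", {
  cio <- builtin_cio()
  back <- parse_obo(write_obo(cio))
  expect_equal(sort(back$terms$id), sort(cio$terms$id))
  expect_equal(back$terms$name[match(cio$terms$id, back$terms$id)],
               cio$terms$name)
})
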