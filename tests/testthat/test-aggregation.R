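eco <- toy_eco()

lines_of <- function(spec) {
  # spec like "high+", "mediumNOT", "rej+", with an optional @type suffix
  parts <- strsplit(spec, "@", fixed = TRUE)
  core <- vapply(parts, `[[`, "", 1)
  type <- vapply(parts, function(p) if (length(p) > 1) p[2] else "ECO:0000033", "")
  negative <- grepl("NOT$", core)
  level <- sub("(NOT|\\+)$", "", core)
  rejected <- level == "rej"
  evidence_lines(
    polarity = ifelse(negative, "negative", "positive"),
    evidence = type,
    level = ifelse(rejected, NA_character_, level),
    rejected = rejected
  )
}

test_that("rejected evidence is dropped, order preserved", {
  l <- lines_of(c("high+", "rej+", "lowNOT"))
  kept <- filter_rejected(l)
  expect_equal(nrow(kept), 2)
  expect_equal(kept$level, c("high", "low"))
  expect_equal(nrow(filter_rejected(l[0, ])), 0)
  expect_equal(nrow(filter_rejected(lines_of(c("rej+", "rejNOT")))), 0)
})

test_that("concordance is mixed-polarity by default and pluggable", {
  expect_equal(detect_concordance(lines_of(c("medium+", "mediumNOT"))), "conflicting")
  expect_equal(detect_concordance(lines_of(c("high+", "high+"))), "congruent")
  expect_equal(detect_concordance(lines_of(c("lowNOT", "lowNOT"))), "congruent")
  expect_error(detect_concordance(lines_of("high+")), "at least two")
  # custom predicate hook
  always <- function(lines) TRUE
  expect_equal(detect_concordance(lines_of(c("high+", "high+")), always),
               "conflicting")
})

test_that("conflict strength compares the best level on each side", {
  expect_equal(classify_conflict_strength(lines_of(c("medium+", "mediumNOT")))$strength,
               "strong")
  weak <- classify_conflict_strength(lines_of(c("high+", "high+", "lowNOT")))
  expect_equal(weak$strength, "weak")
  expect_equal(weak$winner, "positive")
  # a low positive straggler does not soften a high-vs-high tie
  expect_equal(classify_conflict_strength(lines_of(c("high+", "highNOT", "low+")))$strength,
               "strong")
  expect_error(classify_conflict_strength(lines_of(c("high+", "high+"))),
               "conflicting")
})

test_that("overall level is max plus promotions, capped at high", {
  pol <- aggregation_policy()
  expect_equal(overall_level(lines_of(c("medium+", "medium+")), "same", pol),
               "medium")
  expect_equal(overall_level(lines_of(c("medium+", "medium+", "medium+")),
                             "multiple", pol), "high")
  expect_equal(overall_level(lines_of(c("high+", "high+")), "multiple", pol),
               "high")
  # promotion by count alone
  expect_equal(overall_level(lines_of(c("low+", "low+", "low+", "low+")),
                             "same", pol), "medium")
  # stacked promotions: many low lines of multiple types reach high
  expect_equal(overall_level(lines_of(c("low+", "low+", "low+", "low+")),
                             "multiple", pol), "high")
  expect_error(overall_level(lines_of(character(0)), "same", pol), "at least one")
})

test_that("aggregate reproduces the published worked examples", {
  # conflicting autopod annotations: medium vs medium NOT, same type
  autopod <- aggregate_evidence(lines_of(c("medium+", "mediumNOT")), eco)
  expect_equal(
    autopod$statement$label,
    "confidence statement from strongly conflicting evidence lines of same type"
  )
  expect_equal(autopod$polarity, "undetermined")

  # ERG9: two congruent high lines of different types -> CIO:0000012
  erg9 <- aggregate_evidence(
    lines_of(c("high+@ECO:0000200", "high+@ECO:0000015")), eco
  )
  expect_equal(erg9$statement$id, "CIO:0000012")

  # urinary bladder: two medium same-type lines stay medium...
  phylo <- "TOYECO:0000007"
  devsim <- "TOYECO:0000004"
  bladder2 <- aggregate_evidence(
    lines_of(c(paste0("medium+@", phylo), paste0("medium+@", phylo))), eco
  )
  expect_equal(bladder2$statement$axes$level, "medium")
  expect_equal(bladder2$statement$axes$typality, "same")
  # ...and a third medium line of a different type raises it to high
  bladder3 <- aggregate_evidence(
    lines_of(c(paste0("medium+@", phylo), paste0("medium+@", phylo),
               paste0("medium+@", devsim))), eco
  )
  expect_equal(bladder3$statement$axes$level, "high")
  expect_equal(bladder3$statement$axes$typality, "multiple")
})

test_that("a single surviving line passes through as its own statement", {
  s <- aggregate_evidence(lines_of(c("high+", "rej+")), eco)
  expect_equal(s$statement$id, "CIO:0000003")
  expect_equal(s$statement$axes$arity, "single")
  expect_equal(s$polarity, "positive")
  expect_equal(s$contributing, 1L)
})

test_that("degenerate inputs raise contract errors", {
  expect_error(aggregate_evidence(lines_of(character(0)), eco), "no evidence")
  expect_error(aggregate_evidence(lines_of(c("rej+", "rejNOT")), eco),
               "no assessable evidence")
})

test_that("aggregate is permutation invariant and ignores rejected lines", {
  set.seed(3)
  kinds <- enum_line_kinds()
  for (rep in 1:30) {
    idx <- sample(nrow(kinds), sample(2:4, 1), replace = TRUE)
    l <- lines_from_kinds(kinds, idx)
    if (all(l$rejected)) next
    base <- tidy(aggregate_evidence(l, eco))
    perm <- tidy(aggregate_evidence(l[sample(nrow(l)), ], eco))
    expect_equal(perm, base)
    with_rejected <- dplyr::bind_rows(
      l, lines_from_kinds(kinds, sample(which(kinds$rejected), 1))
    )
    expect_equal(tidy(aggregate_evidence(with_rejected, eco))$label, base$label)
  }
})

test_that("appending a congruent positive line never lowers the level", {
  set.seed(9)
  kinds <- enum_line_kinds()
  positive_live <- which(!kinds$rejected & kinds$polarity == "positive")
  level_rank <- function(x) match(x, cio_levels())
  for (rep in 1:30) {
    idx <- sample(positive_live, sample(2:4, 1), replace = TRUE)
    l <- lines_from_kinds(kinds, idx)
    before <- aggregate_evidence(l, eco)$statement$axes$level
    extra <- lines_from_kinds(kinds, sample(positive_live, 1))
    after <- aggregate_evidence(dplyr::bind_rows(l, extra), eco)$statement$axes$level
    expect_gte(level_rank(after), level_rank(before))
  }
})

test_that("strong conflicts never carry a level; others always do", {
  set.seed(13)
  kinds <- enum_line_kinds()
  for (rep in 1:60) {
    idx <- sample(nrow(kinds), sample(2:4, 1), replace = TRUE)
    l <- lines_from_kinds(kinds, idx)
    if (sum(!l$rejected) < 1) next
    s <- aggregate_evidence(l, eco)
    if (s$statement$axes$concordance == "strongly_conflicting") {
      expect_true(is.na(s$statement$axes$level))
      expect_equal(s$polarity, "undetermined")
    } else {
      expect_false(is.na(s$statement$axes$level))
    }
  }
})

test_that("policy knobs move the outcome as documented", {
  phylo <- "TOYECO:0000007"
  # no multitype promotion: different types no longer lift the level
  no_promo <- aggregation_policy(multitype_promotion = FALSE)
  s <- aggregate_evidence(
    lines_of(c("medium+@ECO:0000200", "medium+@ECO:0000015")), eco,
    policy = no_promo
  )
  expect_equal(s$statement$axes$level, "medium")
  # promote_count reachable at 2
  s2 <- aggregate_evidence(
    lines_of(c(paste0("low+@", phylo), paste0("low+@", phylo))), eco,
    policy = aggregation_policy(promote_count = 2)
  )
  expect_equal(s2$statement$axes$level, "medium")
  # weak-conflict demotion
  s3 <- aggregate_evidence(
    lines_of(c("high+", "high+", "lowNOT")), eco,
    policy = aggregation_policy(weak_conflict_demotion = TRUE)
  )
  expect_equal(s3$statement$axes$concordance, "weakly_conflicting")
  expect_equal(s3$statement$axes$level, "medium")
  expect_error(aggregation_policy(promote_count = 1), ">= 2")
})

test_that("exact typing mode makes distinct same-branch terms multiple types", {
  l <- lines_of(c("medium+@ECO:0000033", "medium+@TOYECO:0000005"))
  sub <- aggregate_evidence(l, eco)
  expect_equal(sub$statement$axes$typality, "same")
  ex <- aggregate_evidence(l, eco, type_policy = evidence_type_policy("exact"))
  expect_equal(ex$statement$axes$typality, "multiple")
})

test_that("tidy and glance expose the summary as one-row tibbles", {
  s <- aggregate_evidence(lines_of(c("high+", "mediumNOT")), eco)
  td <- tidy(s)
  expect_equal(nrow(td), 1)
  expect_equal(td$concordance, "weakly_conflicting")
  expect_equal(td$polarity, "positive")
  gl <- glance(s)
  expect_equal(gl$contributing, 2L)
})
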