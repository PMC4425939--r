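---
title: "Aggregating annotation confidence with the CIO"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aggregating annotation confidence with the CIO}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciotools)
```

## The model

A curated annotation links a biological entity (a gene product, an
anatomical structure) to a term (a GO term, a taxon-scoped homology
hypothesis), supported by one or more *evidence lines*, each typed by an
ECO term and sourced from a reference. The Confidence Information Ontology
(CIO) expresses how much an annotation should be trusted. `ciotools`
represents every assignable CIO statement by five semantic coordinates —
arity, typality, concordance, level, rejected — and keeps the mapping
between coordinate combinations and term labels bijective over the 18 leaf
statements:

```{r}
cio_leaves()
```

Four assumptions underlie the model:

* **Confidence is ordinal, not numeric.** Three levels (`low`, `medium`,
  `high`) are the common denominator across curation teams; how a team
  maps E-values, replicate counts or alignment identities onto them is out
  of scope here and deliberately left to the team.
* **Confidence is always interpreted relative to its evidence source**, so
  a confidence term should be accompanied by an ECO term; the validator
  flags violations.
* **Independent corroboration is worth more than repetition.** Evidence
  lines of multiple ECO types supporting the same assertion raise overall
  confidence; repeated lines of one type raise it only in numbers.
* **Retraction is not negation.** A `rejected` tag on an evidence line
  records that the line itself was invalidated (e.g. a retracted paper);
  it is excluded from aggregation but retained for traceability. A NOT
  qualifier, by contrast, is a live negative claim and participates in
  conflict detection.

## Evidence typing

Whether two evidence lines are "of the same type" is decided from the ECO
`is_a` structure. The default rule is *subsumption*: same type iff one term
equals, or is an ancestor/descendant of, the other. This reproduces all the
standard cases (two traceable author statements: same; sequence alignment
vs mutant phenotype: different; two phylogenetic-distribution lines: same;
phylogenetic distribution vs developmental similarity: different). The ECO
itself does not fix the granularity at which two terms stop counting as
one type — are two different children of "author statement" the same type?
Subsumption answers "no"; an `exact` mode (identity only) is provided for
teams that want stricter typing, and is strictly stronger. A group is
same-type only when *every* pair matches: one differing line makes the
whole group "multiple types", which also means that the one heterogeneous
line is what earns the group its multi-type promotion.

## The aggregation rules and their knobs

For one assertion's lines, after dropping rejected lines (a single
survivor passes through as its own single-evidence statement):

1. **Concordance.** The default conflict predicate is mixed polarity —
   positive and NOT annotations of the same assertion. What counts as a
   conflict is resource-specific (e.g. incompatible GO terms), so the
   predicate is a function argument, not a constant.
2. **Conflict strength.** Strong iff the best level on the positive side
   equals the best level on the negative side; otherwise weak, and the
   side with the higher best level wins. Strongly conflicting statements
   carry no overall level and an undetermined polarity: the evidence does
   not support a consensual conclusion, and such assertions should be
   prioritised for re-annotation.
3. **Overall level** (congruent groups and the winning side of weak
   conflicts): the side's maximum level, then one promotion step if the
   group is multi-type (`multitype_promotion`, default on), one step if
   the side has at least `promote_count` lines (default 3), saturating at
   `high`.

The defaults are the minimal rule set consistent with the published
behaviour of the ontology: two medium same-type lines stay medium; a third
medium line of a different type reaches high; two congruent high lines of
different types reach the top statement CIO:0000012; many low-confidence
congruent lines can still reach high through stacked promotions.

Two rules are genuinely open and are therefore policy knobs with
documented defaults rather than claims of intent:

* **Weak-conflict level.** By default the winning side's level is computed
  as if congruent, without demotion — the ontology reaches "weakly
  conflicting …, overall confidence high", so that leaf must be
  attainable. `weak_conflict_demotion = TRUE` subtracts one step for teams
  that want conflict to cost confidence.
* **Typality of conflicting groups** is computed over *all* non-rejected
  lines, not just the winning side, because the statement describes the
  whole evidence set.

A promotion threshold of 3 was chosen so that a mere pair of same-type
repetitions does not move the level (matching the two-medium-lines case)
while "several" congruent lines do.

## File dialects

The Bgee anatomical-similarity dialect has seven tab-separated columns
(entity, qualifier, taxon, RAW/SUMMARY, evidence term name, confidence
term name, reference). Printed dashes are placeholders for empty fields.
SUMMARY rows are written with empty evidence and reference fields — the
dialect attributes supporting evidence through the RAW rows — so the
in-memory record's pipe-joined evidence list is dropped when writing this
dialect (and preserved in the GAF dialect, which has no such constraint).

GAF 2.0 has no confidence column, so the GAF dialect appends the CIO term
as column 18 and a SUMMARY marker as column 19; strict GAF consumers
ignore trailing columns. GO evidence codes are translated to ECO ids
through a user-extensible map whose built-ins are restricted to codes with
an unambiguous published correspondence (ISA, IMP, TAS, IEA); unmapped ECO
ids are written as themselves.

Summaries are grouped on (subject, object) — gene product + GO id, or
entity + taxon. References are deliberately **not** part of the key:
evidence for one assertion is aggregated across sources. Pre-existing
SUMMARY rows are never trusted: they are dropped and regenerated, which
makes summarisation idempotent and lets a later rejection of a single
evidence line propagate to the summary on the next run.

Legacy files with no confidence column can still be summarised by imposing
one arbitrary single-evidence level on every line
(`impute_legacy_confidence()`, default `medium`); the summaries then
reflect at least the multiplicity and consistency of the evidence.

## Numerical and degenerate-input choices

* Levels are compared as ranks 1–3; promotions saturate at `high` and the
  optional weak-conflict demotion floors at `low`. Demotion applies after
  the cap.
* An assertion whose lines are all rejected has no assessable evidence:
  `aggregate_evidence()` raises an error, and the file-level pipeline
  skips the group with a warning instead of fabricating a summary row.
* Aggregation is permutation-invariant; ties need no breaking because only
  side maxima, counts and the type partition enter the rules.
* OBO parsing keeps only `[Term]` stanzas and `is_a` edges (the logic uses
  subsumption only); cycles and dangling `is_a` targets are hard errors,
  obsolete terms are retained but excluded from traversal, and using one
  as an annotation term is a validation finding rather than a parse error.
* Canonical CIO keys are labels; numeric ids are attached only where the
  published record fixes them (CIO:0000003, CIO:0000012) — inventing the
  remaining ids would risk colliding with the released ontology. Labels
  match case-insensitively so sentence-cased table renderings resolve.

## What the synthetic generator emulates — and what it does not

`generate_annotations()` produces grouped RAW lines with polarity,
evidence type drawn from a 13-term toy ECO, a single-evidence level or
`rejected`, and a reference id; each assertion also carries a latent truth
label and the summary statement computed by an independently written
decision-table oracle. Defaults (1–4 lines per assertion, 25% negative
lines, uniform levels, 5% rejected) are chosen to exercise every branch of
the rule engine — congruent, weakly and strongly conflicting, single-line
passthrough and all-rejected groups — at rates a curator would recognise
from a mixed-quality annotation corpus, not to mimic any particular
resource's empirical distribution.

What passing tests on this generator shows is that the engine implements
its stated decision table exactly (the test suite checks engine/oracle
agreement exhaustively over every evidence multiset of size ≤ 4 — about
21,000 cases — plus permutation invariance, rejected-line no-ops and
idempotence). What it does not show: that the rules are *calibrated* —
real annotation files have correlated evidence (the same publication
feeding several lines), non-uniform level distributions, and conflicts far
rarer than 25%; the toy ECO is two levels deep, whereas the real ECO's
depth makes the subsumption typing rule coarser. Conclusions about real
corpora need the real ECO file (loadable via `parse_obo()`) and the
resource's own policy settings.

## Limitations

* Assigning the *single-evidence* level from raw experimental metrics is
  out of scope by design; the package starts from curated levels.
* Conflicts are detected only through the NOT qualifier by default;
  term-incompatibility conflicts (e.g. mutually exclusive GO terms)
  require a custom predicate.
* The OBO layer models `is_a` only — no OWL semantics, cross-ontology
  imports, or relationship types beyond subsumption.
* Confidence at the separate levels of experiment, author and curator
  interpretation is not modelled; the statement applies to the annotation
  as a whole.

## Problem sizes used in the shipped checks

The test suite enumerates all evidence multisets of size ≤ 4 over 24 line
kinds (~21,000 aggregations) for the oracle-equivalence property; the
acceptance script repeats the enumeration at size ≤ 3 (2,841 live cases)
and runs a 200-assertion synthetic file end to end. These sizes were
picked because the rule space is already covered exhaustively at group
size 4 — every branch (passthrough, congruent, weak, strong) and every
promotion combination occurs — so larger groups add runtime, not coverage.
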