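# ciotools

Tools for attaching and aggregating annotation confidence with the
Confidence Information Ontology (CIO).

## The problem

Biocuration resources attach evidence to their annotations (via the
Evidence and Conclusion Ontology, ECO), but confidence in that evidence is
recorded inconsistently or not at all: resource-specific star ratings,
gold/silver/bronze tiers, or nothing. The CIO provides a shared vocabulary
for confidence. A confidence statement is determined by five coordinates:

* **arity** — supported by a *single evidence* or by *multiple evidence
  lines*;
* **typality** — for multiple lines, whether the evidence types are the
  *same* or of *multiple types* (decided from the ECO `is_a` structure:
  two terms are the same type when one subsumes the other);
* **concordance** — *congruent*, *weakly conflicting* (one side of a
  positive/NOT contradiction is clearly better supported) or *strongly
  conflicting* (both sides' best evidence ties; no consensual conclusion,
  hence no overall level);
* **level** — `low < medium < high`;
* **rejected** — a tag for retracted or invalidated evidence, kept for
  traceability but never aggregated.

`ciotools` models these axes, maps them bijectively onto the 18 assignable
CIO leaf terms, and implements a configurable rule engine that derives one
summary statement per assertion from its single-evidence lines:

1. drop `rejected` lines;
2. a single surviving line passes through as its own statement;
3. otherwise decide typality over the ECO, and concordance from mixed
   polarity (the conflict predicate is pluggable);
4. a conflict is **strong** when `max level(positive) == max level(negative)`,
   else **weak** with the higher side winning;
5. the overall level is the side's maximum level, promoted one step for
   multi-type support and one step for at least `promote_count` congruent
   lines (both configurable), capped at `high`.

GAF 2.0-style gene association files (with a trailing confidence column)
and Bgee anatomical-similarity TSVs are read and written natively.

## Worked example

Two conflicting homology annotations of the autopod among Vertebrata —
positive and NOT, both medium-confidence traceable author statements:

```r
library(ciotools)
eco <- toy_eco()

autopod <- worked_example_bgee()
out <- summarize_annotations(autopod, eco)
out$confidence[out$line_kind == "SUMMARY"]
#> [1] "confidence statement from strongly conflicting evidence lines of same type"
```

Both sides' best evidence is `medium`, so the conflict is strong: the
summary carries no overall level and an empty qualifier.

Two congruent high-confidence GO annotations of ERG9 (sequence alignment
ECO:0000200 + mutant phenotype ECO:0000015 — different types) reach the
ontology's highest statement:

```r
erg9 <- aggregate_evidence(
  evidence_lines(c("positive", "positive"),
                 c("ECO:0000200", "ECO:0000015"),
                 c("high", "high")),
  eco
)
erg9$statement$id
#> [1] "CIO:0000012"
erg9$statement$label
#> [1] "confidence statement from congruent evidence lines of multiple types, overall confidence high"
```

A command-line interface is installed under `exec/`:

```sh
cio summarize --format bgee annotations.tsv annotated.tsv
cio validate  --format gaf  gene_associations.gaf
cio synth     --seed 42 synthetic.tsv
```

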