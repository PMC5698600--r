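---
title: "Electronic-Northern methods: model, thresholds and simulator design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electronic-Northern methods: model, thresholds and simulator design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enorthern)
```

## The measurement model

Expressed sequence tags (ESTs) are single-pass cDNA reads; the number of
ESTs attributed to a gene in a tissue's pooled libraries, normalized to
"transcripts per million" (TPM), is a coarse digital expression measure.
Two properties of this measure drive every design choice in this package:

* **Count quantization.** A tissue with a pooled library of roughly *N*
  ESTs can only produce TPM values near multiples of `1e6 / N`. The bundled
  45-gene milk-fat panel shows exactly this granularity (values 29, 59, 88,
  118, ... consistent with *N* near 34,000), which is why TPMs are modeled
  as integers and the reader rejects non-integer cells rather than rounding
  them silently.
* **Zeros are censoring, not expression.** A zero TPM usually means the
  tissue's libraries were too shallow to catch the transcript. A gene with
  a zero in any of the three compared tissues therefore has an *incomplete
  profile* and is `EXCLUDED` from classification rather than treated as
  evidence of absence. On the bundled panel this rule excludes exactly the
  23 genes its source flagged as incomplete.

## Statistics and threshold rules

With mammary, skin and muscle TPMs per gene, the package computes:

* **Percent mammary abundance**: `100 * TPM_ma / sum(TPM_ma)`, summed over
  *all* panel genes. Excluded genes still contribute mammary transcripts,
  so they stay in the denominator; the printed percentages of the bundled
  panel are consistent only with this convention (total mammary TPM
  10,642 over 45 genes).
* **Mammary/skin ratio**: reported only when both TPMs are positive. A
  zero mammary TPM makes the ratio trivially zero; following the reporting
  convention of the panel's source, such cells are left undefined rather
  than printed as 0.
* **Relative expression coefficient** `E_r = TPM_ma / sqrt(TPM_s * TPM_mu)`:
  the geometric mean makes the reference symmetric in the two control
  tissues and `E_r` scale-invariant — multiplying every TPM by a constant
  leaves it unchanged. It is defined whenever both reference TPMs are
  positive; a zero numerator gives `E_r = 0`.
* **Classification**: `UP` iff `TPM_ma > TPM_s` and `E_r >=` the up
  threshold (default 2); `DOWN` iff `TPM_ma < TPM_s` and `E_r <=` the down
  threshold (default 0.5); otherwise `NOT_DIFFERENTIAL`. The twofold
  default is a conventional significance-free cutoff, not a fitted value;
  both thresholds are inclusive and are compared on *unrounded*
  coefficients, so display precision can never flip a call. Skin, not
  muscle, appears in the guard comparison because mammary tissue is
  ontogenetically modified skin: the guard protects against calling a gene
  "mammary-preferential" when its expression is actually higher in the
  tissue mammary gland derives from, while muscle serves as a second,
  unrelated control inside the geometric mean.

Two cases the threshold rules leave open are resolved as follows and
treated as the package's documented defaults: a gene with `TPM_ma = TPM_s`
falls to `NOT_DIFFERENTIAL` whatever its coefficient (neither rule's strict
inequality holds), and a gene whose coefficient crosses one threshold while
its TPM comparison points the other way (e.g. `E_r = 2.6` with
`TPM_ma < TPM_s`, as for LASS2 on the bundled panel) is also
`NOT_DIFFERENTIAL`.

The adult/young stage comparison is provided as a generic operation
(`stage_preference()`, strict inequality by default, an optional fold
threshold) because stage-resolved TPMs are rarely published; the bundled
panel carries none, so the six-gene adult-preferential finding of its
source can be expressed but not reproduced here.

## Rounding

Derived values are reported to 3 decimals using round-half-away-from-zero
(`round_half_up()`), the convention of hand-prepared tables; base R's
half-to-even would disagree on boundary cells. All comparisons and the
conservation property (percent abundance sums to 100 before rounding) use
full precision.

## Network summarization

The network module deliberately contains no inference: it loads
STRING-style weighted edge lists (combined score plus per-channel evidence
scores, all in [0, 1]), merges duplicate and reversed pairs by elementwise
maximum, and offers purge-to-gene-set, degree ranking, isolated-node
detection, connected components and per-channel filtering. Hubs are ranked
by raw degree with alphabetical tie-breaking — the findings this style of
analysis supports are qualitative ("which genes are the major components"),
and no centrality measure is warranted by the data. The default combined
score cutoff of 0.4 is STRING's historical medium-confidence setting; it is
an explicit parameter everywhere, and an assumption, because the database
version this analysis style was developed against did not document its
default cutoff.

The bundled edge list `string_fixture_synthetic.tsv` is **hand-written and
synthetic**: the historical database release behind the original milk-fat
network is retired and cannot be exported. The fixture is shaped to
illustrate the qualitative structure that analysis found (two clusters
around PPARG and SREBF1/SREBF2 converging at FASN; SPTLC1 and XDH isolated
after purging to the 13 UP genes) and is used in examples and demonstration
tests only — graph-operation correctness is established against brute-force
oracles (adjacency counting and transitive closure) on random graphs, not
against this file.

## The simulator

`sim_config()` / `simulate_est_study()` emulate the sampling process behind
EST-profile TPMs: each tissue is a fixed-size multinomial draw over the
panel's true transcript proportions, and `TPM = round(1e6 * count / N)`.
Multinomial rather than Poisson sampling reflects that an EST library is a
fixed-size draw, and gives exact count conservation. Mammary proportions
are the base proportions times per-gene fold changes, renormalized; truth
labels follow the classifier's own thresholds (fold ≥ 2 is a true UP, fold
≤ 0.5 a true DOWN). Defaults are chosen to mirror the bundled panel's data
regime: 34,000-EST libraries (inferred from the panel's TPM granularity —
an inference, not a claim about the real libraries) reproduce the
coarse quantization of real values. Each replicate derives its own seed
from `(seed, replicate)`, so any replicate is reproducible in isolation.

What the generator does *not* model: sequencing error, clone-library
normalization bias, 3' sampling bias, or gene-length effects. Passing
recovery tests therefore show that the classifier behaves correctly under
idealized EST sampling noise at realistic depths — not that it is robust to
the technical artifacts of real EST libraries.

### Calibration design

The recovery claim asserted by the test suite is: at 34,000-EST libraries
and base proportion 0.01 per gene, genes with a mammary fold of 8 are
called UP in at least 95% of 200 replicates, and null genes in at most 5%.
The panel used is 100 genes at equal proportion 0.01 (so the proportions
sum to 1), 10 of them at fold 8. Renormalization then compresses the
effective mammary fold to `8 / 1.7 ≈ 4.7` for signal genes and `1 / 1.7 ≈
0.59` for nulls — comfortably beyond and below the twofold rule, so the
bounds measure classifier behaviour under sampling noise rather than
borderline effect sizes. At this depth a base-proportion gene receives
about 340 ESTs per tissue (about 3% relative sampling noise), which is why
the observed rates sit near 100% and 0% rather than near the bounds.

## Problem sizes

The test suite works at deliberately small scale: 1,000 random TPM triples
for the coefficient oracle, 20–30 random graphs of at most 12 nodes for
the graph oracles, 30 replicates per library size for the null-calibration
curve and 200 replicates of the 100-gene panel for the recovery bounds.
These sizes give Monte-Carlo error far smaller than the asserted margins
while keeping the whole suite in seconds.

## Known limitations

* The tissue set is fixed to the (mammary, skin, muscle) triple the
  coefficient is defined for; the reader remaps column names but not the
  tissue design.
* EST-profile TPMs lack exactitude as expression measures; differences in
  TPM track expression patterns only coarsely, and no statistical test or
  multiple-testing correction is attached to the twofold rule — by design,
  matching the method this package implements.
* The alias map (`gene_aliases()`) covers only the panel symbols that have
  changed; joining other historical panels to current interaction databases
  may need additional curation.
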