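---
title: "Permutation-based panel biomarker discovery: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Permutation-based panel biomarker discovery: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(permpanel)
```

This vignette is the package's own account of its statistical content: the
testing procedure and its assumptions, what the synthetic-data generator
does and does not emulate, the numerical and design choices that were
genuinely open, and the known limitations.

## The testing procedure

Each protein is tested for a case/control difference with a two-sample
statistic — by default the pooled-variance t. The null distribution is not
taken from the t distribution: plasma log2 intensities are demonstrably
non-normal (see the generator section), so the reference distribution is
built by permuting the group labels. The p-value is the proportion of
re-assignments whose statistic is at least as extreme in absolute value as
the observed one.

Three choices deserve explanation.

**Exceedance rule.** "At least as extreme" is implemented as `|T*| >= |T|`
rather than a strict inequality. Under the strict rule a completely
constant protein would receive p = 0, which is impossible for a valid
permutation p-value; under the `>=` rule the identity assignment always
counts, so exhaustive p-values are bounded below by 1/C(n, n1) and a
constant protein receives p = 1. A `rule = "strict"` flag reproduces the
literal strict reading for comparison. Numerically, the exceedance
comparison uses a relative tolerance of 1e-9 so that the identity
assignment and exact sign-flips are counted as ties despite floating-point
rounding.

**Plain proportion, optional smoothing.** The default p-value is the plain
proportion b/B. In Monte-Carlo mode this estimator can return 0 for
extremely differential proteins; an optional `(b+1)/(B+1)` smoothing mode
is provided for users who need strictly positive p-values, but it is off by
default because the plain proportion is the quantity the PFER/FDR
summaries below are defined against.

**Statistic choice.** The pooled-variance t is the default: it accounts for
per-protein variance while remaining a monotone transform of the mean
difference under equal group sizes and pooled spread, and it is the
conventional parametric comparator. `mean_difference` (scale-free in the
permutation sense but variance-blind) and `welch_t` are selectable.
Proteins with zero overall variance cannot support any t statistic and fall
back to the mean difference with a warning rather than failing the run.

Exhaustive enumeration is used automatically when C(n1+n2, n1) does not
exceed `n_perm`, and enumerates all assignments (complementary labelings
are not deduplicated — the p-value is identical either way and the
enumeration matches the natural definition). Monte-Carlo re-assignments are
independent uniform draws of the case subset, so repeats are possible;
draws are seeded (Mersenne-Twister via `withr::with_seed`) and the seed is
recorded in the fitted object.

## Error-rate summaries

At significance level alpha over m tested proteins, the package reports the
per-family Type 1 error rate `PFER = m * alpha` — the expected number of
false positives in the family — and the nominal false discovery rate
`FDR = PFER / k`, where k is the number of proteins declared significant.
These are deliberately simple, definition-level summaries; no
Benjamini–Hochberg or other stepwise procedure is applied, because the
pipeline's selection rule is a fixed per-protein threshold and the
summaries describe exactly that rule. With k = 0 the FDR is reported as
`NA` rather than 0.

Defaults mirror the intended use: `alpha = 0.001`, `n_perm = 100000`
(p-value granularity 1e-5, adequate to resolve the 0.001 threshold).

## The synthetic-data generator

The generator is the package's instrument for calibration and power
claims, so its model is fixed and documented. Log2 intensity of peptide k
of protein g in sample s is

    y = baseline + protein_g + sample_s + peptide_k + residual + effect

* `protein_g ~ N(0, 1.5)` — between-protein abundance spread;
* `sample_s ~ N(0, 0.3)` — sample-level (preparation) effects shared by all
  peptides of a sample;
* `peptide_k ~ N(0, 0.5)` — peptide ionization offsets, constant across
  samples (they cancel in group comparisons, as they should for a
  protein-level question);
* `residual` — by default a centred lognormal (shape 0.8 on the raw scale)
  scaled to unit standard deviation. This is the term that makes pooled
  log2 intensities right-skewed and Kolmogorov–Smirnov-rejectable as
  normal at realistic sizes, matching the observed behaviour of label-free
  plasma data; `normal` and a 90/10 scale-mixture alternative are
  available.
* `effect = ±effect_size` is added to the case samples of every peptide of
  a differential protein (all peptides of a protein shift together, since
  testing happens after rollup). The over-expressed count is
  `floor(n_differential * frac_overexpressed + 0.5)`.

Defaults emulate a two-batch plasma profiling design: 40 cases vs 40
controls, 1422 proteins observed through 1–6 peptides each (≈ 3.5 on
average, ≈ 5000 peptides), 254 differential proteins of which 208 are
over-expressed, and a 2 log2-unit effect. Missing values are **not**
generated by default; an optional missing-at-random fraction exists and is
honoured by the rollup (per-cell weight renormalization), but the
permutation engine requires a complete matrix, so missingness must be
resolved before testing.

What the generator does *not* emulate: peak detection and alignment noise,
intensity-dependent variance, batch drift within a study, peptide
sequences, and informative missingness. Passing tests on this generator
therefore demonstrate the statistical machinery — calibration of the
permutation null, power at a stated effect size, correctness of the
summaries — not robustness to every artifact of real LC-MS/MS data.

## Quantification choices

* **Zeros before log2**: replaced by half the smallest positive intensity
  in the table (messaged), a conventional floor that keeps the transform
  defined without imputing structure.
* **Quantile normalization** uses `limma::normalizeQuantiles(ties = TRUE)`;
  tied values within a column receive the mean of the rank-means they
  span. A single-sample table is returned unchanged with a warning.
* **Rollup weights**: equal by default. Inverse-variance weights (1 over
  the peptide's across-sample variance, normalized within protein) are
  offered for down-weighting noisy peptides; a zero-variance peptide's
  weight is floored at the reciprocal of machine epsilon. The full
  three-effect mixed model sometimes used for label-free quantification
  (group/sample/replicate) is deliberately simplified to this weighted
  rollup: the designs this package targets have no replicate injections,
  so the replicate stratum is empty and the weighted average is the
  remaining content of that model.
* **KS reference parameters** are estimated from the data by default
  (common practice; mildly anti-conservative) with a fixed-parameter mode
  for exact oracle checks; the p-value is asymptotic.

One interaction is worth knowing about. Quantile normalization forces all
samples to a common distribution. When differential effects are
direction-imbalanced (e.g. 82% over-expressed), case samples genuinely
have a shifted distribution, and normalization removes that shift —
which both attenuates true effects slightly and pushes every null protein
a little in the opposite direction. At a very strict alpha this can
promote null proteins with the counter-direction into significance. This
is a property of quantile normalization itself, not of the testing
machinery; with direction-balanced effects or without normalization the
null calibration is exact (and is verified on null data in the test
suite, where no planted shift exists).

## Panels, pathways, similarity

* Panel derivation intersects the significant set with reference sets;
  `rule = "any"` (membership in at least one reference) is the default,
  `"all"` requires membership in every reference. Identifier matching is
  case-sensitive and exact; an optional two-column mapping table supports
  cross-namespace joins. The panel is always a subset of the significant
  set and, under `"any"`, grows monotonically with added references.
* Enrichment is the one-sided (over-representation) hypergeometric tail;
  a two-sided variant delegates to `stats::fisher.test`.
  Pathways with no members in the universe are excluded with a warning.
* The protein-method similarity is the Jaccard index. Two empty sets are
  defined as identical (similarity 1). Reported percents are truncated
  toward zero (13/32 = 40.625% prints as 40%), and the raw fraction is
  always emitted alongside, so no information is lost to the display
  convention.
* The pathway-profile similarity is the Pearson correlation of two PPFCM
  columns; a constant column makes it undefined (`NA` with a warning)
  rather than silently 0. Pathway ranking breaks count ties
  lexicographically so ranks are reproducible.

## Pipeline and reproducibility

`run_pipeline()` executes simulate → quantify → test → panel → pathways →
similarity, writing every artifact as TSV/GMT text plus a JSON manifest
(configuration echo, package version, per-file MD5 checksums, stage
seeds, timestamps). Stage seeds are derived deterministically from the
single base seed (a fixed affine map modulo 2^31 − 1), so one integer
reproduces the entire run byte-for-byte; the manifest's checksums detect
any tampered intermediate. Stages are file-coupled, so re-running a stage
from a prior stage's outputs reproduces the end-to-end files exactly. The
CLI wrapper (`inst/cli/permpanel.R`) is a thin `optparse` layer over these
functions where flags override config keys.

## Verification strategy and problem sizes

The test suite checks every computational claim against an independent
route: exhaustive permutation p-values against direct enumeration with
`t.test`-based statistics; the KS statistic against a hand-rolled ECDF
scan; enrichment p-values against an explicit `choose()` tail sum; Pearson
scores against the definitional formula; Venn regions against brute-force
membership classification.

The simulation-based properties use sizes chosen to make the statistical
assertions sharp while remaining quick to verify: Type-I calibration on a
null 40 vs 40 study with 1000 single-peptide proteins and B = 10000
(rejection fraction within 3 binomial standard errors of alpha = 0.001);
planted-effect recovery on the full default design (1422 proteins, 254
planted, B = 10000, ≥ 90% recovery with directions preserved); Monte-Carlo
vs exhaustive agreement across all two-group layouts with at most 12
samples at B = 50000. For the last of these, note that a per-comparison
3-standard-error band applied to ~75 simultaneous comparisons will be
exceeded occasionally by a perfectly correct sampler, so the family-level
assertion allows the binomially expected number of mild exceedances while
bounding all deviations well below bug territory.

## Known limitations

* The permutation engine holds a proteins × permutations block in memory
  per chunk (chunked at 2000 permutations by default) and requires a
  complete matrix.
* Monte-Carlo p-values have granularity 1/B and can be exactly 0 without
  smoothing.
* No stepwise multiple-testing procedures; PFER/nominal-FDR only.
* Quantile normalization assumes most features are non-differential (or
  differential in both directions equally); see above.
* The generator's identifiers are opaque strings; nothing chemical is
  simulated.
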