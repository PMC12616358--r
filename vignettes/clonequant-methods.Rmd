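---
title: "Quantifying clonal tumor growth from barcode sequencing: models and methods"
author: "clonequant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying clonal tumor growth from barcode sequencing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonequant)
```

# The measurement problem

Tumor barcoding (Tuba-seq) initiates lung tumors with a pool of barcoded
Lenti-sgRNA/Cre vectors in Cas9-expressing mice. Every transduced cell
founds a clonal expansion uniquely tagged by an 8-nt sgID (identifying the
sgRNA, hence the targeted gene) followed by a 30-nt barcode cassette of the
form `GCNNNNNTANNNNNGCNNNNNTANNNNNGC`, in which the 20 Ns are random.
Amplicon sequencing of bulk tumor-bearing lung then measures, for every
clone, a read count proportional to its cell number. The package turns
those reads into calibrated per-clone cell numbers and into genotype-level
statements about how gene inactivation changes tumor initiation and
growth — including how those effects differ between cohorts (young versus
aged mice being the motivating design).

The chain of inference is: parse and error-clean barcodes, calibrate reads
to cells with spike-in benchmarks, remove cross-sample contamination,
admit samples and vectors that pass representation filters, select
titer-matched portions of each size distribution (adaptive sampling), and
summarize with relative size statistics under a nested bootstrap.

# Barcode processing

**Mate concordance.** Both mates of a read pair must yield an identical
sgID+cassette string; disagreeing pairs are dropped. This suppresses most
sequencing error before any modeling.

**Spurious-tumor collapse.** Residual errors create satellite barcodes
near genuine large clones. Within a sample (and within an sgID, since
sgIDs differ pairwise by at least three nucleotides), a record whose reads
are fewer than 5% of a record within Hamming distance two is merged into
it. The rule is applied greedily in descending read order; a small record
merges into the largest qualifying survivor, with ties broken toward the
lexicographically smaller barcode, and merged records cannot re-merge.
Read totals are conserved exactly. The comparison uses the 20 informative
positions by default (the fixed spacers carry no identity); a flag extends
it to the full 30-mer. An `O(n^2)` reference implementation is kept in the
test suite and the two are checked for equality on hundreds of random
instances.

**Spike-in calibration.** Three benchmark cell lines of `1e5` cells each
are added to every sample before lysis. Cells per clone =
reads x (total spike-in cells / total spike-in reads), pooled over the
three lines (a single minimum-variance factor); per-line factors are
retained for QC. Calibration is linear, so uniform rescaling of all read
counts leaves cell numbers unchanged.

# Cross-sample contamination model

Because each vector's barcode diversity is finite (set by the number of
bacterial colonies pooled during plasmid barcoding), the same sgID-barcode
can recur across mice by chance. Recurrence beyond chance indicates
contamination. Occurrences per barcode are modeled as Poisson with rate
`lambda`; only observed barcodes (k >= 1) are seen, so the observed mean
occurrence count `mu_nonzero` relates to the rate by
`lambda / (1 - exp(-lambda)) = mu_nonzero`. The solver inverts this map
with `uniroot` on an `expm1`-stabilized residual (tolerance 1e-10); the
identity `estimateLambda(forward(lambda)) = lambda` is property-tested on
a log-spaced grid from 1e-6 to 20.

The removal threshold `N_r` is the smallest integer containing 99.9% of
the recurrence distribution. We take the quantile on the *zero-truncated*
Poisson by default, because `mu_nonzero` is estimated from observed
(k >= 1) barcodes; the untruncated quantile is available
(`truncated = FALSE`) and the choice is recorded in the model object.
Barcodes in more than `N_r` samples are removed everywhere — unless a
single sample holds strictly more than 95% of the pooled reads, in which
case the barcode is kept in that dominant sample only (index hopping from
a very large genuine tumor). A share of exactly 95% is not rescued. The
filter is idempotent for a fixed model.

# Admission filters

Samples with fewer than 1,000 unique barcodes are treated as failed
transductions; vectors with fewer than 3,000 unique barcodes pooled across
the experimental cohorts are insufficiently represented (a Cas9-negative
control below 750 corroborates that the cause is pooling, not biology; a
well-represented control is flagged as a conflict but the vector is still
excluded, for manual review). All thresholds are strict "fewer than": a
count exactly at threshold is retained. `applyQcFilters()` takes both
decisions on tallies computed once, which makes the two filters exactly
order-commutative. The desk-scale demo configuration carries thresholds
scaled to its cohort size (100 / 300 / 75), preserving the 4:12:3
proportions of the full-scale defaults.

# Adaptive sampling

Comparing size distributions across cohorts is only meaningful on
equivalent portions — the same number of tumors per infectious unit of
virus delivered. Given a benchmark vector and cohort with `N_bench`
tumors, every other (vector i, cohort j) quota is

    N[i, j] = N_bench * (T_j / T_bench) * (p_ij / p_bench)

where `T_j` is the cohort's total delivered titer and `p_ij` the vector's
pool proportion, estimated from Cas9-negative control mice in which all
vectors are functionally inert. Quotas are integerized with banker's
rounding; the benchmark entry is exact by construction, and rebasing the
plan on any other vector with the consistently rescaled count reproduces
identical quotas and selections (asserted in tests).

Per-cohort quotas are split across mice proportionally to each mouse's
total tumor count (largest-remainder apportionment, ties to the first
mouse index), capped at availability with one redistribution pass. Within
each (mouse, vector) the quota-many largest tumors by cell number are
selected, ties broken by reads descending then lexicographic barcode — a
deterministic rule, so repeated runs select identical sets.

`benchmarkN()` implements the benchmark-count recipe — tumors of the
benchmark vector supported by at least five reads, rounded to the nearest
100 — with the rounding granularity configurable because desk-scale
synthetic cohorts hold hundreds rather than tens of thousands of tumors
(the demo pipeline rounds to the nearest 10). The benchmark is always
user-overridable for sensitivity analyses.

# Effect statistics

**LN mean.** Clone sizes are summarized by the maximum-likelihood mean of
a log-normal fit, `exp(m + s^2/2)` with the 1/n variance estimator (an
MLE, deliberately not 1/(n-1)). On adaptively sampled sets this statistic
integrates effects on both initiation (more tumors push larger tumors into
the top-N) and growth.

**Relative metrics.** Each vector's statistic (LN mean, or the size at the
50th-90th percentiles, linear-interpolation convention, `quantile`
type 7 — configurable) is divided by the *median* across the inert
vectors. Gene-level values are weighted averages over the gene's sgRNAs,
weights proportional to adaptively sampled tumor counts. Relative metrics
are invariant to global size rescaling; the absolute statistics are
scale-equivariant (both property-tested).

**Nested bootstrap.** Uncertainty propagates both mouse-to-mouse and
within-mouse variability: mice are resampled with replacement to the
cohort size, tumors are resampled with replacement within each selected
mouse to that mouse's count, and adaptive sampling is re-executed inside
every pseudo-dataset, so sampling variability flows into the intervals
(a flag could restrict resampling to the already-sampled set; re-running
is the conservative default). The default is B = 10,000 replicates; 95%
intervals are the 2.5th/97.5th percentiles, and two-sided p-values are
`2 * min(Pr(T > b), Pr(T < b))` with ties at the baseline split equally
and a floor of 2/B (no zero p-values). The baseline is 1 for ratio
statistics and 0 for young-minus-aged contrasts; contrast p-values are
Benjamini-Hochberg adjusted across genes within one metric.

The inner loop of the standard statistic (per-gene relative LN mean) is
compiled (`bootstrapRelativeLNMean()`); resampling is expressed as
per-tumor multinomial counts over size-sorted groups, so no per-replicate
sorting is needed. A pure-R `nestedBootstrap()` accepts any statistic
functional and serves as the reference: the compiled path's point
estimate is tested for exact equality with `relativeStats()`, and its
replicate distribution for agreement with the R path.

**scoreRGM.** An independent cross-cohort contrast based on geometric
means of matched top portions. For a cutoff L (500 cells) applied in the
aged cohort, a reduction factor R is fitted so that the median per-mouse
count of inert tumors above cutoff matches between cohorts when young
sizes are reduced by R — equivalently, young tumors are counted above the
adjusted cutoff L/R. With `N_L` aged inert tumors above L, `N_{LR}` young
inert tumors above L/R, and `p_X` the within-cohort ratio of sgX to inert
tumors above the cohort's cutoff,

    scoreRGM_X = log2( [GM(top p_X*N_L sgX, aged) / GM(top N_L inert, aged)] /
                       [GM(top p_X*N_LR sgX, young) / GM(top N_LR inert, young)] )

Zero under exchangeability; positive when X suppresses tumors more
strongly in aged mice. Note the direction convention: a shrink of aged
sizes to half of young fits R near 0.5 (sizes x R), and the label-swap
antisymmetry `score(aged, young; L/R, 1/R) = -score(young, aged; L, R)`
holds exactly. `p_X` is computed within the cohort being scored; a
pool-proportion-based alternative is a documented switch point.

*Fitting R.* The objective |median young count - median aged count| is
piecewise constant in R. Golden-section search is unreliable here: on
plateaus the usual `f(x1) <= f(x2)` elimination can discard the interval
containing the true minimum (we observed exactly this on a fixture where
the aged cohort was a copy of the young one). Because the young count is
monotone in R, the package instead bisects the monotone count difference
to its crossing and then resolves the minimizing plateau toward R = 1 (no
reduction) — an exact search. A 0.01-step grid search is retained as an
oracle and the two agree within one grid step on randomized tables.

**Distribution comparison.** `ecdfCompare()` selects each young sample's
top `N` tumors and each aged sample's top `round(N x titer ratio)` (so a
threefold titer gives threefold selection), pools them, and applies the
two-sided asymptotic Kolmogorov-Smirnov test (`ks.test`, `exact = FALSE`).

# The synthetic-cohort generator

The generator emulates the statistical structure the analysis assumes,
end to end:

* a vector pool with finite per-vector barcode diversity (default 5,000
  distinct 20-mers, standing in for bacterial-colony pooling), sgIDs
  separated by >= 3 mismatches, and three reserved spike-in barcodes
  outside all vector sets;
* per mouse and vector, tumor counts Poisson with mean
  titer x pool proportion x initiation rate x cohort multiplier (the
  generative law for tumor number is not dictated by the assay; Poisson is
  our choice and is recorded in the config);
* clone sizes as rounded log-normals with floor 1 (cell counts are
  integers), log-location set by an age baseline plus the log of a
  per-gene, per-age effect multiplier — multipliers are ignored in
  Cas9-negative cohorts;
* reads per clone Poisson around the clone's share of the sample depth
  (multinomial and exact-expected modes available; the expected mode
  round-trips through processing exactly), with per-base substitution
  errors on the 30-nt cassette and read-level cross-sample contamination,
  either uniform or concentrated in the single largest clone
  ("dominant" mode, exercising the >95% rescue rule).

The demo configuration (`demoConfig()`) is a titer-compensated two-cohort
design at desk scale: two cohorts of four mice, eight vectors (three
inert, five targeting four genes, equal pool proportions), aged mice
receiving a threefold higher titer with a 0.6 initiation multiplier and a
halved baseline clone size (log-locations log 20 and log 10 cells,
sigma = 2), depth 8e4 reads per sample. Those choices give roughly 600
tumors per young mouse and the low per-clone coverage regime of real
libraries, in which the >= 5-read benchmark support captures about half
of the benchmark vector's tumors.

What the generator does *not* emulate: PCR jackpotting and polymerase
errors beyond uniform substitutions, depth imbalance between sequencing
rounds, index-hopping lane structure, GC-content biases, or any biology of
tumor progression (clonal sweeps, subclonal structure). Passing tests
therefore demonstrate that the estimators recover the generative model's
truth under realistic sampling noise — not that real libraries satisfy
these assumptions.

# Calibration and recovery checks (problem sizes)

The acceptance suite runs, at fixed seeds:

* null calibration — 200 simulated two-cohort studies of 8 mice/cohort
  with all effect multipliers 1, bootstrap B = 1,000: per-gene 95% CIs for
  the relative LN mean cover 1 at a rate consistent with 0.95 (binomial
  99% bounds), and the age-contrast q < 0.05 rate stays at the nominal
  level;
* recovery — a 2.0x relative-LN-mean effect at 20 mice/cohort is
  estimated with |bias| below 5% of the effect and >= 90% CI coverage over
  40 replicates; an age-specific effect (3x in young only) at 12
  mice/cohort yields a significant positive young-minus-aged contrast and
  a negative scoreRGM in >= 90% of 50 replicates;
* exactness — noiseless round trips, oracle equivalences for collapse,
  the lambda solver, recurrence thresholds and R fitting, and the
  symmetry identities above.

These sizes are desk-scale by design; real cohorts (tens of mice, ~9e4
barcodes per mouse) pose no additional methodological difficulty, only
more rows.

# Numerical and degenerate-input conventions

* `lambda` solver: `mu_nonzero` within 1e-10 of 1 maps to `lambda = 0`
  (the truncated-mean limit); `mu_nonzero < 1` is a data error.
* `recurrenceThreshold(0)` is 1; thresholds are non-decreasing in lambda.
* LN mean of a single tumor is that tumor's size; zero or negative sizes
  are domain errors, not NA.
* Bootstrap replicates on which a statistic is undefined (an empty
  resampled stratum) are dropped from CI/p computation; if more than half
  of replicates are undefined the estimate is reported as a failure.
* Quotas exceeding availability truncate with a warning after one
  redistribution pass; selection ties are broken deterministically
  (cells, then reads, then barcode).
* All randomness flows from one root seed expanded per stage by a fixed
  affine scheme; identical config + seed reproduces byte-identical
  outputs, including bootstrap intervals.

# A worked run

```{r demo, eval = FALSE}
cfg <- demoConfig()
res <- runPipeline(cfg, opts = demoPipelineOptions(B = 1000L), seed = 3)
res$effects$young       # per-gene relative LN mean with CI, p, q
res$contrast            # young - aged differences, BH-adjusted
quotas(res$plan)        # titer- and proportion-scaled tumor quotas
```

# Known limitations

* The contamination model is per-vector and presence/absence based; it
  does not model lane-level index-hopping mechanics beyond the
  dominant-sample rescue, and cannot flag contamination that lands in
  fewer than `N_r` samples.
* Pool-proportion estimates inherit barcode-collision bias when diversity
  is low relative to tumor number (duplicate draws of one barcode in a
  mouse are indistinguishable and counted once).
* The compiled bootstrap covers the relative-LN-mean statistic; percentile
  metrics bootstrap through the slower generic path.
* Gene-level aggregation assumes sgRNAs targeting one gene are exchangeable
  up to sampling weight; discordant sgRNAs (off-target or inefficient
  guides) are visible only in the per-sgRNA attribute table.
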