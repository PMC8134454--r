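---
title: "Methods: epigenetic drift, passage clocks and read-pattern analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: epigenetic drift, passage clocks and read-pattern analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epidrift)
```

## Background and scope

Long-term culture of primary cells (mesenchymal stromal cells, fibroblasts,
endothelial cells) leaves continuous, highly reproducible DNA methylation
changes at specific CpG sites. Two views of this phenomenon are in tension:
a *targeted* model, in which an epigenetic writer is recruited to specific
loci and coherently modifies a CpG and its neighbors, and a *drift* model,
in which modifications accumulate stochastically and independently at
predisposed sites. The two models make different predictions at the level of
single sequenced molecules: a targeted writer produces block-methylated
epialleles and strong correlation between neighboring CpGs within reads,
whereas drift produces independent per-CpG states, vanishing neighbor
correlation, and growing pattern diversity with passage.

`epidrift` implements the computational machinery for both the biomarker
side (passage clocks) and the mechanism side (read-pattern, clonality and
hemimethylation analysis), plus generators that simulate data under each
model so every claim the package makes can be checked against a known
ground truth.

## The passage clock

The clock is a multivariable linear model on beta values (methylation
fractions in $[0,1]$):

$$\widehat{\text{passage}} = \beta_0 + \sum_i \beta_i \, b_i$$

The packaged `published_model()` is the four-CpG pyrosequencing predictor
bound to CpGs at *ALOX12* (cg03762994), *DOK6* (cg25968937), *LTC4S*
(cg26683398) and *TNNI3K* (cg05264232), with intercept 39.0341 and
coefficients $-10.9266$, $-0.4219$, $+5.8979$ and $-38.889$ passages per
beta unit. Two conventions matter:

* **Beta scale.** Inputs are fractions, not percentages. The coefficient
  scale forces this: a swing of 1.0 in the *TNNI3K* beta moves the estimate
  by about 39 passages. Pyrosequencing percentages must be divided by 100
  at ingestion.
* **No clipping.** Predictions are reported as-is; negative estimates are
  possible and meaningful as extrapolations (e.g. the all-ones input gives
  $-5.3055$).

`train_model()` refits clocks of this form by OLS, `best_subset_model()`
searches exhaustively over all combinations of `n_hyper` + `n_hypo`
candidate CpGs (default 2 + 2) for the minimum-RSS subset, and
`cross_validate()` runs repeated k-fold cross-validation (default 10x10).

### Reporting conventions

$R^2$ is reported as the squared Pearson correlation between predicted and
true passage, matching the predicted-vs-real scatter convention of clock
figures. Because publications do not always say which convention they used,
`evaluate_predictions()` also exposes `r2_explained` $= 1 - SSE/SST$. Fold
assignment shuffles sample indices with a user seed and splits them into
nearly equal folds, distributing the remainder to the first folds; metrics
are pooled over all held-out predictions of all repeats, so a report is
fully determined by `(data, cpgs, folds, repeats, seed)`.

## Preprocessing pipeline

The intended order is: chromosome filtering → kNN imputation → quantile
normalization → outlier test → correlation/selection. CpGs on chrX/chrY are
removed first because they confound donor sex with culture effects. Two
numerical choices are deliberate:

* **kNN imputation** (`knn_impute()`): the distance between CpG rows is the
  Euclidean distance over the columns observed in both rows; neighbors must
  be observed in the column being imputed; ties in distance break by row
  order; imputed values are clipped to $[0,1]$. The literature rarely
  states k or the metric for this step, so these defaults (k = 10) are
  package decisions, documented here rather than attributed elsewhere.
* **Quantile normalization** (`quantile_normalize()`): classical rank-mean
  normalization with ties receiving the mean of the tied ranks' reference
  values, making the transform idempotent; it refuses missing values
  rather than silently pairing imputation strategies.

The outlier test (`detect_outlier_samples()`) is the Bonferroni-adjusted
test on externally studentized residuals of the passage regression, via
`car::outlierTest()`. Note its edge case: on *exactly* linear data the
deleted-case variance is zero and the studentized residual is undefined, so
nothing is flagged; the test presumes residual noise.

## Amplicon read calling

Bisulfite amplicon reads are short and primer-defined, so the package
anchors each read by its forward primer (allowing C→T conversion at
reference cytosines plus one other mismatch) instead of genome-scale
alignment. This keeps calling deterministic and dependency-free. At each
CpG offset, `C` is called methylated, `T` unmethylated, anything else
missing. Bisulfite conversion is verified per read at the covered non-CpG
cytosines; reads with more than `max_mismatch_frac` (default 0.1)
unconverted positions are discarded and counted. Coordinates are 0-based
throughout, and a CpG is identified by the offset of its C on the top
strand.

## Pattern spectra and the single-read predictor

A sample's *pattern spectrum* is the frequency distribution of complete
epialleles (reads with no missing state); diversity is summarized by the
Shannon index $H' = -\sum_i p_i \ln p_i$ in nats, used both for DNAm
patterns and for clonal barcode composition. Reads with missing states are
excluded from spectra but still participate in likelihood-based prediction
— spectra need complete patterns, likelihoods do not.

The single-read predictor treats the states $x_i$ of one read as
independent Bernoulli draws with probabilities $m_i(p) = a_i + b_i p$,
where $(a_i, b_i)$ come from per-CpG regressions of sample-level methylated
fraction on passage in a training set. The log-likelihood

$$\ell(p) = \sum_i x_i \ln m_i(p) + (1 - x_i)\ln(1 - m_i(p))$$

is maximized over the integer grid $p = 0,\dots,50$; ties go to the
smallest passage. Probabilities are clipped to
$[\varepsilon, 1-\varepsilon]$ with $\varepsilon = 0.001$ before taking
logs — the floor is a package decision (sources for this model class do not
state one) and prevents a single incompatible CpG from annihilating a
read's likelihood. A sample-level estimate is the count-weighted mean of
per-read maxima. The per-read distribution is retained because read-level
heterogeneity is itself the observation of interest: under drift, early-
and late-passage samples both contain reads assigned across the whole grid,
with only the mean shifting.

For neighbor correlation, reads are pooled across the samples of a donor
set by default (a per-sample mode is available by passing single sets);
correlations are Pearson correlations of the binary state vectors, with
zero-variance CpGs flagged undefined rather than zero-filled.

## Hemimethylation from hairpin reads

Hairpin ligation joins the two strands of one molecule, so one read carries
both strands of each CpG dyad, and a UMI in the loop identifies PCR
duplicates. UMIs are grouped by the standard directional rule: an edge
$u \to v$ exists when the Hamming distance is at most 1 and
$\text{count}(u) \ge 2\,\text{count}(v) - 1$; clusters are reachable sets
from count-descending roots (ties broken lexicographically, making the
result input-order invariant). Consensus per cluster is the per-CpG,
per-strand majority, with exact ties set to missing. Hemimethylation at a
CpG is the fraction of informative molecules (both strands called) whose
strand states disagree. With a 10-nt UMI and $10^4$ molecules, a small
fraction of distinct true UMIs fall within Hamming distance 1 of each other
and are merged; this loses a few percent of molecules but does not bias the
per-CpG rates, which the tests verify against the generator's flip
probability.

## Reprogramming trajectories

For time courses, `signature_delta()` computes per timepoint the mean
absolute beta difference to day 0 — per donor first, then averaged across
donors, so donors with different baselines do not cancel. Trajectory
agreement between signatures is their Pearson correlation across
timepoints. Per-CpG univariate passage predictors (used for mean passage
estimates through a time course) are obtained by regressing passage on beta
in a training cohort — they are training-set artifacts, not published
constants, and signatures are user-supplied inputs since the external
age/pluripotency CpG lists are not redistributed here.

## The synthetic-data generators

`sim_config()` fixes all study conditions once; every generator is a pure
function of it, with per-component substreams derived from the root seed so
stages can be re-run independently and reproduce bit-exactly.

* **Cohort** (`simulate_cohort()`): 24 samples at passages 2–13 from two
  donors; 200 CpGs of which 10 + 10 drift at 0.02 beta/passage under
  Gaussian noise of 0.01 beta — a drift magnitude and noise level matching
  what array studies of culture expansion report for their selected sites.
  Betas are clipped to $[0,1]$. Note a structural consequence: at zero
  noise, every drifting CpG is an affine function of passage, so any two
  are exactly collinear and only single-CpG models are estimable — the
  noiseless limit is a test fixture, not a realistic cohort.
* **Reads** (`simulate_reads()`): per-CpG lines with $|b_i| \in
  [0.008, 0.015]$ per passage, hypermethylating CpGs starting low and
  hypomethylating ones high; 2000 reads/sample. The targeted-writer
  alternative draws a latent block state and flips each CpG independently
  with `writer_error` = 0.05. Probabilities are clipped to
  $[0.001, 0.999]$, mirroring the predictor's floor.
* **Clonal culture** (`simulate_clonal_culture()`): 100 founding clones
  with heritable patterns, 16-nt barcodes and RGB colour labels; each
  passage mutates patterns per CpG at 0.01 and resamples 10% of a
  10,000-cell population multinomially, which erodes clonal Shannon
  diversity the way serial bottlenecks do in barcoded cultures.
* **Hairpin** (`simulate_hairpin()`): bottom strands copy the top with
  per-CpG flip probability `hemi_rate` (default 0.05); 10-nt UMIs; PCR
  duplication with mean 4; per-base UMI error 0.005.
* **Time course** (`simulate_timecourse()`): all signatures share one
  logistic switch, $\beta(t) = s + (e - s)\,\sigma((t - t_0)/\tau)$ with
  $t_0 = 17.5$ days and $\tau = 2$, placing the transition between day 15
  and day 20; 3 donors, noise 0.01.

What the generators deliberately do **not** emulate: array probe noise
structure and batch effects, sequencing quality decay along reads, coverage
bias, non-linear (saturating) drift at extreme passages, and cell-type
mixtures. Tests passing on these simulations therefore validate the
*algorithms* under their stated models; they do not certify performance on
any particular real cohort.

## Problem sizes and determinism

The test suite runs the full property battery — including the $10^4$-read
neighbor-correlation contrast and the $10^4$-molecule hairpin recovery — in
well under a minute on one CPU; these sizes were chosen as the smallest at
which the binomial sampling bounds asserted by the tests are comfortably
inside their tolerances. All stochastic tests fix seeds through
`sim_config()` or `withr::with_seed()`, and generators restore the caller's
RNG state.

## Known limitations

* Primer anchoring assumes reads are oriented with the forward primer;
  paired-end merging and adapter trimming are upstream concerns.
* The single-read model assumes linear per-CpG drift and conditional
  independence of CpGs given passage; both are the *drift* hypothesis
  itself, so the predictor is diagnostic rather than assumption-free.
* The best-subset search is exhaustive at fixed subset size (2 + 2 by
  default); it does not search across sizes.
* `knn_impute()` is quadratic in CpGs with missing data and intended for
  the post-filtering scale, not whole-array matrices.
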