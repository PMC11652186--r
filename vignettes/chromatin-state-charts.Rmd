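---
title: "Control-chart classification of chromatin states from cfDNA fragmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Control-chart classification of chromatin states from cfDNA fragmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ocrchart)
```

## The monitoring view of chromatin accessibility

Cell-free DNA fragments survive plasma nucleases where nucleosomes
protect them, so along the genome their coverage, end positions and the
windowed protection score (WPS) trace the nucleosome landscape. Mapping
genomic position to a pseudo-time axis turns chromatin-state calling into
a statistical process control problem: closed chromatin (CCR) is the
in-control state, open chromatin (OCR) a known out-of-control state, and
partially open chromatin (pOCR) — a cell mixture in which only a fraction
of cells have the locus open — an undefined out-of-control state between
them. `ocrchart` implements this monitoring view in three stages: a
robust Hotelling T² chart that cleans a noisily labeled binary training
set, a sensitized T² chart that fuses chart and classifier probabilities
into a three-band decision rule, and a confident-learning/co-teaching
stage that refines the chart's labels into the final calls.

This vignette documents the model assumptions, the tunable parameters,
the synthetic data generator and its limits, and the numerical and design
choices a maintainer should know about.

## Stage 1: the robust Hotelling T² chart

Each 20-kbp interval (`segment_bp`) is tiled by 100 non-overlapping
200-bp windows (`window_bp`); per window the means of four per-base
tracks — WPS (window `wps_w` = 120 bp), coverage, 5′-end and 3′-end
counts — form one observation in `R⁴`. Windows of labeled-closed training
intervals supply the in-control sample.

**Why a robust estimate.** The training labels are wrong for a sizable
fraction of intervals, so the in-control mean and covariance would be
contaminated by genuinely open windows. The in-control model is therefore
a minimum regularized covariance determinant (MRCD) estimate: after
median/MAD standardization, the size-`h` subset
(`h = ⌈n(1 − alpha_trim)⌉`, `alpha_trim` = 0.25) minimizing the
determinant of `ρI + (1 − ρ)·c·S_h` is found by C-steps from six
deterministic starting scatters (identity, Spearman, tanh, quadrant,
normal-scores and shrunk-classical correlations); `ρ` is the smallest
grid value keeping the condition number at or below 50, and `c` is the
chi-square consistency factor. With `alpha_trim = 0` and `ρ = 0` the
estimate is exactly the classical mean/covariance, which the tests
exploit as an oracle. A one-step chi-square reweighting is available
(`reweight = TRUE`) but off by default: with moderately displaced
contamination (open windows near the reweighting cutoff) it re-admits the
outliers and inflates the scatter, which is precisely the failure the
robust chart exists to avoid.

**Control limit.** Following the scaled-F model of the statistic, the
out-of-sample T² distribution is summarized by its Monte-Carlo mean `m`
and variance `v` over `n_mc` simulated clean fits, and matched to
`E[T²] = dq/(q−2)` and `Var[T²] = 2d²q²(p+q−2)/(p(q−4)(q−2)²)`. These two
equations solve in closed form,
`q̂ = (2m²p − 4m² + 4vp)/(vp − 2m²)`, `d̂ = m(q̂−2)/q̂`, and
`UCL = d̂·F_{1−α}(p, q̂)` at `alpha = 0.05`. The family's variance floor
`2m²/p` is attained as `q → ∞` (a scaled chi-square); a pooled variance
at or slightly below the floor maps to that limiting member, and one far
below it raises an error, since no member matches. The printed variance
expression is the standard variance of a `d`-scaled `F(p, q)` variate;
moment matching is solved from the two moment equations directly, so the
algebraic grouping of the printed form is immaterial.

**Run rules.** Single-window alarms are upgraded to region calls by three
rules tailored to open-region geometry: (1) three or more consecutive
exceedances (600 bp at default windows — one alarm tolerance beyond the
docked two-window/400-bp open-region scale, absorbing one nucleosome of
noise); (2) a first- or last-window exceedance, called with its two
inward neighbours (600 bp) because an open region may straddle the
segment boundary; (3) two exceedance runs separated by fewer than three
sub-limit windows merge into one call, intervening windows included.
Overlapping calls merge and carry all contributing rule identifiers.
Open-labeled candidates are kept only if they overlap (≥1 bp, half-open
coordinates) a call; closed-labeled candidates only if they overlap none.

In the bundled pipeline each candidate is the central 2 kbp
(`candidate_bp`) of its 20-kbp monitored segment — a gene/TSS-scale
region inside a larger monitored interval — so one spurious alarm
elsewhere in the segment does not overturn a closed label.

## Stage 2: the sensitized T² chart

The chart monitors one summary vector per interval: the population
standard deviations of the windowed WPS and coverage means
(`sd_wps`, `sd_coverage`). Structured chromatin fluctuates strongly
across windows; open chromatin is flat, so these dispersions order the
three states.

Two probabilities are fused. The MEWMA statistic
`Z_i = λ(X_i − X̄_IC) + (1−λ)Z_{i−1}`, `T² = Z′S_Z⁻¹Z` with
`S_Z = λ/(2−λ)·S_IC` and `Z₀ = 0` (each query interval is one incoming
observation, so the default is a single recursion step per interval; a
sequence mode exists for ordered windows) maps onto `(0,1)` through
`pT² = σ((T² − BD)/BD)`, where `BD` is the mean over `B` bootstrap
resamples of the `1−α` quantile of the in-control statistics — so
`pT²(BD) = 0.5` exactly. The classifier probability is `pC = σ(θ)` with
`θ` the model's raw score. The fusion

`ST² = η·δ·pT² + (1 − η·δ)·pC`, with `δ = 2|pC − ½|`,

gates the chart's weight by the classifier's decisiveness: an uncertain
classifier hands the decision entirely to its own `pC = ½`; a decisive
one still cedes weight `η·δ` to the chart. `η` defaults to 0.3; values
`≥ 0.7` trigger a warning because the partially-open band `(CL, 1−η]`
then collapses into the region where in-control statistics live, and
partially open calls become unreliable. Bands are closed on the left
boundary of the closed state: CCR for `ST² ∈ [0, CL]`, pOCR for
`(CL, 1−η]`, OCR for `(1−η, 1]`. The control limit is the bootstrap mean
of the `1−α` quantile of in-control `ST²` values, multiplied by the
mixture ratio `τ` when known (default 0.7); the un-adjusted limit is used
when `τ` is not supplied. Calibration errors out if the adjusted limit
leaves no partially-open band.

**The classifier behind `pC`.** The default architecture is a robust
generative one: each class is a shrinkage-regularized Gaussian fitted
with small-loss trimming (after a warm-up fit, the samples with the
largest negative log-likelihood under their own class — the likely
mislabeled ones — are dropped and the class refitted; the trimming
fraction is `forget_rate`). `θ` is the log posterior odds, so the score
stays calibrated for observations off the binary training manifold:
a τ-mixture that resembles neither pure class receives an uncertain or
closed-leaning score rather than a saturated one, which is what routes
partially open intervals into the middle band. Discriminative softmax
("linear") and one-hidden-layer ("mlp") networks trained by Adam with
warm-up plus small-loss sample selection are available for comparison;
a purely discriminative boundary between two well-separated classes
saturates `pC` for anything on the open side of mid-gap, which collapses
the middle band — the reason the generative score is the default.
Training hyperparameters: Adam, batch 128, 150 epochs with 10 warm-up
epochs, and evaluation metrics averaged over 5 seeds. The learning rate
defaults to 0.05, sized for these compact models on standardized
features (a rate suited to a deep sequence model would leave them
unconverged within the epoch budget).

## Stage 3: confident learning and co-teaching

The chart's three-class labels still contain mistakes (leaked in-control
intervals in the middle band, borderline mixtures in the open band).
Cross-validated class probabilities — out-of-fold, so free of
self-confirmation — feed the confident joint: per class `j` the threshold
`t_j` is the mean predicted probability of `j` among samples observed as
`j`, each sample is assigned to the most probable class among those
reaching their thresholds, and the (observed, assigned) counts estimate
the joint of noisy and true labels. Samples in off-diagonal cells are
pruned (a single pass; the three-step estimate/prune/reweight procedure
is not iterated), classes are reweighted by inverse retained frequency,
and two peer softmax networks are co-taught: after warm-up, each network
ranks samples by its own loss and its peer updates on the small-loss
subset, with keep rate `r(e) = 1 − min(noise_estimate, 0.3)·min(1,
(e − warmup)/10)`. The pipeline passes a small residual noise estimate
(post-pruning), so co-teaching forgets little of the already-cleaned
data. Final predictions average the two networks' probabilities; exact
ties break to the lowest class index for determinism.

The refinement model sees `(sd_wps, sd_coverage, ST²)` — the raw summary
features plus the chart's own evidence, the compact analogue of a final
model consuming rich encodings alongside the chart output. With only the
raw summaries the refinement can fall below the chart it is meant to
refine, because the pruned-label geometry is less separable than the
band rule that produced it.

## The synthetic data generator

`sim_params()` encodes the generative model the charts assume:

- **Closed state:** one nucleosome per `period_bp` = 190 bp; fragment
  midpoints Gaussian around the dyads (`placement_jitter_bp` = 20);
  lengths normal 167 ± 15 bp truncated to [100, 400] (mono-nucleosomal
  cfDNA). Per-nucleosome depth is `depth_ccr` = 114 fragments modulated
  by a smooth log-normal occupancy field (CV `occupancy_sd` = 0.2, AR(1)
  autocorrelation `occupancy_phi` = 0.9 across nucleosomes, i.e. a ~2 kbp
  correlation length). The depth corresponds to ~100× coverage — the deep
  cfDNA sequencing regime this kind of monitoring assumes; at shallow
  depth the per-window open-region signal sits inside counting noise and
  no chart can see it. The occupancy field reproduces the domain-scale
  coverage waviness of real data; it is also what survives, attenuated by
  `1−τ`, in partially open mixtures and makes them distinguishable from
  fully open regions in the dispersion summaries.
- **Open state:** uniform fragment placement with expected per-base
  coverage `ocr_depletion` = 0.3 of the closed state's (fragment counts
  scaled by the length ratio so the *coverage* ratio equals the
  depletion), and shorter fragments (100 ± 20 bp, truncated at 60):
  open chromatin is nuclease-hypersensitive and yields sub-nucleosomal
  fragments, which raises end-density relative to coverage and drives
  the WPS negative — the off-axis signature that lets the robust chart
  separate genuine openness from ordinary depth fluctuations.
- **Partially open:** the element-wise convex combination
  `τ·OCR + (1−τ)·CCR` of an open and a closed feature matrix (τ = 0.7 by
  default), with a random binary observed label, mirroring how such
  regions enter binary training sets. A fraction `noise_rate` (default
  0.2) of the open/closed observed labels is flipped.

What the generator does **not** emulate: sequence content, GC and
mappability bias, tissue-of-origin mixtures across loci, real nucleosome
positioning heterogeneity, or open regions embedded sub-segment-scale in
closed background. Passing tests therefore demonstrate that the charts,
filters and refinement behave as designed under the stated statistical
structure — not that the pipeline's absolute accuracies transfer to real
cfDNA sequencing data.

## Numerical choices and degenerate inputs

- All featurization is deterministic; coordinates are 0-based half-open
  (BED), the 3′-end signal uses `end − 1` as the last covered base, and a
  candidate abutting a call shares no base with it.
- A trailing partial window is dropped with a message; "sliding" windows
  are non-overlapping tiles (stride = width), which makes exactly 100
  windows per default segment.
- Population (divide-by-`n`) standard deviations in the summary vector,
  fixed for reproducibility.
- The classifier score is clamped to ±30 before the sigmoid so `pC`
  stays strictly inside (0, 1) in double precision.
- Degenerate inputs error early: constant variables in the MRCD fit,
  `n ≤ p`, singular smoothed covariance, single-class training data, a
  pruning pass that would empty a class, an adjusted control limit at or
  above `1 − η`.
- Every stochastic step (simulation, Monte-Carlo calibration, bootstrap,
  network initialization, fold assignment, co-teaching shuffles) derives
  from a single root seed through a fixed integer scheme; identical
  seeds give byte-identical pipeline artifacts.

## Problem sizes used by the test-suite

The acceptance-style checks calibrate the robust chart at `p = 4`,
`n = 500` with 500 Monte-Carlo replicates and measure the false-alarm
rate on 10,000 fresh in-control observations pooled over 20 independent
fits (the pooled rate is the unconditional quantity the calibration
targets). Pipeline-level checks run 40 open / 80 closed training
intervals, 40 test intervals per class, `n_mc = 200`, `B = 200` and
40-epoch classifier training, repeated over seeds (5 for the
noise-robustness ordering, 3 per mixture ratio for the τ-stability
check). These sizes were chosen as the smallest at which the measured
quantities are stable across seeds; the generator's scientific
parameters are never scaled down with them.

## Known limitations

- The MRCD scale uses MAD rather than a pairwise robust scale in the
  standardization step; for heavily skewed marginals a pairwise scale
  would be preferable.
- The control-limit calibration simulates Gaussian in-control data; on
  the synthetic cfDNA features (log-normal occupancy field) the realized
  per-window false-alarm rate is somewhat above nominal, which the
  candidate-region design absorbs.
- The middle band inherits the mixture-ratio adjustment `CL·τ` verbatim;
  no alternative adjustment functions are explored.
- `η` is configuration only; there is no automatic selection, and values
  ≥ 0.7 are warned against rather than forbidden.
- Three-class separation weakens as τ approaches the open state
  (mixtures at τ ≥ 0.8 resemble fully open intervals), which bounds the
  flatness of accuracy in τ.
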