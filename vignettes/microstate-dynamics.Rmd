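---
title: "EEG microstate dynamics with microdyn: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEG microstate dynamics with microdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microdyn)
```

## The model

Resting-state EEG does not wander continuously through topography space:
the scalp potential field tends to remain quasi-stable in one of a small
number of stereotypical configurations for tens of milliseconds and then
switch abruptly. These transiently stable topographies are called
*microstates*, and their temporal statistics — how long each state dwells
(duration), how often it recurs (occurrence), what share of time it covers
(coverage), and which state follows which (syntax) — are sensitive markers
of large-scale brain dynamics in health and dementia.

The analysis chain microdyn implements is the standard one:

1. **Global field power (GFP).** At each sample the GFP is the spatial
   (population) standard deviation of the average-referenced signal over all
   electrodes. Topographies at GFP local maxima have the best topographic
   signal-to-noise ratio, so clustering is restricted to maps at GFP peaks.
2. **TAAHC clustering.** The topographic atomize-and-agglomerate
   hierarchical clustering starts with every GFP-peak map as its own
   cluster, repeatedly *atomizes* the worst cluster — the one whose members
   correlate least with their own centroid (lowest summed |spatial
   correlation|) — and reassigns each freed map to the surviving cluster it
   correlates with best. Because the cluster count shrinks by one per step,
   a nested solution is recorded at every k. Under polarity invariance (a
   map and its negation are the same state, the resting-state convention)
   the cluster template is the first principal component of the member
   maps; fit quality is the global explained variance
   \(GEV = \sum_t (GFP_t r_t)^2 / \sum_t GFP_t^2\),
   with \(r_t\) the spatial correlation of map *t* to its template.
3. **Choice of k.** A bank of cluster-validity criteria (normalized
   Krzanowski–Lai, the cross-validation criterion, and a dispersion-elbow
   ratio) each vote an optimal k over 1–12; the median vote wins, ties
   going to the smaller k. At the cohort level the per-subject optima are
   summarized by their (lower) median.
4. **Group maps.** Subject templates have arbitrary class labels and signs,
   so group averaging aligns subjects by the label permutation (and sign
   flips) that maximize total |spatial correlation| with the running mean
   maps, iterating to convergence.
5. **Back-fitting.** Group maps are fit back to each subject: every GFP
   peak takes the label of the template with the highest |spatial
   correlation|, and samples between consecutive peaks are interpolated with
   the boundary halfway between the peaks. Runs touching an epoch boundary
   are potentially truncated and are excluded from the temporal statistics.
   A robustness mode labels *all* samples independently instead.
6. **Statistics.** Transition probabilities are compared with an
   independence-expected matrix and tested by a run-shuffling randomization
   test; topographies are compared across groups and classes by TANOVA
   (randomization on global map dissimilarity); spectral summaries (Welch
   dominant frequency in 4–15 Hz, band powers) and sliding-window dynamic
   functional-connectivity variability are computed for correlation with
   the microstate metrics, with FDR (or Bonferroni) multiplicity control.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| band-pass before segmentation | 2–20 | Hz | the conventional microstate band; a 0.3–54 Hz Butterworth (order 2, zero-phase) is used as the acquisition band |
| epoch length / count | 2 s / 30 | — | fixed analysis grain; subjects with fewer than 30 clean epochs are excluded |
| k search range | 1–12 | classes | the standard meta-criterion range |
| polarity invariance | on | — | resting-state convention (canonical classes A–D imply it) |
| GFP | population SD | µV | all electrodes are the population |
| dFC window / step / taper σ | 22 / 1 / 3 | volumes | the common sliding-window convention; configurable and logged |
| transition shuffles / TANOVA permutations | 1000 | — | add-one permutation p-values, never exactly 0 |

## What the synthetic generator emulates — and what it does not

`simulateMicrostateEEG()` plants K average-referenced, unit-RMS template
topographies (smooth Gaussian random fields over a synthetic sensor disk),
switches between them with geometric (memoryless) run lengths of a stated
mean dwell, multiplies the active template by a sinusoidal carrier (so GFP
peaks twice per carrier cycle, as the microstate model assumes), and adds
spatially white, average-referenced Gaussian noise at a stated
template-RMS-to-noise-RMS ratio. `simulateCohort()` shares templates across
subjects and plants group dwell differences; per-subject seeds derive
deterministically from one master seed. `simulateNetworkTimecourses()`
draws zero-mean Gaussian volumes whose covariance is that of the currently
active state, with geometric state dwells — connectivity that genuinely
switches over time.

This suffices to give every pipeline stage a recovery test with known
ground truth, but it is deliberately not a forward model: there are no
cortical sources, no volume conduction, no blinks or EMG, and the
within-state amplitude dynamics of real EEG are not characterized by an
amplitude-modulated sinusoid — that choice is a stand-in. Passing the
recovery tests shows the *estimators* are correct and calibrated, not that
real recordings satisfy the generative assumptions.

## Numerical choices and tie rules

- **Peak detection.** Strict local maxima; a flat plateau flanked by lower
  values contributes its left-center sample; series endpoints are never
  peaks.
- **Interpolation boundary.** For peaks p < q the later run starts at
  `ceiling((p + q) / 2)`: the exactly-halfway sample of an even gap belongs
  to the later peak. Stated once, used everywhere.
- **Truncation.** The first and last run of every epoch are flagged
  potentially truncated and excluded from duration/occurrence/coverage.
  With analysed time defined as the assigned, non-truncated time, the
  bookkeeping identity duration × occurrence = coverage × 1000 holds
  exactly per class.
- **Normalization.** Maps are unit-GFP normalized before clustering and
  back-fitting (whether the original analyses normalized is not knowable
  from the methods available to us; correlation-based matching makes most
  steps scale-free anyway, and TANOVA p-values are invariant to global
  scaling by construction).
- **Worst cluster in TAAHC.** Lowest summed member-to-centroid
  |correlation|, ties to the earliest-created cluster; this follows the
  algorithm's originating description.
- **Degenerate inputs.** Zero-variance maps cannot be correlated or
  normalized and raise errors rather than propagating NaN; dFC windows with
  a zero-variance segment yield NA (never silently zero), and variability
  fails when more than 10% of a pair's windows are undefined.

## Known measurement biases (by design of the method)

Peak-interpolated segmentation can place run boundaries only on the GFP
peak grid, which has 2 × carrier frequency points per second. With a
realistic ~10 Hz alpha carrier the grid spacing is ~50 ms, so geometric
dwells of ~80 ms are substantially quantized: runs shorter than the grid
are absorbed into their neighbours and mean duration is biased upward
(by roughly 30 ms in that regime). This is a property of the method, not an
implementation defect — it is why the duration-recovery validation uses a
dense 40 Hz carrier at 512 Hz sampling (grid 12.5 ms), where recovery of an
80 ms dwell is within a few ms. Conversely the all-samples fitting mode is
exact at infinite SNR but splits runs near carrier zero crossings at any
finite SNR (the local SNR goes to zero there), biasing durations downward.
Group *contrasts* in duration are robust to the shared quantization bias:
the planted 65 vs 77 ms cohort separates correctly under the default
peak-interpolated pipeline.

## Design decisions in genuinely open territory

- **Meta-criterion composition.** The exact criterion bank of published
  meta-criteria varies; we implement a configurable bank (normalized
  Krzanowski–Lai, cross-validation criterion, dispersion elbow) with a
  median vote and ties to smaller k, and validate it by planted-k recovery
  (≥ 18/20 across k ∈ {3,…,6} at low noise).
- **Transition-randomness null.** We shuffle run order within epochs
  (exactly preserving per-class run counts), merge adjacent same-class runs
  arising from a shuffle, and use an independence chi-square sum as the
  global statistic; calibration under independent syntax is itself part of
  the validation suite (rejection rate within the binomial band at α = 0.05).
- **TANOVA internals.** Effect size is the sum over factor levels of the
  global map dissimilarity (RMS difference of unit-GFP maps) between
  level-mean and grand-mean maps; group labels permute across subjects,
  class labels within subjects, and the interaction permutes residual maps
  after removing both main effects (residuals compared by raw RMS —
  re-normalizing near-zero residual maps is unstable). The group-effect
  permutation distribution is computed with a single matrix product, so
  null-calibration experiments over hundreds of simulated datasets run in
  seconds.
- **Connectivity measure.** Windowed Pearson correlation with a
  Gaussian-tapered rectangle (σ = 3 volumes), not regularized precision;
  an optional Fisher-z transform is exposed. The single full-length window
  reproduces the static correlation exactly.
- **Interface.** The package's functions, `runPipeline()` and this
  vignette are the interface; readers/writers cover delimited matrices with
  JSON sidecars and a minimal 16-bit EDF implementation for EEG
  round-trips.

## Validation problem sizes

The validation suite runs entirely on synthetic data generated at test
time: cohorts of 4–20 subjects with 64-channel, 256–512 Hz recordings of
60 s (30 two-second epochs) per subject; TAAHC on ~1200–1700 GFP-peak maps
per subject; 500 simulated datasets × 1000 permutations for TANOVA null
calibration; 200 simulated sequences × 199 shuffles for transition-test
calibration; and 10-seed replications for every recovery claim. These sizes
were chosen so each property is measured with useful Monte-Carlo precision
while the whole suite remains quick to run.

## Limitations

- The generator's geometric dwell law and AM-sinusoid carrier are
  idealizations; real microstate dynamics may have heavier-tailed dwell
  distributions and broadband carriers.
- The meta-criterion bank and the transition/TANOVA nulls are principled
  reconstructions of analyses whose original definitions live in
  software or supplements not available here; they are validated by
  calibration and recovery, not by numerical identity to any particular
  implementation.
- Printed clinical effect sizes from patient cohorts (group duration
  tables, clinical correlations) require the original recordings and are
  out of scope; the package validates the *machinery* on planted ground
  truth instead.

## A worked example

```{r example, eval = FALSE}
co <- simulateCohort(c(5, 5), c(65, 77),
  nChannels = 64, k = 5,
  durationS = 60, snr = 2, seed = 1
)
res <- runPipeline(co, microdynConfig(kMode = "fixed", k = 5, seed = 1))
res$table[, c("id", "group", "gev", "meanDurationMs")]
tanova(
  array(unlist(lapply(res$models, templates)), c(64, 5, 10)),
  res$table$group,
  nPerm = 1000, seed = 1
)$p
```
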