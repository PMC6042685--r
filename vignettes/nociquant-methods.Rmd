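---
title: "Quantification methods for larval nociception experiments"
author: "nociquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantification methods for larval nociception experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nociquant)
```

nociquant implements the measurement and statistical procedures used in
Drosophila larval nociception work: quantifying nuclear pMad (the activated
BMP-pathway transcription factor) in nociceptor cell bodies, measuring the
size and segmental layout of single-neuron axon terminal arbors, analyzing
GCaMP calcium responses of nociceptor terminals to a slow thermal ramp, and
the nonparametric statistics used for nocifensive-behavior data. This
vignette documents the models behind each pipeline, the tunable parameters
and their defaults, what the synthetic-data generators do and do not
emulate, and the numerical choices made where the procedures leave freedom.

## Nuclear pMad quantification

BMP signaling activity in a nociceptor is read out as the nuclear
immunofluorescence level of phosphorylated Mad. The measurement model per
neuron is:

1. The confocal Z-stack is collapsed to a **maximum intensity projection**
   per channel.
2. The nucleus is delineated as a region of interest. Nuclei are located as
   the *GFP-negative hole*: nociceptors express a membrane GFP marker, so
   the nucleus appears as a dark region fully enclosed by cytoplasmic GFP.
   `segment_nucleus()` automates this (Otsu threshold on the GFP
   projection, then the largest enclosed background component), but manual
   masks are first-class inputs — recovery analyses use ground-truth masks
   so that segmentation error never contaminates quantification error.
3. `raw_nuclear_mean` is the mean pMad intensity over the ROI.
4. The **four-corner background**: the ROI mask is translated, shape and
   size preserved, so its bounding box sits `margin_px` (default 2 px) from
   each image corner; the background estimate is the mean of the four
   corner-ROI means. For any background field that is linear in the image
   coordinates, the four-corner mean equals the field's value at the image
   center, so the estimator is exact for a centered nucleus over a linear
   gradient.
5. `corrected = raw_nuclear_mean - background`. Corrected values may be
   negative and are recorded as-is; the statistic is a difference of means
   and clipping would bias it.
6. **Normalization to co-processed controls**: specimens stained in the
   same solutions share a `batch_id`, and
   `percent_change = 100 (mean_exp - mean_ctrl) / mean_ctrl` is defined
   only within a batch. Pairing across batches is refused rather than
   silently pooled, because staining intensity is only comparable within a
   batch. `corrected` is invariant to any global additive offset, and
   `percent_change` to any global gain applied to both groups — the two
   nuisances a staining batch introduces.

The imaging design samples three ddaC neurons (segments A4–A6) per animal;
`aggregate_by_animal()` averages neurons within an animal before group
statistics (avoiding pseudo-replication), with `unit = "neuron"` available
to match per-neuron sample sizes where those are the published unit.

## Axon terminal morphometry

Single nociceptor axon terminals are labelled by stochastic flip-out
clones (GFP) against a pan-nociceptor CD2 neuropil label. The terminal
area statistic is:

- maximum projection, then **Otsu binarization** of GFP and CD2
  independently;
- `normalized_area = gfp_pixels / (cd2_pixels / n_neuromeres)` — the
  arbor's area in units of one average neuromere, which cancels
  specimen-to-specimen differences in nerve-cord size. The neuromere count
  is a per-image annotation (it is counted in the cropped image), never
  inferred.

Otsu's method operates on a 256-bin histogram regardless of bit depth
(16-bit intensities are rescaled into 256 bins), which keeps the classic
formulation stable on sparse 16-bit histograms. Foreground is *strictly
greater than* the threshold and variance ties break toward the smallest
threshold; neither convention is forced by the method, so both are pinned
here and enforced by an exhaustive-search oracle in the tests. Channels
that cannot be binarized (a single occupied histogram bin, typically from
too-low expression) mark the clone **excluded** rather than quantified;
the one exception is an identically zero GFP channel, which is a valid
measurement of zero terminal area. For low-expression specimens,
`match_enhance()` applies a pure gain so the source's upper-decile mean
matches a control reference — the matching statistic behind "linear
enhancement" is not standardized anywhere, so the upper-decile mean is
this package's documented choice: it tracks foreground brightness while
ignoring the background mode, and a pure gain is monotone, so it can never
reorder pixels.

Projection layout is summarized from manual presence/absence annotations
per (neuromere, longitudinal tract). Because clones enter the nerve cord
at different segments, profiles are aligned on the **entry neuromere**
(offset 0) before aggregation; the heat map reports the percentage of
clones with a branch at each (offset, tract) position, computed over
non-excluded clones.

## Calcium imaging against a thermal ramp

Nociceptor terminal activity is recorded as GCaMP fluorescence while a
probe ramps at 0.1 °C/s from bath temperature (~25 °C) to 50 °C. The
pipeline per animal:

1. `roi_trace()`: per frame, maximum projection of the 10–11-slice Z-stack,
   then the mean over a circular ROI of diameter 6 px centered on the
   annotated neuromere centroid. ROI membership is "pixel center strictly
   within radius 3.0" so pixel counts are reproducible.
2. `dff()`: \(F_0\) is the mean of the first 30 frames (~7.5 s at 4 Hz,
   within the pre-ramp hold), and \(\Delta F/F_0 = 100\,(F - F_0)/F_0\).
   \(\Delta F/F_0\) is invariant to camera gain by construction.
3. `interpolate_temperature()`: camera and thermocouple run on separate,
   unsynchronized clocks; each frame's probe temperature is linearly
   interpolated between the bracketing 4 Hz log samples, with endpoint
   hold outside the log's span (the ramp is slow, so held edges introduce
   at most a fraction of a bin).
4. `bin_by_temperature()`: bins are \([k, k+1)\) °C anchored at integers
   and labelled by the anchor \(k\); empty bins are missing, never zero.

Group comparison (`compare_binned_groups()`) runs a two-sided
Mann-Whitney U test per bin on per-animal binned means — animals, not
frames, are the statistical unit. The default reports raw per-bin
p-values, the convention figures annotate; `adjust = "bonferroni"`
controls the familywise error across the tested bins and is the
appropriate form for claims that a response differs *only* within some
temperature range, since with ~25 bins an uncorrected 5% test yields at
least one spurious bin in roughly a third of null experiments.

## Behavioral statistics

Nocifensive escape locomotion is scored either as a latency (stimulation
ceases at 11 s; non-responders carry the cap value and a censored flag) or
as a binary response to a fixed optogenetic stimulus. Summaries are mean ±
SE, with censored latencies included at face value (the field's reporting
convention) and binomial SE \(\sqrt{\hat p(1-\hat p)/n}\) for proportions.

- `mann_whitney_u()`: mid-ranks throughout, so stacks of censored 11 s
  values form ordinary tie blocks. The p-value is exact (via the null
  distribution of U) when the pooled sample size is ≤ 20 and tie-free,
  otherwise a tie-corrected normal approximation with continuity
  correction. Treating censored values as ties at the cap is a documented
  limitation, not a survival model: rank tests tolerate the resulting tie
  block, and the studies' own analyses used rank tests, not
  censored-data models.
- `steel_test()`: the many-to-one rank analogue of Dunnett's test. Each
  group is compared with the shared control by a standardized two-sample
  rank sum \(T_j\); named implementations of this test differ in how they
  control the family, so this package *defines* its reference as a seeded
  joint permutation: all observations are relabelled, \(\max_j |T_j^*|\)
  is recomputed per resample (tie-corrected standardization included), and
  the adjusted per-group p is \((1 + \#\{\max |T^*| \ge |T_j|\})/(B+1)\)
  with \(B = 10^5\) by default. An asymptotic variant integrates the exact
  one-factor correlation structure
  \(\mathrm{corr}(T_i, T_j) = \sqrt{\rho_i \rho_j}\),
  \(\rho_j = n_j/(n_0 + n_j)\), of the limiting multivariate normal, and
  the two variants are cross-checked against each other and against an
  exhaustive enumeration of all relabelings at small n.
- `fisher_exact()` and `bonferroni()` follow the standard two-sided
  hypergeometric and \(\min(1, mp)\) definitions.

## Synthetic data: what it emulates and what it does not

Every pipeline stage is validated on generated inputs whose ground truth
makes the expected output computable in closed form when noise is zero.

- **Soma images** (`generate_soma_image()`): elliptical cytoplasm with an
  interior elliptical nucleus, GFP bright on cytoplasm and zero in the
  nucleus, pMad equal to programmed nuclear/cytoplasmic means over an
  additive background with a linear gradient, i.i.d. Gaussian noise per
  z-slice (default SD 50 on a 16-bit scale against a nuclear mean of
  1000, i.e. 5% per pixel), clipped to the bit range and rounded to
  integer counts. Corners are left as pure background so the four-corner
  estimator is well-posed. Gaussian noise is chosen over Poisson (which
  is available conceptually but not the default) because it makes
  recovery tests analytic; note that the max projection of i.i.d. noise
  adds the same positive offset everywhere, which the background
  subtraction cancels exactly in expectation.
- **Clone images** (`generate_clone_image()`): a neuromere-ladder neuropil
  (CD2) and a clone arbor occupying a known subset (GFP), two well
  separated intensity modes (5000 vs 400 at noise SD 100) so Otsu's
  bimodality assumption holds; the truth records exact mask pixel counts.
  A contrast below 4 noise SDs raises a separability warning.
- **GCaMP recordings** (`generate_gcamp_recording()`): hold–ramp–hold
  temperature protocol at 0.1 °C/s, a 4 Hz thermocouple log on a clock
  deliberately offset from the jittered ~4 Hz camera clock, and terminal
  fluorescence \(F(t) = F_0^{true}(1 + r(T(t)))\) for a programmed
  response curve \(r\). The control profile is a Gaussian bump of
  amplitude 0.2 (a 20% peak) and width 2 °C centered at **43.5 °C** — the
  midpoint of the 43 °C bin. The peak is placed mid-bin deliberately:
  with \([k, k+1)\) binning, a curve peaking exactly at a bin boundary
  makes the two adjacent bins equal by symmetry, and "the peak bin" would
  be a coin flip. Recordings default to a reduced frame geometry
  (32 × 64 px, 3 slices) because the ROI statistic is independent of
  frame size; the temporal and stimulus design (frame rate, ramp, 30-frame
  baseline, 6-px ROI, asynchronous clocks) is kept at the experimental
  values.
- **Behavior tables** (`generate_behavior_dataset()`): latencies are
  lognormal (positive and right-skewed, the natural default for reaction
  latencies) censored at 11 s; binary responses are Bernoulli.

What the generators do **not** emulate: optical point-spread functions,
shot-noise statistics, motion, bleaching, GCaMP kinetics (the programmed
response is an instantaneous function of temperature), or realistic
dendrite/axon morphology. Passing recovery tests therefore demonstrates
that the *measurement and statistical machinery* is correct and unbiased
under the stated noise model — not that the pipelines are robust to every
artifact of real microscopy. `reference_behavior_tables()` is likewise a
synthetic reconstruction: response counts follow exactly from published
n and percentages, while latency cohorts are deterministic
midpoint-quantile samples of a censored lognormal moment-matched to
published means and SEs, so recomputed summaries reproduce the published
values by construction of the inputs, and what is being exercised is the
summary/statistics code path.

## Simulation sizes and reproducibility

The validation suite uses desk-scale designs chosen to match the studies'
own group sizes: pMad effect recovery uses 3 batches of 20 control + 20
experimental images; calcium peak localization uses cohorts of 17 animals
(control) and 19 (amplified) across 20 seeded replicates; Steel's type-I
calibration uses 2000 simulated experiments (control + 3 groups, n = 20,
lognormal) with 400 permutation resamples per test — the Monte-Carlo
p-value \((1+\#)/(1+B)\) is valid at any \(B\), and 400 resamples give
rejection thresholds aligned with \(\alpha = 0.05\) while keeping the
calibration run fast. All stochastic procedures take explicit seeds and
are reproducible bit-for-bit; generators are pure functions of
`(truth, seed)` and restore the caller's RNG state.

## Known limitations

- Censored latencies are analyzed at the cap value; no survival model is
  provided, so between-group differences concentrated beyond 11 s are
  invisible by design.
- The four-corner background estimator is exact only for backgrounds
  linear in image coordinates; strongly curved background fields bias
  `corrected` by the field's curvature over the corner-to-center span.
- Otsu binarization assumes a bimodal histogram; arbors occupying a very
  small fraction of the field can push the threshold into the background
  mode. The exclusion rule catches only the degenerate (single-bin) case.
- The automated nucleus segmentation requires the GFP hole to be fully
  enclosed in the projection; touching the image border defeats it, which
  is why manual masks remain first-class.
- Steel's test is defined here by its permutation reference; other
  implementations using asymptotic critical values will differ slightly at
  small n (the asymptotic variant is provided for exactly that
  comparison).
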