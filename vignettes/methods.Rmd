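---
title: "Methods: marker quantification and calcium transient decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: marker quantification and calcium transient decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(astroquant)
```

# Scope

`astroquant` implements two quantification procedures used when
characterising astrocytes differentiated from stem cells in culture:
counting marker-positive cells and their co-localization in multichannel
immunofluorescence micrographs, and decomposing ATP-evoked Ca²⁺
fluorescence transients into kinetic components. Both procedures are
validated against ground-truthed simulators included in the package. This
vignette records the models, the tunable parameters, the numerical choices,
and the places where the procedure was genuinely open and a design decision
had to be made.

# Image quantification

## Thresholding and quality control

Each channel is binarised with Otsu's method: the histogram threshold
maximising the between-class variance over 256 equal-width bins, with ties
broken toward the lower threshold (so a run of equivalent cuts between two
separated populations yields the most inclusive foreground). A constant
channel has no separating threshold and raises an error rather than
returning an arbitrary value.

The mask is then scored by the Pearson correlation between the channel the
threshold was computed from and the 0/1 mask treated as an image. A score
of at least 0.8 accepts the mask. Below that, two fallback stages run:

1. Rolling-ball-style background subtraction — grayscale opening with a
   disc of radius `background_radius` (default 50 px, roughly twice the
   default cell diameter, so cells are erased from the background estimate
   while illumination structure survives) — followed by re-thresholding.
   After correction, the QC score compares the *corrected* channel to the
   mask: the corrected image is the one the threshold was computed from,
   and under a strong illumination gradient the raw channel bounds the
   achievable correlation below 0.8 for any mask whatsoever, which would
   make the acceptance loop unsatisfiable.
2. If still failing, a sweep over 64 quantile-spaced candidate thresholds
   of the corrected channel keeps the mask with the highest QC score. The
   result records the final score, whether it passed, and that the
   fallback ran.

Debris and artifacts are handled by an optional user-supplied exclusion
mask (no automatic detection); excluded pixels leave the mask, the QC
correlation, and every area denominator.

## Counting rules

Nuclei are segmented from the counterstain channel, holes filled, split by
one round of distance-transform watershed (`tolerance = 1`), and filtered
at a minimum size of 30 px. Pairs the watershed cannot separate count as
one nucleus — deterministic and documented, rather than a heuristic second
pass. A cell is *marker-positive* when a nucleus centroid falls inside a
marker-mask component of at least 30 px: this counts cells rather than
stain fragments and anchors the denominator of "% marker-positive cells"
to the nuclei count (the denominator choice is recorded in the output).
Percent area is the marker-mask pixel fraction of the unexcluded field;
the per-average-cell area is percent area divided by the positive-cell
count, so `per_cell × count = percent_area` holds exactly by construction.
Densities convert through the pixel size (µm/px), which must be supplied —
it is acquisition-specific and cannot be inferred from an image.

## Co-localization

The Pearson coefficient is evaluated directly from its sum formula over a
pixel set chosen by policy: all unexcluded pixels of the field (default),
or the union of the two channels' Otsu masks (focusing the statistic on
stained regions). The policy and pixel count are recorded. Constant inputs
are signalled as undefined rather than returned as 0.

# Calcium transient decomposition

## Normalization and filtering

Each trace is divided by the mean fluorescence of its baseline window
(0 s to the stimulus time, 20 s by default), making the baseline mean of
F/F0 exactly 1 and cancelling the arbitrary gain of the recording — all
downstream features are invariant to scaling the raw trace by any positive
constant. Traces are then filtered with a second-order Butterworth low-pass
applied forward and backward (zero phase). The default cutoff of 0.2 Hz at
1 Hz sampling passes the tens-of-seconds timescale of astrocytic
transients while suppressing sample-to-sample noise; the effective
magnitude response is the square of the single-pass response, ~17-fold
power attenuation at twice the cutoff. `filtfilt` startup transients are
kept out of the data by odd-reflection padding (24 samples at each end),
which preserves level and slope at the boundaries — without padding a
constant trace comes back distorted at the edges. Non-uniformly sampled
traces are linearly resampled to their median interval first.

## Onset detection

A trace responds when the filtered post-stimulus signal exceeds
`baseline mean + k·SD` (default `k = 3`) for at least `m = 3` consecutive
samples, with an absolute floor of `min_delta = 0.01` F/F0 units so the
criterion stays defined in the noiseless limit. Two details matter:

* The SD is taken from the *unfiltered* baseline samples. They are
  uncorrelated, so ~20 samples estimate the noise level stably, and a
  threshold in raw-noise units is conservative on the smoothed trace —
  smoothed noise is autocorrelated, and a 3σ threshold in *filtered* units
  produced spurious sustained excursions on roughly one pure-noise trace
  in ten.
* The reported onset is the threshold crossing immediately before the
  detected excursion, linearly interpolated between samples, rather than
  the first whole sample above threshold; this removes most of the
  half-sample discretisation bias from the latency estimate. Latency is
  onset minus stimulus time.

## Features

The peak is the global maximum after onset (the first, for multi-peak
traces). Rise time is the interval between the linearly interpolated first
crossings of 10% and 90% of peak amplitude, with the baseline level fixed
at F/F0 = 1 (the normalization guarantees it; it is not refitted). AUC is
the trapezoidal integral of `F/F0 − 1`, clipped below at zero, from onset
to the end of the decay-fit window, with both bounds interpolated exactly.

The decay is fit by least squares (Levenberg–Marquardt, started from a
log-linear regression of the positive tail) as `a·exp(−t'/τ)` on the
baseline-subtracted signal from the peak. The window starts at
min(300 s, recording end); when the normalized error — RMSE of the fit
divided by peak amplitude — is 10% or more, the window shrinks (up to 40
candidate end points, minimum 5 samples) until the error stays below 10%,
and the final window is reported. A fitted τ beyond 10⁴ s indicates a
non-decaying tail and is flagged as a fit failure with τ absent.

A response is *biphasic* when, after the decay first reaches half of peak
amplitude, the signal remains at or re-rises to at least half-amplitude
for a sustained `d_sustain = 20` s (a decay that never reaches
half-amplitude inside the analysis window is itself sustained); otherwise
*monophasic*. The 20 s default quantifies "sustained" on the timescale of
store-operated Ca²⁺ entry plateaus; it is configurable and logged.

Note that for a biphasic waveform the single-exponential decay model is
deliberately misspecified — the signal tends to the plateau, not to
baseline — so the fitted τ there reflects the window-shrink rule rather
than the generative decay constant, and may be flagged as diverging.
τ recovery is therefore only asserted for monophasic waveforms; phase,
latency and rise time are asserted for all.

## Error handling

`extract_features()` never aborts a batch: non-responders short-circuit
with phase `"none"` and absent kinetic fields, and any per-trace error
(e.g. NaN samples, zero baseline) is captured in the `error` field of that
trace's row.

# Simulators

The simulators generate data with the statistical structure the analysis
assumes, plus ground truth recorded before corruption.

**Micrographs.** Cells are Gaussian-profile discs: intensity
`exp(−d²/2s²)` inside radius r and exactly zero outside, with s chosen so
the rim value is 0.5. This is the simplest shape with a controllable pixel
area, a soft interior gradient, and a crisp boundary, so on a clean image
the Otsu threshold falls between background and rim and the recovered mask
equals the true footprint exactly — which is what makes exact noiseless
recovery a meaningful test. Nuclei take a quarter of the cell area; cell
areas are Gamma-distributed (defaults: mean 600 px, SD 150 px at full
frame size); centres are rejection-sampled so nuclei never overlap. A
marker channel lights exactly `round(fraction × n_cells)` cells; for two
markers a latent bivariate Bernoulli assignment targets the requested
membership correlation, with the realized value reported in the ground
truth rather than guaranteed (pixel-level PCC is not analytically
controllable). Corruption is applied last: an ambient background level
(default 0.02; stray light plus camera offset — without it a purely
multiplicative gradient leaves empty regions at exactly zero and cannot
degrade the threshold QC), a multiplicative left-to-right linear
illumination ramp, and additive per-pixel Gaussian noise. The frame
defaults to 1388 × 1040 px, matching a ×20 widefield acquisition; the
default pixel size of 0.32 µm/px is typical for that configuration but
must be set to the instrument's calibration for real data.

**Traces.** A responding ROI follows `F(t) = F0·(1 + A·s(t))` plus
Gaussian noise in F/F0 units, where `s` is zero until stimulus + latency,
rises as a raised cosine over the rise duration, and decays as
`(1−p)·exp(−Δt/τ) + p`. The raised-cosine rise keeps the waveform
band-limited (somatic transients are smooth), with a closed-form 10–90%
rise time of 0.5903 × rise duration. Plateau ratio `p ≥ 0.5` holds the
decayed signal above half of peak — a biphasic response; `p = 0` is
monophasic. Defaults emulate the recordings the analysis targets: 300 s at
1 Hz (the acquisition rate is a stated default, not an inferred one),
stimulus at 20 s, latency 23 s, τ 80 s, rise duration 6.4 s (10–90% RT
3.8 s), peak amplitude ratio 1 with ±10% per-ROI jitter, 20%
non-responders, noise SD 0.02. Antagonist treatment is emulated purely as
amplitude attenuation. Non-responders carry `s ≡ 0`.

**What the simulators do not emulate:** real astrocyte morphology,
three-dimensional structure, photobleaching and drift, Poisson photon
statistics (noise is Gaussian), mechanistic pharmacology, and inter-cell
Ca²⁺ wave propagation. Passing recovery tests therefore demonstrates that
the analysis chain is correct and calibrated under its own assumptions —
not that those assumptions hold for any particular microscope or dye.

# Validation surface and problem sizes

The test suite asserts, among others: Otsu equals a brute-force
between-class-variance maximizer on 100 seeded random images; the PCC
formula hits its analytic extremes (+1 self, −1 inversion) to 10⁻¹²;
noiseless micrographs (347 × 260 px, 20 cells, 20 seeds — a half-scale
field that keeps blob geometry while staying fast) are recovered exactly,
and within ±5 percentage points at noise SD 0.1; the kinetics grid
(latency {3, 10, 23} s × τ {60, 80} s × plateau {0, 0.6}, 50 traces per
condition at noise SD 0.02) is recovered with latency MAE ≤ 1 sample,
rise time ≤ 10%, monophasic τ median error ≤ 15%, and ≥ 90% phase
accuracy; the onset criterion's false-positive rate on pure noise is ≤ 5%;
ANOVA holds its type-I rate within [0.03, 0.07] over 1000 null draws; and
the exact Mann-Whitney path equals full enumeration for n ≤ 8.

Two systematic effects are worth knowing. The measured rise time on the
filtered trace is broadened by the 0.2 Hz filter by roughly 8–9% at the
default 6.4 s rise duration — a property of measuring crossings on a
smoothed waveform, constant across conditions, and within the stated
tolerance; analyses that need unbiased RT at short rise times should raise
the cutoff or measure on the unfiltered trace. And the detected latency is
biased late by about half a sample plus the time the signal needs to climb
from zero to the detection threshold (~0.5 s at the default amplitude).

# Statistics

Group comparisons follow the reporting conventions of the field:
mean ± SEM (SEM absent for n = 1), one-way ANOVA with all pairwise
comparisons using the pooled residual variance and Bonferroni adjustment
(raw p × number of pairs, capped at 1), or the two-sided Mann-Whitney test
(exact for small tie-free samples, normal approximation with continuity
and tie correction otherwise; completely tied data returns p = 1 with a
flag). Stars: `*` p < 0.05, `**` p < 0.01, `***` p < 0.001 on adjusted
p-values. When a comparison is chosen automatically, ANOVA is used for
three or more groups with n ≥ 5 each passing a Shapiro-Wilk screen at
α = 0.05, Mann-Whitney otherwise, and the choice is recorded. The default
unit of analysis in the pipeline is the coverslip/replicate-level
measurement as produced by the stages; both per-image and per-group tables
are emitted so pooled and unpooled views stay available.

# Pipeline reproducibility

`run_pipeline()` drives the stages from a serializable config. The single
global seed fans out deterministically into per-stage, per-item substreams
(all below 2³¹), so any stage can be re-run in isolation and reproduce its
artifacts byte for byte. Every stage writes a JSON provenance record with
the MD5 hash of the canonicalised config, the seed, and the counts
processed; output rows carry the source path and ROI/field identifiers.

# Known limitations

* No illumination flat-fielding beyond the fallback background
  subtraction; no automatic artifact detection.
* Touching nuclei are split by a single watershed pass; dense clumps
  undercount.
* The decay model is a single exponential by design; biphasic τ is not a
  generative estimate (see above).
* Whether a reported latency includes solution-exchange dead time is a
  property of the rig, not the trace; the simulator treats latency as
  purely cellular.
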