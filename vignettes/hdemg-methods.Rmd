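---
title: "Methods: spatiotemporal HD-sEMG analysis and its synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatiotemporal HD-sEMG analysis and its synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and numerical choices behind
`hdemg`, in the spirit of a statistical-methods appendix: what each stage
assumes, which parameters matter and why their defaults are what they are,
what the synthetic-data generator does and does not emulate, and where the
design was genuinely open.

## The measurement model

A forearm gesture is modeled as a spatial amplitude field sampled by an
8 × 8 electrode grid: 8 circumferential rows encircling the arm (so the row
axis is periodic) and 8 longitudinal columns at a fixed 2 cm pitch, with the
circumferential pitch set by the forearm circumference divided by 8.
Channel 1 sits proximally on the dorsal starting row; rows advance
counterclockwise as seen on a right arm, placing channels 1–32 dorsally and
33–64 ventrally. For left arms the circumferential order is mirrored,
keeping the starting row.

The monopolar EMG on channel $c$ is treated as an amplitude-modulated
band-limited stochastic carrier:

$$x_c(t) = A_c \, e(t)\, w_c(t) + n_c(t) + p_c(t),$$

where $e(t)$ is the contraction profile, $A_c$ the gesture's spatial
amplitude at that electrode, $w_c$ broadband myoelectric activity
(approximately Gaussian, 20–450 Hz), $n_c$ baseline noise and $p_c$ 50 Hz
powerline interference. The analysis chain is built so that rectification
followed by a 2 Hz low-pass recovers $A_c\,e(t)\,\mathrm{E}|w_c|$; for a
unit-variance Gaussian carrier $\mathrm{E}|w_c| = \sqrt{2/\pi} \approx
0.798$ (folded-normal mean), which is what connects planted template
amplitudes to measured envelope levels in the validation suite.

## Preprocessing

* **Band-pass**: Butterworth, `butter(4, c(20, 450)/(fs/2))`, i.e. an
  order-8 transfer function (4 poles per band edge) following the usual
  call convention of scientific computing environments. 20 Hz removes
  motion artifact and baseline drift; 450 Hz is below the Nyquist frequency
  of the 2048 Hz acquisition.
* **Notch**: a constrained biquad with zeros on the unit circle at 50 Hz
  and Q = 50 (1 Hz bandwidth). No IIR notch designer exists in the
  available `signal` toolbox, so the standard audio-EQ biquad formula is
  implemented directly; its magnitude response is verified in the tests
  against `signal::freqz`.
* **Envelope**: full-wave rectification, then a third-order 2 Hz Butterworth
  low-pass. Tiny negative excursions caused by filter ringing are clamped to
  zero — envelopes are amplitudes by definition.
* **Phase handling**: every filter is applied zero-phase
  (forward–backward, with odd-reflection padding of three filter orders per
  end). The analysis is offline, and causal group delay would bias onset
  estimates; the cost is that magnitude responses are squared and that a
  smoothed onset rises slightly *before* the physical event (measured at
  under 70 ms for thresholds at or above 1% of the plateau). Filtering runs
  in a small compiled kernel (direct-form II transposed across all channels
  simultaneously); the per-sample channel block is contiguous in memory,
  which is what makes 100-seed and 25-cohort validation runs affordable.
* **Ordering**: notch after band-pass. For LTI filters the order is
  immaterial; it is fixed for bit-reproducibility.

### Faulty channels

Faulty channels are replaced sample-wise by the mean of their available
non-faulty neighbors in the grid 8-neighborhood, wrapping across rows
(cylindrical forearm) and truncating at the longitudinal extremes (edge
cells have 5 neighbors). Replacements are computed from the original
non-faulty set, so repair is order-independent and idempotent. The
automatic detector flags channels whose RMS is more than 5× or less than
0.05× the median channel RMS — an explicit, reproducible stand-in for the
visual inspection such data normally receive; a manual list always
overrides it. In the study pipeline the rule is evaluated on the initial
rest period: over a whole session, a genuinely active electrode can exceed
5× the median RMS, whereas at rest only the dead (≈ no signal) and
saturated (≈ amplifier noise) signatures stand out.

## Segmentation

An onset is the first sample at which a summary envelope exceeds
$\mu_b + k\,\sigma_b$ with $k = 10$, where $\mu_b, \sigma_b$ are measured
over the initial rest period after discarding the first 0.5 s of filter
transient (the baseline window is a declared convention; the 10 SD rule is
the standard choice for surface EMG onset detection). Above-threshold runs
separated by less than 0.25 s are merged, runs shorter than 0.25 s are
dropped, and runs ending inside the baseline interval are discarded as edge
transients. Finding a number of bursts different from the protocol's
repetition count is an error — segmentation is never guessed, mirroring the
fact that such data are normally also checked visually.

How to aggregate 64 channels into "the signal" is not fixed by convention.
The default summary trace is the mean of the *raw* envelopes over channels
whose normalization factor exceeds the 25th percentile (amplitude-weighted
and robust to dead channels). When participant-wide normalization factors
are available the mean of the *normalized* envelopes over the same channel
selection is used instead — with factors anchored by a maximal-effort
recording this gives every active channel equal vote. A session-local
normalized mean is deliberately not the default: normalizing a quiet
channel by its own session maximum makes it hover near 1 and erases the
onset contrast. A single-channel mode exists for comparison.

Each onset opens a 3 s contraction window; the steady-state window trims
one third of the contraction duration from each side — the middle 1 s under
the default protocol — discarding the transient phases.

## Normalization and heatmaps

The per-electrode normalization factor is the maximum of the 1 s
centered moving average of its envelope across the participant's complete
dataset (all gestures plus the maximal-effort recording). The moving
average is computed over full windows only, so a single-sample artifact of
amplitude $a$ on a baseline $b$ can raise the factor by at most
$(a-b)/N_w$. A repetition heatmap holds each electrode's mean envelope over
one steady window, on the grid; normalized maps divide by the factors, and
gesture maps are cell-wise means of the 10 repetition maps.

The center of gravity (COG) of a map takes the cells with values at or
above 80% of the map maximum (ties at exactly the threshold are included —
"equal or larger") and returns their amplitude-weighted centroid. The row
coordinate is a circular mean of row angles by default, since the rows
encircle the forearm and a high-amplitude cluster may straddle the row-0/7
seam, where a planar centroid would land on the wrong side of the arm; a
planar fallback is provided because the classical formulation is planar.
Both conventions agree away from the seam. Grid coordinates map to
anatomical percentages as $\mathrm{COG}_x = (r + 0.5)/8 \cdot 100$ (% of
circumference) and $\mathrm{COG}_y = (0.2 L + 2c + 1)/L \cdot 100$ (% of
forearm length $L$ in cm): the array starts at 20% of forearm length, and
cell centers sit half a pitch past the line — the half-pitch offset is a
declared convention, as the cell-center origin is not otherwise fixed.

## Repeatability, similarity, dimensionality

Repeatability and gesture similarity are squared Pearson correlations
between maps reshaped to 1 × 64 vectors: 45 unique pairs among 10
repetitions per gesture, 21 among 7 gesture-average maps, hence 315
coefficients per participant. Normalized maps feed all of these. A map
with zero variance across its cells raises an error rather than producing a
silent NaN that would poison group averages.

Dimensionality applies a PCA to the 64 × 70 concatenation of all
repetition heatmaps. The 70 heatmap vectors are the variables (columns,
each centered) and the 64 electrodes the observations — the orientation
under which a centered matrix has at most 63 components, matching how such
decompositions are reported for this grid; a transposed mode is available.
No variance scaling is applied. The reported dimensionality is the smallest
component count whose cumulative variance explained exceeds 90% (strictly
greater). One subtlety that shaped the synthetic design: centering
non-negative disjoint patterns couples them through their means and
*shrinks* the last component, so planted-rank validation uses compact,
near-orthogonal templates (see below).

## Myocontrol assessment

Classification operates on the band-pass filtered raw signals (not the
envelopes): the 10 steady-state segments per gesture are concatenated in
repetition order (~10 s), and 200 ms windows with 100 ms overlap are cut
*within* segments by default — windows never span the splice between
non-contiguous pieces of signal, so each 1 s segment yields
$\lfloor(1 - 0.2)/0.1\rfloor + 1 = 9$ windows and each gesture 90. A
straddling mode (99 windows) exists because the concatenated-vector wording
of the classical procedure is ambiguous. Each window yields the four
Hudgins time-domain features per channel — mean absolute value, zero
crossings, slope-sign changes, waveform length, in channel-major order
(256 features for 64 channels). The ZC/SSC dead-band defaults to 0 and is
configurable; with it, ZC and SSC are amplitude-scale invariant while MAV
and WL scale linearly.

The classifier is linear discriminant analysis with per-feature
standardization (training-set statistics) and a pooled within-class
covariance shrunk toward a scaled identity with an analytic
(Ledoit–Wolf-type) intensity. With 256 features and a few hundred training
windows the unregularized pooled covariance is ill-conditioned or singular
(e.g. duplicated features); shrinkage keeps the discriminant defined
without tuning. Validation is three-split Monte Carlo cross-validation with
stratified 70/30 partitions — stratification is a safeguard, since an
unstratified 30% draw over 7 classes can lose a class entirely. Accuracy
curves rerun the CV on the first $k$ gestures of a declared gesture order
($k \ge 2$; a single-class problem is degenerate).

Window-level random splitting follows the apparent classical procedure but
lets overlapping windows of the same repetition appear in both partitions,
which inflates offline accuracy relative to repetition-blocked splitting.
The package reports what the procedure defines; numbers should be read as
offline, window-level accuracies.

## The synthetic cohort generator

The generator exists so every stage can be validated against ground truth.
Per participant it plants:

* **Base spatial templates** — isotropic Gaussian bumps in grid units at
  max–min separated centers (greedy farthest-point layout with circular row
  distance, jittered per participant by ±0.4 cells by default). The
  sampled Gaussian's nominal center is moment-corrected per axis (a
  one-dimensional root find) so the discrete amplitude-weighted centroid
  equals the requested center *exactly* — grid truncation would otherwise
  bias it by ~0.01 cells — making planted centers exact ground truth for
  COG recovery. Rows wrap circumferentially via a wrapped Gaussian whose
  circular centroid is exact by symmetry.
* **Gesture assignment** — with $k$ distinct templates and 7 gestures, the
  first $k$ gestures are pure; the rest are blends with a dominant base
  (coefficient 1) and secondary bases at 1/2, chosen disjointly. Blends
  keep the planted rank at $k$ while producing correlated gestures, and the
  coefficients were chosen so the cumulative variance explained at $k - 1$
  components stays comfortably below the 90% threshold for all
  $k \in 1..7$ under the centering convention above.
* **Contraction profile** — trapezoids with a 250 ms ramp (instructed
  transitions are abrupt; muscle force is not), 10 × 3 s on / 3 s off at
  2048 Hz by default, rest first, so planted onsets fall at 3, 9, 15, … s.
* **Variability** — per-repetition lognormal amplitude jitter (sd 0.1) and
  per-repetition mixing noise in base-template space (sd 0.2 healthy, 0.3
  DMD), a minimal model of co-contraction variability that stays in the
  span of the base templates (planted rank is preserved). The mixing sd
  maps to expected repetition R² of roughly $(1+\gamma^2)^{-2}$ — about
  0.92 and 0.84 — bracketing the high repeatability such recordings show.
* **Group profiles** — healthy: 5 base templates, spread 1.0 cells,
  comfortable activation at 26% of maximum, absolute envelope scale 89 µV;
  DMD: 3 templates, spread 0.7, 63%, 35 µV. These encode the reported
  group contrast: DMD participants activate close to their maximum yet
  produce lower absolute amplitudes and a lower-dimensional gesture space.
* **An MVC-like reference session** — all base templates superimposed at
  `absolute_scale / activation_level`, floored at 25% of that amplitude so
  *every* electrode has a genuine dataset maximum. This anchors the
  normalization factors the way a dynamic maximal-effort recording does;
  without it, quiet channels would be normalized by their own noise floor
  and normalized activations would be meaningless.
* **Noise** — per-channel independent Gaussian carriers band-passed to
  20–450 Hz and scaled to unit variance, baseline noise of 3 µV, 50 Hz
  powerline at 10 µV with random phase per channel, and optional faulty
  channels (dead = 1% of baseline noise, saturated = 50×, the two
  signatures visual inspection flags). The generator requires nonzero
  baseline noise for the segmentation stage to be meaningful: with a truly
  zero baseline the 10 SD threshold degenerates to zero.

Sessions are fully reproducible from integer seeds; cohorts are returned as
lazy plans (templates + seeds + ground truth) and synthesized on demand,
since a realized 64-channel session occupies ~60 MB.

**What the generator does not emulate** — and therefore what passing tests
do not show about real recordings: motor-unit structure and firing
statistics, volume conduction and inter-channel correlation (carriers are
independent across electrodes), electrode–skin impedance variation, fatigue
and slow drifts, movement artifact, and any quantitative model of DMD
co-contraction structure (the blend matrix is a modeling choice, not a
measured quantity). Conclusions about real data rest on the pipeline's
correctness, which is what the synthetic cohorts validate.

## Validation scales

The test suite validates at sizes chosen for a single CPU: filter oracles
via independent frequency-response evaluation; onset recovery on 100 seeded
two-repetition sessions at 1024 Hz (±100 ms at SNR 50:1); COG recovery on
100 seeded single-repetition sessions (0.5-cell circular tolerance, ≥95%
hit rate); exact planted-rank recovery (ranks 3 and 5) through the full
pipeline on compact near-orthogonal templates with mixing and jitter
disabled; chance-level behavior of the classifier over 20
label-permutation seeds; and the four group-contrast directions (higher
normalized maxima, lower absolute maxima, fewer PCs, steeper accuracy
decay for the DMD profile) over 25 seeded one-versus-one cohorts at
1024 Hz. The acceptance script runs the full 8 + 3 cohort at the complete
study conditions (7 gestures × 10 repetitions, 2048 Hz).

## Known limitations

* The default healthy profile, with its broad (spread 1.0) and jittered
  templates, typically lands at 4–5 principal components rather than
  exactly 5: template overlap and the centering convention both concentrate
  variance. The DMD–healthy dimensionality *contrast* is robust; the
  absolute component count is sensitive to template geometry.
* Offline window-level cross-validation inflates accuracy (see above);
  block-wise splitting would be the stricter protocol.
* The notch filter distorts a 1 Hz band around 50 Hz; for heavily
  contaminated recordings spectral interpolation would be preferable, and
  is out of scope here.
* The delimited-import path assumes recordings can be exported as a plain
  numeric matrix (columns = channels, µV); no proprietary acquisition
  formats are parsed.
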