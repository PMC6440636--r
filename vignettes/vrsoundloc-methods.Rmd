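---
title: "Methods: binaural cue errors and pointing analysis for VR sound localization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: binaural cue errors and pointing analysis for VR sound localization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vrsoundloc)
```

## The problem

A head-mounted display (HMD) is a physical obstacle sitting on the listener's
head. It reshapes the acoustic path from a loudspeaker to each ear and
therefore perturbs the three cues the auditory system uses to localize
sound: the interaural time difference (ITD), the interaural level
difference (ILD), and monaural spectral features. In loudspeaker-based
virtual sound environments combined with VR glasses, these perturbations —
together with the amount of visual information the display provides —
determine how well a listener can point at a sound source.

`vrsoundloc` implements the full measurement-to-table pipeline for such an
experiment: cue-error extraction from paired binaural impulse responses
(BRIRs) recorded with and without the HMD, the rigid calibration of the
virtual scene onto tracked real-world reference points, and the analysis of
hand-pointing responses. A synthetic-data module generates every input the
pipeline consumes, so all stages are testable without measurement hardware.

## Physical analysis

### Impulse-response preparation

Measured BRIRs are truncated to 128 samples (2.7 ms at 48 kHz) with
`truncate_ir()`, which removes reflections from other loudspeakers and
room objects while keeping the direct sound and the head/pinna response.

### Auditory filterbank

Band powers are computed in a gammatone filterbank spaced at one filter per
equivalent rectangular bandwidth (ERB) between 200 Hz and 16 kHz
(34 filters at the defaults). The ERB follows Glasberg & Moore,
`ERB(f) = 24.7 (4.37 f/1000 + 1)` Hz, and centers are uniform on the
ERB-number scale. Filters are fourth-order gammatone FIR prototypes
(`gammatone_fir()`), 64 ms long so that the narrowest (200 Hz) filter's
envelope decays fully inside the prototype.

Band power is reported in dB **relative to each filter's own unit-impulse
output power**. Two properties motivate this reference: a unit impulse
reads 0 dB in every band, and any per-filter gain convention cancels
exactly in the quantities of interest, which are all *differences* —
between conditions (spectral difference), or between ears (ILD). An
all-zero channel returns a documented floor of −120 dB rather than an
error, so silent channels propagate through batch analyses.

Three frequency regions partition the analysis range: low
(200 Hz – 1 kHz), mid (1 – 5 kHz) and high (5 – 16 kHz). A filter belongs
to the region containing its center frequency; boundaries are half-open
`[lo, hi)` with the final region closed at 16 kHz, so every filter belongs
to exactly one region.

### Cue definitions

* **Spectral difference (SD)**: per ear and region, the mean over member
  filters of the absolute band-power difference between the with-HMD and
  without-HMD responses. Differences are taken per filter first, then
  averaged, so opposite-signed perturbations within a region do not cancel.
* **ILD**: per region, the mean over member filters of left-minus-right
  band power.
* **ITD**: each ear's pure delay is the lag of the peak cross-correlation
  between its impulse response and its minimum-phase version
  (`ear_delay()`); the ITD is the left-minus-right delay. The estimate is
  integer-lag by design: reported ITD errors are whole samples
  (one sample at 48 kHz ≈ 21 µs), and no subsample interpolation is
  attempted.
* **Cue errors** (`cue_errors()`): ILD and ITD errors are differences of
  magnitudes, `|cue_with| − |cue_without|`, so a positive error means the
  HMD made the interaural difference larger. The signed-difference
  alternative is available via `magnitude = FALSE`.

### Minimum phase, numerically

The minimum-phase construction is the one numerical hot spot. The package
factors the truncated impulse response's z-transform and divides out the
all-pass component of every zero lying outside the unit circle. Two
implementation details matter:

1. Polynomial roots come from LAPACK eigenvalues of the companion matrix,
   not from `polyroot()`: the classical Jenkins–Traub implementation loses
   several digits at degree ≳ 100, which is fatal when zeros sit close to
   the unit circle.
2. The all-pass correction is evaluated bin-by-bin on the FFT grid, where
   each factor `(conj(r) x − 1)/(x − r)` has unit modulus *identically* —
   so magnitude preservation does not depend on root accuracy at all.
   Root accuracy only affects how cleanly the corrected spectrum inverse-
   transforms back to a finite causal sequence.

In practice magnitude spectra are preserved to ~1e−11 dB on 128-sample
responses. Leading zero samples (a pure delay) are stripped before
factoring, and the result's sign is canonicalized so its first sample is
positive, matching the cepstral convention.

## VE-to-RE calibration

Three tracked reference points sit on the ear-level loudspeakers at 0° and
±45° azimuth. `calibrate()` implements the three-step alignment used at
run time:

1. rotate the virtual point set so its plane normal coincides with the
   real one;
2. translate so a chosen reference point coincides with its real
   counterpart;
3. rotate about the real normal, through the reference point, by the angle
   between the in-plane vectors to a second point in each frame.

Inside `calibrate()` the plane normal is the *ordered* cross product
`(p2−p1)×(p3−p1)` in both frames: point correspondence makes it rotate
consistently with the frame. (The standalone `plane_normal()` helper
instead canonicalizes the sign — positive z, falling back to positive x,
then y — which is the right convention when no correspondence exists, but
would flip the virtual plane upside down under large displacements if used
for calibration.) The second point of step 3 is the lowest-index
non-reference point. For an exactly rigid correspondence the procedure is
exact; over 1,000 random rigid displacements of the tracker geometry the
worst point residual stays below 1e−9 m, and the result agrees with an
independent least-squares (Kabsch) registration.

`alignment_residual()` reports the maximum point offset and the
recalibration flag, which fires when the offset exceeds 2 cm — the
threshold the experimental setup used. The worst-case rotation implied by
a positional tolerance depends on which lever arm the offset acts across;
`worst_case_rotation_deg()` therefore takes the lever as an argument
rather than asserting one geometry.

## Behavioral pipeline

`analyze_responses()` chains four stages:

1. **Handedness mirroring** (`mirror_handedness()`): left-handed subjects'
   target and response azimuths are negated so pointing-hand effects line
   up across the cohort. The operation marks mirrored rows, making the
   analysis idempotent.
2. **Pointing-bias estimation** (`estimate_pointing_bias()`): the
   hand-held controller induces a per-subject offset (subjects do not know
   where the invisible pointing ray leaves the device). The bias is each
   subject's mean signed azimuth/elevation error over all targets and
   repetitions of the two *visual*-localization conditions; the group bias
   is the mean of subject biases.
3. **Bias correction** (`apply_bias_correction()`): per-subject biases are
   subtracted from responses in all conditions except the laser-pointer
   condition, where visible feedback of the pointing direction makes the
   controller-shape bias irrelevant.
4. **Outlier screening** (`filter_outliers()`): responses farther than 45°
   from the target in either wrapped azimuth or elevation are discarded.
   "Farther than" is strict — an error of exactly 45° is kept. Screening
   runs *after* bias correction, i.e. on the errors the analysis actually
   uses; the alternative order is not exposed because a 19° elevation bias
   would otherwise push ordinary responses over the threshold.

`summarize_errors()` emits a long-format table per group and error
dimension: mean absolute error, median/quartiles of the signed error
(R's default type-7 inclusive linear interpolation, so boxplot statistics
are bit-reproducible), 1.5 × IQR whisker bounds, and counts.
`hemifield_contrast()` differences left- against right-hemifield cells at
matched |azimuth|. Inferential statistics (mixed models, post-hocs) are
deliberately out of scope — the long table is designed to feed `lme4`,
`emmeans` or any comparable tool directly.

Azimuth errors are wrapped to (−180°, 180°], with the tie at ±180°
resolved to +180°; elevation errors are plain differences. Angles are
degrees on every public surface.

## Synthetic data

The generators define the conditions every quantitative check runs under;
they are fixed, not tuned per test.

### Spherical-head BRIRs

`spherical_head_brir()` places a unit impulse at the near ear and, at the
far ear, an impulse delayed by the Woodworth frontal-incidence ITD
`(a/c)(θ + sin θ)` (head radius 8.75 cm, c = 343 m/s) and filtered by a
one-pole low-pass head shadow whose coefficient grows with the lateral
angle. The lateral angle combines azimuth and elevation through
`sin λ = sin(az) cos(el)`, giving cone-of-confusion behavior. The ITD is
quantized to integer samples so that integer-lag cue extraction recovers
it exactly: at 90° azimuth the model produces 31 samples ≈ 646 µs against
the continuous 656 µs. The model deliberately omits pinna, torso, and room
acoustics: it provides correct *interaural* structure, not realistic
monaural spectra.

### Parametric HMD perturbation

`apply_hmd_model()` reshapes a BRIR the way the measured with-HMD
responses differ from the without-HMD ones:

* an **ITD offset** added to the contralateral ear, zero at 0° and 90°
  azimuth with a piecewise-linear peak of 62.5 µs (3 samples) at 75°,
  quantized to whole samples;
* **per-region ILD boosts**: zero-phase raised-cosine attenuation of the
  contralateral ear in log-frequency, scaled so the realized region-mean
  ILD error tracks the configured offset (default 6 dB at the mid/high
  peak azimuths of 60°/30°, and a quarter of that in the low region,
  keeping low-region errors below 2 dB);
* **spectral ripple** in the mid/high bands of both ears, amplitude
  growing with each ear's contralaterality, reduced by a factor 0.4 below
  the horizontal plane (the HMD sits above the ears), with the ripple
  phase derived deterministically from the seed.

The perturbation is deterministic given (azimuth, elevation, config); the
seed moves only the ripple phase. Setting all magnitudes to zero returns
the input bit-for-bit.

### Stimulus and response cohorts

`pink_noise_burst()` synthesizes the 240 ms pink-noise stimulus with 20 ms
raised-cosine ramps at a nominal 65 dB level roved uniformly within ±3 dB,
a fresh realization per call. Digital level is referenced to a
configurable full-scale point since no acoustic calibration constant
applies in software.

`simulate_responses()` builds the full design — 10 subjects × 8 conditions
× 27 sources × 5 repetitions = 10,800 trials — with per-subject biases
drawn around the group values (−1.6° azimuth, +19.0° elevation),
per-condition angular noise, an HMD lateral overshoot larger on the left
than the right, an elevation penalty in the blind-folded HMD condition,
and a 0.003 lapse probability with lapses uniform over the frontal
hemisphere (the scale that reproduces an outlier rate of a few per
thousand under the 45° rule). The per-condition elevation-noise defaults
were chosen once so that the folded-normal means of the corrected errors
land near the study's condition means (≈ 12, 10.2, 8.1, 6.6 and 2.4° from
blind-folded-with-HMD down to laser); `E|N(0, σ)| = σ√(2/π)` gives the
mapping. One subject is left-handed by default; their lateral gains and
azimuth bias are generated mirrored so that median-plane mirroring
restores a homogeneous cohort.

What the cohort does *not* emulate: trial-order and learning effects,
subject-specific noise heterogeneity, the ventriloquism pull of visible
loudspeakers, or any acoustic linkage between the BRIR perturbation and
the behavioral shifts — cue errors and response shifts are generated by
separate parametric mechanisms. Passing pipeline tests on this cohort
therefore validates the *analysis machinery and its calibration*, not
claims about human listeners.

## Problem sizes and reproducibility

The test suite and the acceptance script run the calibration recovery on
1,000 random displacements, the ITD oracle on the ±10-sample delay grid,
cue extraction on the 13 horizontal-plane sources, and 100 replicates of
the 10,800-trial cohort for the condition-ordering check — sizes at which
every stochastic bound sits several standard errors clear of its
threshold. All generators accept a single integer seed; identical seeds
give byte-identical outputs, and the `demo` CLI subcommand writes
identical artifact trees on reruns.

## Known limitations

* The rigid-sphere model's monaural spectra are unrealistic; spectral
  difference magnitudes for synthetic data are meaningful only relative to
  the model's own baseline.
* Integer-lag ITDs cannot resolve sub-sample delays; at 48 kHz the
  quantization step is ≈ 21 µs, which is also the resolution of the
  reported errors.
* The deposited measurement dataset ships in a container this package
  reads only after conversion to the WAV-directory layout (see README);
  no HDF5 reader is bundled.
* Mixed-effects inference is out of scope by design; the package stops at
  tidy error tables.
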