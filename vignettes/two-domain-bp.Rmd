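---
title: "Two-domain fusion for cuffless blood pressure estimation"
author: "pulsebp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-domain fusion for cuffless blood pressure estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 3.5)
library(pulsebp)
```

## The measurement problem

A piezoresistive pressure sensor held against the radial artery records
the arterial pulse wave directly: the main systolic wave launched by
cardiac ejection, plus two reflected ("rebound") waves returning from
the major arterial branch sites, superimposed with delays of a few
hundred milliseconds. The morphology of that superposition — relative
rebound heights, the dicrotic notch separating systole from diastole,
timing ratios, upstroke steepness — co-varies with arterial stiffness,
peripheral resistance and ejection strength, and therefore with systolic
and diastolic pressure (SBP, DBP). `pulsebp` implements a complete
estimation chain from a raw single-channel pressure recording to an
(SBP, DBP) pair, with two design ideas at its core:

1. **BMI-calibrated contact pressure.** The waveform is only informative
   when the sensor's hold-down force balances the soft tissue over the
   artery. The package implements the sweep protocol that finds each
   subject's optimal pressure (OP) and the cubic calibration curve
   `OP(BMI) = -0.0114 BMI³ + 0.7302 BMI² - 15.0889 BMI + 104.4144` (newtons)
   relating it to body mass index.
2. **Input-level fusion of two feature domains.** Six morphological
   features from single beats (time domain) are concatenated with six
   FFT harmonic features from five-beat windows (frequency domain) and
   fed to one 12-30-2 feed-forward network trained by a quasi-Newton
   optimizer. The time domain is precise but sensitive to beat-level
   detection errors; the frequency domain is stable but blurs beat
   detail. Fused, they constrain each other.

No public recording set accompanies this problem, so the package ships a
synthetic pulse-wave generator with known ground truth; every stage is
developed and tested against it.

## The synthetic generator

A beat is the sum of three Gaussian bumps: the main wave (unit reference
amplitude, width 0.08 s) and two rebounds at delays 0.22 s and 0.38 s
with amplitude ratios 0.5 and 0.25 and widths 0.05 s, one period of
0.83 s (72 bpm). These defaults reproduce the textbook radial waveform:
onset *b*, systolic peak *c*, dicrotic notch *d*, first rebound peak
*e*, and the second rebound pair *f*, *g*.

```{r beat}
y <- simulate_beat(beat_params(), fs = 500)
plot((seq_along(y) - 1) / 500, y, type = "l",
     xlab = "time (s)", ylab = "amplitude")
fid <- detect_fiducials(y, fs = 500)
points((unlist(fid[c("b", "c", "d", "e", "f", "g")]) - 1) / 500,
       y[unlist(fid[c("b", "c", "d", "e", "f", "g")])], col = 2, pch = 19)
```

Records concatenate beats at the requested heart rate with log-normal
beat-to-beat jitter on period and amplitude (default CV 2%), add a
sinusoidal respiration baseline at 0.3 Hz (5% of the main amplitude) and
white Gaussian noise. The magnitude spectrum of such a record shows the
respiration line and the cardiac fundamental with its harmonics, the
structure the frequency features rely on.

**Ground-truth pressures.** `bp_from_params()` maps the generator
parameters to an (SBP, DBP) pair. It is an anchored design choice, not a
hemodynamic model: the reference shape maps to 120/80 mmHg; smooth
bounded (tanh) response curves move DBP inside (62.5, 92.5) mmHg and the
pulse pressure inside (27.5, 52.5) mmHg, so the image always stays in a
physiological box and SBP − DBP ≥ 20 mmHg. The drivers follow
pulse-wave-analysis practice qualitatively: a stronger or later first
rebound raises SBP; slower heart rates lower both pressures; the second
rebound contributes moderately. The weights were fixed once, guided by a
parameter-recovery analysis (below), so that both feature domains are
informative but neither is sufficient alone — the property that makes
the two-domain-versus-single-domain comparison meaningful on synthetic
data.

**What the generator does not emulate:** arrhythmia beyond period
jitter, motion artifacts, amplitude modulation by respiration,
vascular-age morphology changes, or any transfer function between
central and radial pressure. Synthetic results demonstrate that the
pipeline recovers what the generative model encodes; they say nothing
about accuracy on human recordings.

## Contact-pressure calibration

The sweep protocol steps the hold-down force from 2 N to 14 N in 0.5 N
increments, recording 20 film-pressure samples per level. The analysis
chain is `fit_baseline()` (running median, window 5 of 20 samples,
replicated-edge policy so output length equals input length),
`select_optimal_level()` (the sample with the largest |pressure −
baseline| over the concatenated sweep marks the strongest pulsation;
ties break toward the lower, more comfortable force), and
`fit_op_curve()` (least-squares cubic of per-subject OP against BMI).
The printed cubic evaluates to 4.4882 N at BMI 22 and 3.5164 N at BMI
20; it is nearly linear below BMI 24 and saturates above, where
`optimal_pressure()` warns. Its accepted domain is BMI 16–30 — outside
that range the calibration data give no support.

In `simulate_pressure_sweep()` the pulsation appears as four isolated
zero-mean excursions per level (alternating sign at samples 4/9/14/19)
whose size decays as a Gaussian (width 1.2 N) in the distance between
applied force and the subject's true OP, with 0.02 N film noise. The
spike layout is deliberate: a 5-sample running median rejects isolated
excursions exactly, the per-level mean equals the level, and
level-transition artifacts in the baseline stay well below the peak
excursion (1.2 N), so the protocol recovers the planted OP grid point.

## Signal conditioning and beat segmentation

`condition_signal()` applies a zero-phase band-pass with the squared
magnitude response of a third-order Butterworth between 0.15 and 25 Hz —
the response a forward–backward (filtfilt) implementation would have.
It is evaluated in the frequency domain on a mirror-padded copy because
the equivalent sixth-order IIR transfer function is numerically unusable
at a normalized corner of 0.15/(fs/2) ≈ 6·10⁻⁴: in double precision it
leaks roughly half the DC level. The FFT form removes DC exactly, is
linear to machine precision, keeps the 0.3 Hz respiration line, passes
1.2 Hz within 2%, and attenuates 50 Hz more than 60-fold.

`segment_beats()` finds systolic upstrokes as runs where the smoothed
derivative (40 ms moving average) exceeds 40% of its 98th percentile,
then paces them on a period grid estimated from the signal's
autocorrelation: starting at the steepest upstroke it accepts, within
0.7–1.35 estimated periods of the last accepted upstroke, the steepest
candidate. The pacing step matters: reflected waves can produce
upstrokes steep enough to pass any fixed threshold at a sub-period delay
(≈ 0.4 s for the second rebound), and a fixed refractory either swallows
them at low heart rates or real beats at high ones. A record with no
autocorrelation peak above 0.2 in the 0.3–2 s lag range is rejected as
non-periodic (flat or pure noise). The beat onset (wave foot) is the
first crossing of 2% of the local rise above the pre-upstroke minimum,
located on a lightly smoothed copy; on noiseless synthetic records all
onsets land within 20 ms of truth, and at 2% amplitude noise the mean
absolute onset error stays below 10 ms. Accepted beats span
onset-to-onset, half open, with periods restricted to 0.3–2 s
(30–200 bpm); the trailing incomplete beat is dropped.

## Fiducial points and features

Within a beat, *c* is the global maximum; *d* is the most prominent
trough between *c* and 75% of the post-peak span (later troughs are
end-of-beat artifacts, and prominence below 1% of pulse height is
noise); *e* is the first maximum after *d*. In young, elastic arteries
the rebound can be submerged and no trough exists: *d* then falls back
to the strongest post-peak concavity change (second-derivative maximum)
and *e* is flagged `e_inferred`. The second rebound pair *f*, *g* is
only reported when *g* rises at least 2% of pulse height above *f*.

Six time-domain features are computed per beat, all amplitudes
referenced to the value at the onset *b*: `FC` (rebound-to-main height
ratio h/H), `Sss` and `Sds` (systolic/diastolic trapezoidal area
fractions split at *d*; `Sds` is stored as `1 - Sss` so the pair sums
to one exactly), `Tft` (onset-to-notch time over period), `Tst`
(onset-to-peak time over period) and `SL` (maximum upstroke slope).
Six frequency-domain features come from the FFT of a window spanning
exactly five onset-to-onset beats — the five-cycle window refines the
frequency sampling to a fifth of the heart rate: amplitudes `A1..A3`
(one-sided magnitudes, normalized by window length, no zero padding)
and raw principal-value phases `P1..P3` at the first three
characteristic peaks. Characteristic peaks are local maxima at
frequencies ≥ 0.6 Hz — the cardiac fundamental and harmonics, explicitly
excluding the respiration line — with candidates below 5% of the
strongest peak treated as noise; if fewer than three clean peaks exist
the window is flagged degenerate and filled at multiples of the
estimated fundamental. Windows tile the record in non-overlapping
groups of five beats, and the time features of a window are the mean
over its five beats, so both domains describe the same span.

## Quality control, normalization, network

The threshold matrix rejects windows whose raw beat period, main-peak
amplitude or bounded ratios leave their acceptance intervals. Defaults
encode attainable radial-pulse morphology: period 0.3–2 s, `Tst` ≤ 0.6,
`Tft` 0.15–0.8, `FC` 0.02–0.98, `Sss` 0.20–0.95, and optionally
amplitude within 5× a reference. On the synthetic benchmark ~1% of
windows are discarded, almost all mis-detected submerged-notch beats.

Accepted features are mean-shifted and scaled to unit population
standard deviation (the 1/n convention; statistics are stored in the
model and re-applied verbatim at prediction time). Data split randomly
70/15/15 into training/validation/test with floor rounding and the
remainder to training. The regressor is a feed-forward network — inputs
(12 fused, or 6 for single-domain ablations), 30 logistic-sigmoid hidden
units, 2 linear outputs — minimizing the joint MSE over (SBP, DBP) with
BFGS. Targets are standardized internally for optimizer conditioning.
Training runs in stages of 25 BFGS iterations (cap 1000) with early
stopping once the validation RMSE has not improved for 6 checks, keeping
the best-validation weights. Three deterministic restarts are trained
with weight decay 10⁻³, 3·10⁻⁴ and 3·10⁻³ on connection weights, and the
restart with the lowest validation RMSE wins — small-sample training
variance otherwise dominates comparisons between models. Everything is
seeded; identical configuration gives bit-identical models.

Hidden-layer width was examined on the benchmark: widening beyond 30
nodes changes validation RMSE by well under 0.2 mmHg while inflating
training time, so 30 is the default.

## The synthetic benchmark and the replication protocol

`make_bp_dataset()` is the package's study condition: 1200 records, one
five-beat window each, simulated at 250 Hz (ample for the ≤ 10 Hz pulse
content; the generator default of 500 Hz matches the hardware protocol's
granularity but doubles cost for no analytical gain). Beat shapes are
drawn uniformly from documented physiological ranges (rebound ratios
0.3–0.7 and 0.1–0.4, delays 0.18–0.28 s and +0.12–0.20 s, heart rate
0.9–1.5 Hz, amplitude 0.7–1.3, widths scaled with the period), with 1%
additive noise, 2% beat jitter, respiration, and — importantly — an
independent log-normal **sensor-coupling gain** (CV 10%) that scales the
recorded waveform but not the labels. Contact-force variability is
exactly what the OP calibration chapter exists to tame; its presence
means absolute recorded amplitude is an unreliable pressure correlate,
which penalizes the frequency domain (whose `A1..A3` are absolute) far
more than the ratio-based time features. Labels are
`bp_from_params()` plus 0.5 mmHg Gaussian reference noise, emulating
cuff-reading error.

The map weights were chosen once from a parameter-recovery analysis
(training the same network to predict each generator parameter from each
feature domain): parameters that need both domains (first-rebound delay,
period, first-rebound ratio) carry most of the weight, the second
rebound — which the time domain sees better — provides the
time-over-frequency margin, and amplitude carries almost none since the
coupling gain masks it for everyone.

On this benchmark the fused 12-input model reaches a 95th-percentile
absolute test error below 2 mmHg; the time-only ablation sits below
3 mmHg and the frequency-only ablation is clearly worst (typically
2.3–3 mmHg, far inside its 9 mmHg band). Stability of the ordering is
assessed by a replication protocol: 100 seeded replicates, each a fresh
70/15/15 split and re-training of all three models on the fixed
benchmark cohort, comparing test-set mean absolute errors. The split is
the randomization device here, exactly as in the underlying study
design; replicating entire cohorts at the sizes a test suite can afford
(a few hundred windows) mainly measures small-sample training noise
rather than the models' relative merits. In the shipped test suite the
fused ≤ time-only ≤ frequency-only chain holds in well over 90 of 100
replicates.

## Numerical choices and degenerate inputs

* FFT-domain filtering uses mirror padding (3 s) extended by edge
  values to a power-of-two length; padding with zeros would step the
  signal and ring through the slow high-pass tail.
* Record rendering assigns samples to beats with a half-sample
  tolerance so floating error in accumulated onset times never moves a
  boundary sample to the wrong beat; records are bit-reproducible for a
  fixed seed.
* `Sds = 1 - Sss` by construction; the area pair sums to one exactly in
  floating point.
* Ties: `select_optimal_level()` takes the first (lowest-level) maximum;
  the notch chooser takes the first of equally prominent troughs.
* Degenerate inputs error with typed conditions
  (`pulsebp_param_error`, `pulsebp_data_error`): flat or pure-noise
  signals at segmentation, beats with no interior maximum, windows
  shorter than five cycles, zero-variance feature columns (warning,
  scale 1), empty test sets.
* Phases are raw principal values in (−π, π]; `P2` in particular wraps
  across the benchmark population, a real burden the frequency-only
  model must carry.

## Limitations

The generator's three-Gaussian beat is a morphological caricature; its
agreement with real radial waveforms is qualitative. The ground-truth
pressure map is a synthetic construction whose purpose is testability,
not physiology; error magnitudes on this benchmark do not transfer to
human data. The calibration cubic is used as printed — the 30-subject
sweep data behind it are not available to refit. Subject-level
train/test separation is not modeled (windows are independent records
here), mirroring a limitation the underlying study itself acknowledges.
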