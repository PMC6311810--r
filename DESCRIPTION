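Package: pulsebp
Title: Cuffless Blood Pressure Estimation from Radial Pulse Waveforms by
    Two-Domain Feature Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for continuous, cuffless estimation of systolic and
    diastolic blood pressure from single-channel piezoresistive
    pressure-sensor pulse waveforms recorded over the radial artery.
    Implements the full analysis chain: BMI-based calibration of the
    optimal sensor contact pressure (sweep protocol, median-filter
    baseline fitting, cubic calibration curve), zero-phase band-pass
    signal conditioning, beat segmentation, detection of the
    characteristic fiducial points of the pulse wave (onset, systolic
    peak, dicrotic notch, rebound peaks), six time-domain morphological
    features and six frequency-domain FFT harmonic features per five-beat
    window, threshold-matrix quality control, and a 12-30-2 feed-forward
    neural network trained by a quasi-Newton (BFGS) optimizer with
    validation-based early stopping that maps the fused feature vector to
    (SBP, DBP). A synthetic pulse-wave generator with known ground-truth
    blood pressure makes every stage testable without hardware or human
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    nnet
Config/testthat/edition: 3
RoxygenNote: 7.3.3
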