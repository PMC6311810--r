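#' Beat-shape parameters for the synthetic pulse-wave generator
#'
#' A radial pulse beat is modelled as the superposition of a main systolic
#' wave and two reflected ("rebound") waves that arrive with fixed delays
#' after the main peak: the first from the thoracic/renal branch site, the
#' second from the abdominal/iliac site. Each component is a Gaussian bump,
#' a standard choice in pulse-decomposition work; the delayed rebounds
#' produce the secondary peak and the dicrotic notch of the classic radial
#' waveform.
#'
#' @param amplitude_main main-wave peak amplitude (arbitrary pressure
#'   units, > 0).
#' @param amp_ratio_rebound1,amp_ratio_rebound2 rebound amplitudes as a
#'   fraction of the main amplitude, in \[0, 1).
#' @param delay_rebound1,delay_rebound2 arrival delays of the rebound
#'   waves after the main peak, seconds; must satisfy
#'   `0 < delay_rebound1 < delay_rebound2 < period`.
#' @param width_main,width_r1,width_r2 Gaussian widths (standard
#'   deviations) of the three components, seconds; each must be below
#'   `period / 2`.
#' @param period beat period, seconds (> 0).
#'
#' @return An object of class `beat_params` (a validated list).
#' @seealso [simulate_beat()], [simulate_record()], [bp_from_params()]
#' @export
#' @examples
#' p <- beat_params()
#' y <- simulate_beat(p, fs = 500)
#' plot(seq_along(y) / 500, y, type = "l", xlab = "s", ylab = "amplitude")
beat_params <- function(amplitude_main = 1,
                        amp_ratio_rebound1 = 0.5,
                        amp_ratio_rebound2 = 0.25,
                        delay_rebound1 = 0.22,
                        delay_rebound2 = 0.38,
                        width_main = 0.08,
                        width_r1 = 0.05,
                        width_r2 = 0.05,
                        period = 0.83) {
  check_scalar(amplitude_main, "amplitude_main", lower = 0, strict_lower = TRUE)
  check_scalar(amp_ratio_rebound1, "amp_ratio_rebound1", lower = 0)
  check_scalar(amp_ratio_rebound2, "amp_ratio_rebound2", lower = 0)
  if (amp_ratio_rebound1 >= 1 || amp_ratio_rebound2 >= 1) {
    stop_param("rebound amplitude ratios must be < 1")
  }
  check_scalar(period, "period", lower = 0, strict_lower = TRUE)
  check_scalar(delay_rebound1, "delay_rebound1", lower = 0, strict_lower = TRUE)
  check_scalar(delay_rebound2, "delay_rebound2", lower = 0, strict_lower = TRUE)
  if (!(delay_rebound1 < delay_rebound2 && delay_rebound2 < period)) {
    stop_param("delays must satisfy delay_rebound1 < delay_rebound2 < period")
  }
  for (w in c(width_main, width_r1, width_r2)) {
    check_scalar(w, "width", lower = 0, strict_lower = TRUE)
    if (w >= period / 2) stop_param("widths must be < period / 2")
  }
  structure(
    list(
      amplitude_main = amplitude_main,
      amp_ratio_rebound1 = amp_ratio_rebound1,
      amp_ratio_rebound2 = amp_ratio_rebound2,
      delay_rebound1 = delay_rebound1,
      delay_rebound2 = delay_rebound2,
      width_main = width_main,
      width_r1 = width_r1,
      width_r2 = width_r2,
      period = period
    ),
    class = "beat_params"
  )
}

# Evaluate the three-Gaussian beat shape at times `tau` (seconds) measured
# from beat onset. The main peak sits at 3 * width_main after onset so the
# waveform starts near zero.
beat_value <- function(params, tau) {
  tm <- 3 * params$width_main
  g <- function(mu, s) exp(-((tau - mu)^2) / (2 * s^2))
  params$amplitude_main * (
    g(tm, params$width_main) +
      params$amp_ratio_rebound1 * g(tm + params$delay_rebound1, params$width_r1) +
      params$amp_ratio_rebound2 * g(tm + params$delay_rebound2, params$width_r2)
  )
}

#' Simulate a single pulse beat
#'
#' Renders one beat period of the three-component superposition model at
#' sampling rate `fs`. With the default shape parameters the waveform shows
#' the main systolic peak followed by two later local maxima (the rebound
#' peaks), i.e. the characteristic points of a textbook radial pulse.
#'
#' @param params a [beat_params()] object.
#' @param fs sampling rate, Hz.
#' @return Numeric vector of `round(period * fs)` samples.
#' @export
simulate_beat <- function(params, fs) {
  if (!inherits(params, "beat_params")) params <- do.call(beat_params, params)
  check_scalar(fs, "fs", lower = 100)
  n <- round(params$period * fs)
  beat_value(params, (seq_len(n) - 1) / fs)
}

#' Specification of a synthetic pulse record
#'
#' Bundles everything needed to simulate a reproducible pulse-wave
#' recording: the beat shape, heart rate, respiration (an additive
#' sinusoidal baseline near 0.3 Hz), additive Gaussian noise, and
#' multiplicative log-normal beat-to-beat jitter on period and amplitude.
#'
#' @param heart_rate heart rate, Hz; must lie in \[0.5, 3.5\].
#' @param resp_rate respiratory rate, Hz; must be below `heart_rate`.
#' @param resp_amp respiration baseline amplitude as a fraction of the main
#'   wave amplitude.
#' @param noise_sd standard deviation of additive Gaussian noise, in
#'   amplitude units.
#' @param n_beats number of beats to simulate (>= 1).
#' @param fs sampling rate, Hz (>= 100).
#' @param seed integer RNG seed; records are bit-reproducible for a fixed
#'   spec.
#' @param beat_params a [beat_params()] object; its `period` is overridden
#'   by `1 / heart_rate`.
#' @param beat_jitter coefficient of variation of the per-beat log-normal
#'   jitter applied to period and amplitude.
#' @return An object of class `record_spec`.
#' @export
record_spec <- function(heart_rate = 1.2,
                        resp_rate = 0.3,
                        resp_amp = 0.05,
                        noise_sd = 0,
                        n_beats = 30,
                        fs = 500,
                        seed = 1,
                        beat_params = pulsebp::beat_params(),
                        beat_jitter = 0.02) {
  check_scalar(fs, "fs", lower = 100)
  check_scalar(heart_rate, "heart_rate", lower = 0.5, upper = 3.5)
  check_scalar(resp_rate, "resp_rate", lower = 0)
  if (resp_rate >= heart_rate) stop_param("resp_rate must be < heart_rate")
  check_scalar(resp_amp, "resp_amp", lower = 0)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  check_scalar(beat_jitter, "beat_jitter", lower = 0)
  if (!is.numeric(n_beats) || n_beats < 1) {
    stop_param("n_beats must be >= 1")
  }
  bp <- beat_params
  bp$period <- 1 / heart_rate
  # re-validate with the record period
  bp <- do.call(pulsebp::beat_params, unclass(bp))
  structure(
    list(
      heart_rate = heart_rate, resp_rate = resp_rate, resp_amp = resp_amp,
      noise_sd = noise_sd, n_beats = as.integer(n_beats), fs = fs,
      seed = seed, beat_params = bp, beat_jitter = beat_jitter
    ),
    class = "record_spec"
  )
}

#' Simulate a pulse-wave record
#'
#' Concatenates `n_beats` beats at the requested heart rate (with per-beat
#' log-normal jitter on period and amplitude), adds a sinusoidal
#' respiration baseline and white Gaussian noise, and attaches the ground
#' truth: SBP/DBP from [bp_from_params()], beat-onset sample indices, and
#' the per-beat jitter factors. For a noiseless, jitter-free record the
#' magnitude spectrum consists of lines at the heart rate and its
#' harmonics, plus the respiration line.
#'
#' @param spec a [record_spec()] object.
#' @return An object of class `pulse_record`: a list with elements
#'   `samples`, `fs`, and `truth` (list with `sbp`, `dbp`, `onsets`
#'   (1-based sample indices), `periods`, `amp_factors`, `beat_params`).
#' @export
simulate_record <- function(spec) {
  if (!inherits(spec, "record_spec")) spec <- do.call(record_spec, spec)
  bp <- spec$beat_params
  n_beats <- spec$n_beats

  res <- with_seed(spec$seed, {
    cv <- spec$beat_jitter
    if (cv > 0) {
      sdlog <- sqrt(log(1 + cv^2))
      per_f <- exp(stats::rnorm(n_beats, -sdlog^2 / 2, sdlog))
      amp_f <- exp(stats::rnorm(n_beats, -sdlog^2 / 2, sdlog))
    } else {
      per_f <- amp_f <- rep(1, n_beats)
    }
    periods <- bp$period * per_f
    onsets_t <- cumsum(c(0, periods[-n_beats]))
    total_t <- sum(periods)
    n <- round(total_t * spec$fs)
    t <- (seq_len(n) - 1) / spec$fs
    # half-sample tolerance so floating error in the onset times never
    # assigns a boundary sample to the previous beat
    bi <- findInterval(t + 0.5 / spec$fs, onsets_t)
    tau <- t - onsets_t[bi]
    y <- amp_f[bi] * beat_value(bp, tau)
    if (spec$resp_amp > 0) {
      y <- y + spec$resp_amp * bp$amplitude_main *
        sin(2 * pi * spec$resp_rate * t)
    }
    if (spec$noise_sd > 0) {
      y <- y + stats::rnorm(n, 0, spec$noise_sd)
    }
    list(y = y, onsets = floor(onsets_t * spec$fs) + 1L,
         periods = periods, amp_f = amp_f)
  })

  bpv <- bp_from_params(bp)
  structure(
    list(
      samples = res$y,
      fs = spec$fs,
      spec = spec,
      truth = list(
        sbp = bpv[["sbp"]], dbp = bpv[["dbp"]],
        onsets = res$onsets, periods = res$periods,
        amp_factors = res$amp_f, beat_params = bp
      )
    ),
    class = "pulse_record"
  )
}

#' @export
print.pulse_record <- function(x, ...) {
  cat(sprintf(
    "<pulse_record> %d samples @ %g Hz (%.1f s), %d beats",
    length(x$samples), x$fs, length(x$samples) / x$fs,
    length(x$truth$onsets)
  ))
  if (!is.null(x$truth$sbp)) {
    cat(sprintf(", truth %.1f/%.1f mmHg", x$truth$sbp, x$truth$dbp))
  }
  cat("\n")
  invisible(x)
}

#' Ground-truth blood pressure for a synthetic beat shape
#'
#' Deterministic smooth map from the generator parameters to a systolic /
#' diastolic pressure pair, used as the label source for synthetic
#' benchmarks. It is an anchored design choice, not a physiological model:
#' the reference shape (`beat_params()` defaults) maps to 120/80 mmHg, and
#' deviations of amplitude, rebound ratios, rebound delays and period move
#' the pressures along smooth bounded (tanh-squashed) response curves. The
#' drivers follow the qualitative direction of pulse-wave-analysis
#' practice: a stronger or earlier first rebound (stiffer arteries) raises
#' SBP; a slower heart rate lowers both pressures; the second rebound
#' contributes moderately to both.
#'
#' Guarantees, for every valid `beat_params`: SBP in (90, 145) mmHg, DBP in
#' (62.5, 92.5) mmHg, and pulse pressure SBP - DBP in (27.5, 52.5) mmHg.
#' SBP is strictly increasing in `amp_ratio_rebound1` when all other
#' parameters are held fixed.
#'
#' @param params a [beat_params()] object.
#' @return Named numeric vector `c(sbp = , dbp = )` in mmHg.
#' @export
#' @examples
#' bp_from_params(beat_params())   # the 120/80 anchor
bp_from_params <- function(params) {
  if (!inherits(params, "beat_params")) params <- do.call(beat_params, params)
  da <- params$amplitude_main - 1
  dr1 <- params$amp_ratio_rebound1 - 0.5
  dr2 <- params$amp_ratio_rebound2 - 0.25
  dd1 <- params$delay_rebound1 - 0.22
  dd2 <- params$delay_rebound2 - 0.38
  dT <- params$period - 0.83

  # pulse-pressure driver (rebound strength/timing dominated)
  g <- 3 * da + 16 * dr1 + 30 * dd1 + 22 * dr2 + 6 * dd2 - 12 * dT +
    4 * dr1 * da
  # diastolic driver (anchored so the reference shape gives DBP = 80)
  q0 <- 15 * atanh((80 - 77.5) / 15)
  q <- q0 + 1 * da + 7 * dr1 + 12 * dr2 + 5 * dd2 - 9 * dT

  dbp <- 77.5 + 15 * tanh(q / 15)
  gap <- 40 + 12.5 * tanh(g / 12.5)
  c(sbp = dbp + gap, dbp = dbp)
}

#' Simulate a sensor contact-pressure sweep
#'
#' Emulates the calibration protocol for finding the optimal contact
#' pressure (OP): the wrist-band force is stepped from 2 N to 14 N in
#' 0.5 N increments and at each level a thin piezoelectric film records 20
#' pressure samples. Within each level the arterial pulsation appears as
#' zero-mean excursions about the applied force whose size peaks when the
#' applied force matches the subject's true OP (too little force gives a
#' small pulse, too much flattens the artery and distorts it); the
#' excursion score decays as a Gaussian in the distance from the OP.
#'
#' @param subject a [subject_profile()] object, or a bare BMI value
#'   (kg/m^2).
#' @param levels applied-force levels in newtons; ascending, within
#'   \[2, 14\].
#' @param seed integer RNG seed.
#' @param noise_sd film readout noise, newtons.
#' @param pulse_gain peak pulsation excursion at the true OP, newtons.
#' @param pulse_sigma Gaussian width of the excursion-vs-force response,
#'   newtons.
#' @return A data.frame of class `pressure_sweep` with columns `level_N`,
#'   `sample_1` .. `sample_20`, and `quality` (the noise-free excursion
#'   score). The subject's true OP is attached as attribute `true_op`.
#' @export
simulate_pressure_sweep <- function(subject,
                                    levels = seq(2, 14, by = 0.5),
                                    seed = 1,
                                    noise_sd = 0.02,
                                    pulse_gain = 1.2,
                                    pulse_sigma = 1.2) {
  if (is.numeric(subject) && length(subject) == 1L) {
    subject <- subject_profile(bmi = subject)
  }
  if (!inherits(subject, "subject_profile")) {
    stop_param("subject must be a subject_profile or a BMI value")
  }
  if (length(levels) == 0L) stop_param("levels must be non-empty")
  if (any(diff(levels) <= 0)) stop_param("levels must be strictly ascending")
  if (min(levels) < 2 || max(levels) > 14) {
    stop_param("levels must lie within [2, 14] N")
  }
  op <- subject$op
  if (is.null(op) || !is.finite(op)) {
    stop_param("subject has no valid optimal pressure (BMI out of range?)")
  }

  # pulse excursions at samples 4/9/14/19 (+, -, +, -): zero-mean within a
  # level, isolated enough that a short running median ignores them
  pattern <- rep(0, 20)
  pattern[c(4, 14)] <- 1
  pattern[c(9, 19)] <- -1

  quality <- pulse_gain * exp(-((levels - op)^2) / (2 * pulse_sigma^2))
  samp <- with_seed(seed, {
    m <- outer(levels, rep(1, 20)) + outer(quality, pattern)
    if (noise_sd > 0) {
      m <- m + matrix(stats::rnorm(length(m), 0, noise_sd), nrow = length(levels))
    }
    m
  })
  out <- data.frame(level_N = levels, samp, quality = quality)
  names(out) <- c("level_N", paste0("sample_", 1:20), "quality")
  class(out) <- c("pressure_sweep", "data.frame")
  attr(out, "true_op") <- op
  out
}
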