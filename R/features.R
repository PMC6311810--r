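#' Column order of the fused feature vector
#'
#' Six time-domain morphological features followed by six frequency-domain
#' harmonic features.
#' @export
FEATURE_NAMES <- c("FC", "Sss", "Sds", "Tft", "Tst", "SL",
                   "A1", "A2", "A3", "P1", "P2", "P3")

#' Time-domain features of a single beat
#'
#' Computes the six morphological descriptors of one pulsation period.
#' All amplitudes are referenced to the signal value at the beat onset
#' `b`:
#' \describe{
#'   \item{FC}{`h / H`, the rebound-peak height `h` (at `e`) over the
#'     main-peak height `H` (at `c`).}
#'   \item{Sss, Sds}{systolic and diastolic area fractions: the
#'     trapezoidal area from `b` to the dicrotic notch `d` (systole, S1)
#'     and from `d` to the end of the beat (diastole, S2), each divided
#'     by S1 + S2. By construction `Sss + Sds == 1`.}
#'   \item{Tft}{systole duration over period: time from `b` to `d`
#'     divided by the beat period `T`.}
#'   \item{Tst}{upstroke time over period: time from `b` to the main peak
#'     `c` divided by `T`.}
#'   \item{SL}{maximum upstroke slope: largest first difference of the
#'     signal on `[b, c]`, in amplitude units per second.}
#' }
#'
#' @param beat a `beat` object.
#' @param fid its `fiducial_set` from [detect_fiducials()]; detected on
#'   the fly when omitted.
#' @return Named numeric vector with elements `FC, Sss, Sds, Tft, Tst,
#'   SL`.
#' @export
extract_time_features <- function(beat, fid = NULL) {
  if (is.null(fid)) fid <- detect_fiducials(beat)
  x <- beat$samples
  n <- length(x)
  fs <- beat$fs
  base <- x[fid$b]

  H <- x[fid$c] - base
  h <- x[fid$e] - base
  if (H <= 0 || fid$c == fid$b) stop_data("degenerate beat: no systolic rise")
  FC <- h / H

  y <- x - base
  S1 <- trapz_uniform(y[fid$b:fid$d], 1 / fs)
  S2 <- trapz_uniform(y[fid$d:n], 1 / fs)
  if (S1 + S2 == 0) stop_data("degenerate beat: zero total area")
  Sss <- S1 / (S1 + S2)
  Sds <- 1 - Sss      # == S2/(S1+S2); complement taken so the pair sums
                      # to 1 exactly in floating point

  Tt <- n / fs
  T1 <- (fid$c - fid$b) / fs
  Tf <- (fid$d - fid$b) / fs
  SL <- max(diff(x[fid$b:fid$c])) * fs

  c(FC = FC, Sss = Sss, Sds = Sds, Tft = Tf / Tt, Tst = T1 / Tt, SL = SL)
}

#' Frequency-domain features of a five-beat window
#'
#' Computes the FFT of a window spanning five complete pulsation cycles
#' (the longer window sharpens the frequency sampling to one fifth of the
#' heart rate) and reports the amplitudes and phases of the first three
#' characteristic spectral peaks. Characteristic peaks are local maxima of
#' the one-sided magnitude spectrum at frequencies of at least `min_freq`
#' (default 0.6 Hz), which excludes the respiration line near 0.3 Hz so
#' the first peak is the heart-rate fundamental and the next two are its
#' harmonics; candidates below 5% of the strongest peak are treated as
#' noise. The three retained peaks are ordered by frequency.
#'
#' Amplitudes are one-sided magnitudes normalized by window length
#' (`2 |X_k| / N`); phases are the raw principal arguments of the complex
#' coefficients, in (-pi, pi].
#'
#' If fewer than three clean peaks exist (e.g. a nearly sinusoidal
#' window), the result is flagged degenerate and the missing entries are
#' filled with the spectrum values at the corresponding multiples of the
#' estimated fundamental.
#'
#' @param window numeric vector covering exactly five onset-to-onset
#'   beats.
#' @param fs sampling rate, Hz.
#' @param n_beats number of beats the window is expected to span (used
#'   only to validate the window length), default 5.
#' @param min_freq lower edge, Hz, of the band searched for
#'   characteristic peaks.
#' @return Named numeric vector `A1, A2, A3, P1, P2, P3` with attributes
#'   `peak_freqs` (Hz) and `degenerate` (logical).
#' @export
extract_freq_features <- function(window, fs, n_beats = 5L, min_freq = 0.6) {
  check_scalar(fs, "fs", lower = 100)
  n <- length(window)
  # a 5-beat window at the slowest plausible heart rate (0.5 Hz) spans
  # 10 s; anything under n_beats periods at 3.5 Hz is certainly short
  if (n < n_beats / 3.5 * fs) {
    stop_data("window shorter than ", n_beats, " pulsation cycles")
  }
  X <- stats::fft(window)
  half <- floor(n / 2)
  k <- 2:(half + 1L)                      # skip DC
  freqs <- (k - 1L) * fs / n
  mag <- 2 * Mod(X[k]) / n

  band <- which(freqs >= min_freq)
  if (length(band) < 3L) stop_data("window too short: no cardiac band")
  ext <- local_extrema(c(0, mag[band], 0))
  peaks <- ext$maxima - 1L                # positions within `band`
  peaks <- peaks[peaks >= 1L & peaks <= length(band)]
  if (length(peaks)) {
    peaks <- peaks[mag[band][peaks] >= 0.05 * max(mag[band][peaks])]
  }

  degenerate <- length(peaks) < 3L
  if (!degenerate) {
    top <- peaks[order(mag[band][peaks], decreasing = TRUE)[1:3]]
    sel <- band[sort(top)]                # ordered by frequency
  } else {
    # fall back to bins at multiples of the estimated fundamental
    f0 <- if (length(peaks)) {
      freqs[band[peaks[which.max(mag[band][peaks])]]]
    } else {
      n_beats * fs / n                    # 5 beats per window
    }
    sel <- vapply(1:3, function(m) {
      which.min(abs(freqs - m * f0))
    }, integer(1))
  }

  ki <- k[sel]
  amps <- 2 * Mod(X[ki]) / n
  phases <- Arg(X[ki])
  out <- c(A1 = amps[1], A2 = amps[2], A3 = amps[3],
           P1 = phases[1], P2 = phases[2], P3 = phases[3])
  attr(out, "peak_freqs") <- freqs[sel]
  attr(out, "degenerate") <- degenerate
  out
}

#' Fused feature vectors for a pulse record
#'
#' Runs the full feature stage on a conditioned (or raw) record: segment
#' into beats, group consecutive beats into non-overlapping windows of
#' `beats_per_window` (default 5), and emit one 12-element fused vector
#' per window. Time features are computed per beat and averaged over the
#' window's beats so that both domains describe the same span; frequency
#' features come from the FFT of the window's samples. Each row also
#' carries the window's mean beat period and onset-referenced main-peak
#' amplitude, the raw quantities monitored by the threshold-matrix QC.
#'
#' @param record a `pulse_record`, or a bare numeric vector with `fs`.
#' @param fs sampling rate (only for bare vectors).
#' @param beats_per_window beats per analysis window.
#' @param condition if `TRUE` (default) apply [condition_signal()] first.
#' @return A data.frame with columns `window_id`,
#'   `FC,Sss,Sds,Tft,Tst,SL,A1,A2,A3,P1,P2,P3`, `period`, `amplitude`,
#'   `degenerate`.
#' @export
extract_features <- function(record, fs = NULL, beats_per_window = 5L,
                             condition = TRUE) {
  if (inherits(record, "pulse_record")) {
    x <- record$samples
    fs <- record$fs
  } else {
    if (is.null(fs)) stop_param("fs required when record is a bare vector")
    x <- as.numeric(record)
  }
  if (condition) x <- condition_signal(x, fs)
  beats <- segment_beats(x, fs)
  nb <- length(beats)
  n_win <- nb %/% beats_per_window
  if (n_win < 1L) {
    stop_data("record has ", nb, " complete beats; need at least ",
              beats_per_window, " for one window")
  }
  rows <- vector("list", n_win)
  for (w in seq_len(n_win)) {
    idx <- ((w - 1L) * beats_per_window + 1L):(w * beats_per_window)
    bt <- beats[idx]
    tf <- vapply(bt, function(b) {
      extract_time_features(b, detect_fiducials(b))
    }, numeric(6))
    tf_mean <- rowMeans(tf)
    span <- beats[[idx[1L]]]$onset_index:
      (beats[[idx[length(idx)]]]$onset_index +
         length(beats[[idx[length(idx)]]]$samples) - 1L)
    ff <- extract_freq_features(x[span], fs, n_beats = beats_per_window)
    amp <- mean(vapply(bt, function(b) max(b$samples) - b$samples[1L],
                       numeric(1)))
    rows[[w]] <- data.frame(
      window_id = w,
      as.list(tf_mean), as.list(ff[1:6]),
      period = mean(vapply(bt, `[[`, numeric(1), "period")),
      amplitude = amp,
      degenerate = attr(ff, "degenerate")
    )
  }
  out <- do.call(rbind, rows)
  stopifnot(identical(names(out)[2:13], FEATURE_NAMES))
  out
}
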