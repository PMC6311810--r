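#' Condition a raw pulse-wave signal
#'
#' Zero-phase band-pass filtering of the raw pressure-sensor signal. The
#' passband (default 0.15–25 Hz) keeps everything that carries pulse
#' information — the respiration line near 0.3 Hz, the heart-rate
#' fundamental and its harmonics, which decay into the noise floor above
#' about 10 Hz — while removing the DC offset, slow drift of the contact
#' force, and high-frequency sensor noise.
#'
#' The filter is applied in the frequency domain: the signal is mirrored
#' at both ends (to suppress wrap-around transients), transformed, and
#' multiplied by the squared magnitude response of a third-order
#' Butterworth band-pass — the response a forward-backward (filtfilt)
#' time-domain implementation would have, but exactly zero-phase and
#' numerically robust at the very small normalized low-frequency corner
#' (0.15 Hz at a 500 Hz rate), where sixth-order IIR transfer functions
#' lose precision. DC is removed exactly, fiducial timing is untouched,
#' and the operation is linear to machine precision.
#'
#' @param raw numeric vector of raw samples.
#' @param fs sampling rate, Hz.
#' @param band two-element passband in Hz.
#' @param order Butterworth order (applied twice, once per direction).
#' @return Filtered signal, same length as the input.
#' @export
condition_signal <- function(raw, fs, band = c(0.15, 25), order = 3) {
  check_scalar(fs, "fs", lower = 100)
  if (!is.numeric(raw) || !all(is.finite(raw))) {
    stop_param("raw must be a finite numeric vector")
  }
  n <- length(raw)
  if (n < 2 * fs) {
    stop_data("record too short for filter warm-up (need >= 2 s of data)")
  }
  if (band[2] >= fs / 2) stop_param("upper band edge must be below Nyquist")
  pad <- min(n, round(3 * fs))
  x <- c(rev(raw[seq_len(pad)]), raw, rev(raw[(n - pad + 1L):n]))
  # grow to a highly composite FFT length; constant (edge-value)
  # extension beyond the mirror pads avoids a step that the slow
  # high-pass tail would otherwise ring into the retained centre
  m <- stats::nextn(length(x), 2)
  x <- c(x, rep(x[length(x)], m - length(x)))
  f <- abs(seq(0, m - 1) * fs / m)
  f <- pmin(f, fs - f)                   # two-sided |frequency|
  lo2 <- ifelse(f == 0, 0, 1 / (1 + (band[1] / pmax(f, 1e-300))^(2 * order)))
  hi2 <- 1 / (1 + (f / band[2])^(2 * order))
  y <- Re(stats::fft(stats::fft(x) * lo2 * hi2, inverse = TRUE)) / m
  y[(pad + 1L):(pad + n)]
}

#' Segment a conditioned signal into beats
#'
#' Locates beat onsets at the foot of each systolic upstroke and cuts the
#' signal into half-open spans `[onset_i, onset_{i+1})`; the incomplete
#' trailing beat is discarded. Upstrokes are found as runs where the
#' smoothed derivative exceeds an adaptive threshold (a fraction of the
#' high quantile of the positive derivative), separated by a refractory
#' period; each onset is the minimum of the signal in a short window
#' before the maximum-slope point.
#'
#' @param signal conditioned numeric signal (see [condition_signal()]).
#' @param fs sampling rate, Hz.
#' @param min_period,max_period accepted beat period range, seconds.
#' @return List of `beat` objects: each a list with `samples`, `fs`,
#'   `onset_index` (1-based position in the parent signal) and `period`
#'   (seconds).
#' @export
segment_beats <- function(signal, fs, min_period = 0.3, max_period = 2) {
  check_scalar(fs, "fs", lower = 100)
  n <- length(signal)
  if (n < 2 * fs) stop_data("signal too short to contain 2 beats")

  # periodicity gate: a pulse train must show a strong autocorrelation
  # peak at some lag in the accepted beat-period range
  xc <- signal - mean(signal)
  if (stats::sd(xc) < .Machine$double.eps * 100) {
    stop_data("no periodicity detected: signal is flat")
  }
  lag_max <- min(n - 1L, round(max_period * fs))
  # autocorrelation via the Wiener-Khinchin identity (much faster than a
  # direct lag loop at these record lengths)
  mfft <- stats::nextn(n + lag_max, 2)
  Fx <- stats::fft(c(xc, rep(0, mfft - n)))
  ac_raw <- Re(stats::fft(Mod(Fx)^2, inverse = TRUE))[1:(lag_max + 1L)]
  ac <- ac_raw / ac_raw[1L]
  lag_lo <- round(min_period * fs)
  if (lag_lo + 1L > length(ac) || max(ac[(lag_lo + 1L):length(ac)]) < 0.2) {
    stop_data("no periodicity detected (flat or pure-noise signal)")
  }
  # dominant beat period in samples, used as the pacing grid below
  T0 <- which.max(ac[(lag_lo + 1L):length(ac)]) + lag_lo - 1L

  # smoothed first derivative (moving average over ~40 ms)
  d <- diff(signal) * fs
  k <- max(3L, round(0.04 * fs))
  d <- as.numeric(stats::filter(d, rep(1 / k, k), sides = 2))
  d[is.na(d)] <- 0
  thr <- 0.4 * stats::quantile(d, 0.98, names = FALSE)
  if (!is.finite(thr) || thr <= 0) stop_data("no pulsatile upstrokes detected")
  above <- d > thr

  # contiguous above-threshold runs -> candidate upstrokes
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  if (length(runs) < 2L) stop_data("fewer than 2 upstrokes detected")
  slope_pts <- vapply(runs, function(i) {
    s <- starts[i]; e <- ends[i]
    s + which.max(d[s:e]) - 1L
  }, integer(1))

  # pace candidate upstrokes on the autocorrelation period grid: anchor
  # at the steepest upstroke and walk outward accepting, in each window
  # of 0.7–1.35 beat periods from the last accepted point, the steepest
  # candidate. This rejects rebound-wave upstrokes (which arrive at a
  # sub-period delay after the systolic upstroke) without a hard
  # refractory that would fail at high heart rates.
  slope_pts <- sort(unique(slope_pts))
  anchor <- slope_pts[which.max(d[slope_pts])]
  walk <- function(from, cands, step) {
    sel <- integer(0)
    last <- from
    repeat {
      gap <- step * (cands - last)
      win <- cands[gap >= 0.7 * T0 & gap <= 1.35 * T0]
      if (!length(win)) {
        beyond <- cands[gap > 1.35 * T0]
        if (!length(beyond)) break
        nxt <- if (step > 0) min(beyond) else max(beyond)  # resync after gap
      } else {
        nxt <- win[which.max(d[win])]
      }
      sel <- c(sel, nxt)
      last <- nxt
    }
    sel
  }
  keep <- sort(c(
    walk(anchor, slope_pts[slope_pts < anchor], -1L),
    anchor,
    walk(anchor, slope_pts[slope_pts > anchor], +1L)
  ))
  if (length(keep) < 2L) stop_data("fewer than 2 beats detected")

  # onset: the foot of the upstroke. Locate the pre-upstroke minimum on
  # a lightly smoothed copy (the raw minimum wanders in the flat
  # inter-beat trough under noise), then step forward to the first
  # crossing of a small fraction of the local rise — the point where the
  # wave visibly leaves its trough.
  ks <- max(3L, round(0.04 * fs))
  xs <- as.numeric(stats::filter(signal, rep(1 / ks, ks), sides = 2))
  xs[is.na(xs)] <- signal[is.na(xs)]
  back <- as.integer(round(0.25 * fs))
  onsets <- vapply(keep, function(p) {
    s <- max(1L, p - back)
    m <- s + which.min(xs[s:p]) - 1L
    if (m >= p) return(m)
    lev <- xs[m] + 0.02 * (xs[p] - xs[m])
    above <- which(xs[m:p] > lev)
    if (!length(above)) return(m)
    m + above[1L] - 1L
  }, integer(1))
  onsets <- unique(onsets)

  beats <- vector("list", length(onsets) - 1L)
  jj <- 0L
  for (i in seq_len(length(onsets) - 1L)) {
    span <- onsets[i]:(onsets[i + 1L] - 1L)
    period <- length(span) / fs
    if (period < min_period || period > max_period) next
    jj <- jj + 1L
    beats[[jj]] <- structure(
      list(samples = signal[span], fs = fs,
           onset_index = onsets[i], period = period),
      class = "beat"
    )
  }
  beats <- beats[seq_len(jj)]
  if (length(beats) == 0L) stop_data("no beats within accepted period range")
  beats
}
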