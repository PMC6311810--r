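# local extrema of a numeric vector (interior strict sign changes of the
# first difference; plateaus resolved to their first sample)
local_extrema <- function(x) {
  dx <- diff(x)
  dx_nz <- dx
  # carry the previous non-zero slope through plateaus
  if (any(dx_nz == 0)) {
    for (i in seq_along(dx_nz)) {
      if (dx_nz[i] == 0 && i > 1L) dx_nz[i] <- dx_nz[i - 1L]
    }
  }
  s <- sign(dx_nz)
  turn <- which(s[-1L] != s[-length(s)]) + 1L
  list(
    maxima = turn[s[turn] < 0],
    minima = turn[s[turn] > 0]
  )
}

#' Detect the characteristic fiducial points of a beat
#'
#' Locates the classic pulse-wave landmarks inside one beat: `b` the beat
#' onset (wave foot), `c` the main systolic peak, `d` the dicrotic
#' notch/trough after the main peak, `e` the first rebound peak, and the
#' optional second rebound trough/peak pair `f`, `g`. In young, elastic
#' arteries the rebound waves can be submerged in the main wave; when no
#' trough exists after the main peak, `d` falls back to the maximum of the
#' second derivative after `c` (the strongest concavity change) and `e` is
#' flagged as inferred at the same location. `f`/`g` are only reported
#' when the second rebound peak rises at least `prominence_floor` of the
#' main-peak height above its preceding trough.
#'
#' @param beat a `beat` object from [segment_beats()], or a bare numeric
#'   vector with `fs` supplied.
#' @param fs sampling rate, needed only when `beat` is a bare vector.
#' @param prominence_floor minimum height of the `g` peak above the `f`
#'   trough, as a fraction of the onset-referenced main-peak height.
#' @return An object of class `fiducial_set`: list with 1-based in-beat
#'   sample indices `b`, `c`, `d`, `e` (and `f`, `g` when present, else
#'   `NA`) plus a `flags` character vector (any of `"e_inferred"`,
#'   `"fg_absent"`). Indices satisfy `b < c < d <= e` and `f < g` when
#'   present.
#' @export
detect_fiducials <- function(beat, fs = NULL, prominence_floor = 0.02) {
  if (is.numeric(beat)) {
    if (is.null(fs)) stop_param("fs required when beat is a bare vector")
    beat <- structure(list(samples = beat, fs = fs, onset_index = 1L,
                           period = length(beat) / fs), class = "beat")
  }
  x <- beat$samples
  n <- length(x)
  if (n < 5L) stop_data("beat too short for fiducial detection")

  b <- 1L
  c_idx <- which.max(x)
  if (c_idx <= 1L || c_idx >= n) {
    stop_data("beat has no interior maximum")
  }

  ext <- local_extrema(x)
  minima_after_c <- ext$minima[ext$minima > c_idx & ext$minima < n]
  maxima_after_c <- ext$maxima[ext$maxima > c_idx & ext$maxima < n]
  flags <- character(0)

  # the dicrotic notch lives in the earlier part of diastole; troughs in
  # the last quarter of the post-peak span are end-of-beat artifacts,
  # and a "notch" shallower than 1% of the pulse height is noise —
  # either way the rebound is submerged and the fallback applies
  H0 <- x[c_idx] - x[1L]
  notch_window <- c_idx + 0.75 * (n - c_idx)
  cand <- minima_after_c[minima_after_c <= notch_window]

  if (length(cand) > 0L) {
    # most prominent trough: deepest relative to the smaller flanking peak
    prom <- vapply(cand, function(m) {
      left_pk <- max(x[c_idx:m])
      right <- maxima_after_c[maxima_after_c > m]
      right_pk <- if (length(right)) x[right[1L]] else x[m]
      min(left_pk, right_pk) - x[m]
    }, numeric(1))
    if (max(prom) < 0.01 * H0) cand <- integer(0)
  }

  if (length(cand) > 0L) {
    d_idx <- cand[which.max(prom)]
    e_cand <- maxima_after_c[maxima_after_c > d_idx]
    if (length(e_cand) > 0L) {
      e_idx <- e_cand[1L]
    } else {
      e_idx <- d_idx
      flags <- c(flags, "e_inferred")
    }
  } else {
    # submerged rebound: strongest concavity change after the main peak
    if (c_idx + 3L > n - 1L) stop_data("beat too short after main peak")
    d2 <- diff(x, differences = 2)
    seg <- (c_idx + 1L):min(n - 2L, as.integer(round(notch_window)))
    d_idx <- seg[which.max(d2[seg])] + 1L
    e_idx <- d_idx
    flags <- c(flags, "e_inferred")
  }

  f_idx <- NA_integer_
  g_idx <- NA_integer_
  H <- x[c_idx] - x[b]
  later_min <- minima_after_c[minima_after_c > e_idx]
  if (length(later_min) > 0L && H > 0) {
    fm <- later_min[1L]
    gm <- maxima_after_c[maxima_after_c > fm]
    if (length(gm) > 0L && (x[gm[1L]] - x[fm]) >= prominence_floor * H) {
      f_idx <- fm
      g_idx <- gm[1L]
    }
  }
  if (is.na(f_idx)) flags <- c(flags, "fg_absent")

  structure(
    list(b = b, c = c_idx, d = d_idx, e = e_idx,
         f = f_idx, g = g_idx, flags = flags),
    class = "fiducial_set"
  )
}

#' @export
print.fiducial_set <- function(x, ...) {
  cat(sprintf("<fiducial_set> b=%d c=%d d=%d e=%d f=%s g=%s",
              x$b, x$c, x$d, x$e,
              ifelse(is.na(x$f), "-", x$f), ifelse(is.na(x$g), "-", x$g)))
  if (length(x$flags)) cat("  [", paste(x$flags, collapse = ", "), "]")
  cat("\n")
  invisible(x)
}
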