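#' Body mass index
#'
#' @param weight body weight, kg (> 0).
#' @param height body height, m (> 0).
#' @return BMI in kg/m^2: `weight / height^2`.
#' @export
#' @examples
#' compute_bmi(70, 1.75)
compute_bmi <- function(weight, height) {
  check_scalar(weight, "weight", lower = 0, strict_lower = TRUE)
  check_scalar(height, "height", lower = 0, strict_lower = TRUE)
  weight / height^2
}

# calibration cubic relating BMI to optimal sensor contact pressure,
# descending powers of BMI; fitted on a 30-subject sweep study
op_cubic_coefficients <- c(-0.0114, 0.7302, -15.0889, 104.4144)

#' Optimal sensor contact pressure from BMI
#'
#' Evaluates the cubic calibration curve
#' `OP = -0.0114 BMI^3 + 0.7302 BMI^2 - 15.0889 BMI + 104.4144` (newtons)
#' relating body mass index to the wrist-band force at which the
#' piezoresistive sensor captures the most detailed radial pulse waveform.
#' The curve is close to linear below a BMI of 24 and saturates above it
#' (24 is the local overweight threshold), so a warning is issued for
#' BMI > 24 where the calibration is less trustworthy.
#'
#' @param bmi body mass index, kg/m^2.
#' @param valid_range BMI interval over which the curve is accepted;
#'   values outside raise an error.
#' @return Optimal contact pressure in newtons.
#' @export
#' @examples
#' optimal_pressure(22)   # 4.4882 N
optimal_pressure <- function(bmi, valid_range = c(16, 30)) {
  check_scalar(bmi, "bmi", lower = 0, strict_lower = TRUE)
  if (bmi < valid_range[1] || bmi > valid_range[2]) {
    stop_param("bmi ", bmi, " outside calibration validity range [",
               valid_range[1], ", ", valid_range[2], "]")
  }
  if (bmi > 24) {
    warning("OP curve saturates above BMI 24; calibration less reliable",
            call. = FALSE)
  }
  drop(op_cubic_coefficients %*% bmi^(3:0))
}

#' Subject profile with derived BMI and optimal pressure
#'
#' @param weight body weight, kg. Ignored if `bmi` is given directly.
#' @param height body height, m.
#' @param bmi body mass index; computed from weight and height when absent.
#' @return An object of class `subject_profile` with fields `weight`,
#'   `height`, `bmi` and `op` (newtons; `NA` when the BMI falls outside
#'   the calibration curve's validity range).
#' @export
subject_profile <- function(weight = NULL, height = NULL, bmi = NULL) {
  if (is.null(bmi)) {
    if (is.null(weight) || is.null(height)) {
      stop_param("supply either bmi or both weight and height")
    }
    bmi <- compute_bmi(weight, height)
  } else {
    check_scalar(bmi, "bmi", lower = 0, strict_lower = TRUE)
  }
  op <- tryCatch(
    suppressWarnings(optimal_pressure(bmi)),
    pulsebp_param_error = function(e) NA_real_
  )
  structure(
    list(weight = weight, height = height, bmi = bmi, op = op),
    class = "subject_profile"
  )
}

#' Running-median baseline of a pressure series
#'
#' Fits the slowly-varying baseline of a film pressure recording with a
#' running median, which tracks the applied force while rejecting the
#' brief pulsation excursions. Series ends are handled by replicating the
#' first and last values so the output has the same length as the input.
#'
#' @param pressure_series numeric vector of pressure samples (newtons).
#' @param window odd window length in samples, between 1 and
#'   `length(pressure_series)`.
#' @return Numeric vector of baseline values, same length as the input.
#' @export
fit_baseline <- function(pressure_series, window = 5L) {
  n <- length(pressure_series)
  if (n == 0L) stop_param("pressure_series must be non-empty")
  if (!is.numeric(window) || length(window) != 1L || window %% 2 == 0) {
    stop_param("window must be an odd integer")
  }
  window <- as.integer(window)
  if (window < 1L || window > n) stop_param("window must be in [1, length]")
  if (window == 1L) return(as.numeric(pressure_series))
  h <- (window - 1L) %/% 2L
  padded <- c(rep(pressure_series[1L], h), pressure_series,
              rep(pressure_series[n], h))
  # interior positions of runmed use full windows; ends come from padding
  stats::runmed(padded, window, endrule = "keep")[(h + 1L):(h + n)]
}

#' Select the optimal level from a contact-pressure sweep
#'
#' Implements the sweep-analysis rule: concatenate all per-level film
#' samples in level order, fit the baseline with a running median, find
#' the sample with the largest absolute difference between pressure and
#' baseline (the strongest pulsation excursion), and report the baseline
#' value there together with the force level it belongs to. Ties are
#' broken toward the lower level, the safer and more comfortable contact
#' force.
#'
#' @param sweep a `pressure_sweep` data.frame (see
#'   [simulate_pressure_sweep()]): column `level_N` plus one column per
#'   within-level sample.
#' @param window running-median window passed to [fit_baseline()].
#' @return List with `level` (newtons, the grid level containing the
#'   maximizing sample), `baseline_value` (newtons) and `max_excursion`
#'   (newtons).
#' @export
select_optimal_level <- function(sweep, window = 5L) {
  if (!is.data.frame(sweep) || !"level_N" %in% names(sweep)) {
    stop_param("sweep must be a data.frame with a level_N column")
  }
  if (nrow(sweep) < 2L) stop_param("sweep must contain at least 2 levels")
  sample_cols <- grep("^sample_", names(sweep))
  if (length(sample_cols) == 0L) stop_param("sweep has no sample_* columns")
  m <- as.matrix(sweep[, sample_cols, drop = FALSE])
  series <- as.numeric(t(m))            # level-major concatenation
  base <- fit_baseline(series, window)
  excursion <- abs(series - base)
  idx <- which.max(excursion)           # first maximum -> lowest level
  level_idx <- (idx - 1L) %/% ncol(m) + 1L
  list(
    level = sweep$level_N[level_idx],
    baseline_value = base[idx],
    max_excursion = excursion[idx]
  )
}

#' Fit a cubic optimal-pressure calibration curve
#'
#' Least-squares third-order polynomial fit of optimal contact pressure
#' against BMI across subjects, the cross-subject step of the sweep
#' calibration protocol.
#'
#' @param bmis BMI values, kg/m^2 (at least 4 distinct values).
#' @param op_values per-subject optimal pressures, newtons.
#' @return An object of class `op_curve`: list with `coefficients`
#'   (length 4, descending powers), `fit_domain` (BMI range of the data)
#'   and `residuals` (newtons).
#' @export
fit_op_curve <- function(bmis, op_values) {
  if (length(bmis) != length(op_values)) {
    stop_param("bmis and op_values must have equal length")
  }
  if (length(unique(bmis)) < 4L) {
    stop_param("need at least 4 distinct BMI values for a cubic fit")
  }
  fit <- stats::lm(op_values ~ poly(bmis, 3, raw = TRUE))
  cf <- rev(unname(stats::coef(fit)))   # descending degree
  if (anyNA(cf)) stop_param("degenerate design: cubic fit is rank-deficient")
  structure(
    list(
      coefficients = cf,
      fit_domain = range(bmis),
      residuals = unname(stats::residuals(fit))
    ),
    class = "op_curve"
  )
}

#' Evaluate a fitted optimal-pressure curve
#'
#' @param object an `op_curve` from [fit_op_curve()].
#' @param bmi BMI values at which to evaluate.
#' @param ... unused.
#' @return Predicted optimal pressures, newtons.
#' @export
predict.op_curve <- function(object, bmi, ...) {
  drop(outer(bmi, 3:0, "^") %*% object$coefficients)
}

#' @export
print.op_curve <- function(x, ...) {
  cat("<op_curve> OP(BMI) =",
      sprintf("%+.6g BMI^%d", x$coefficients, 3:0), "\n")
  cat(sprintf("  fit domain BMI [%.3g, %.3g], RMS residual %.4g N\n",
              x$fit_domain[1], x$fit_domain[2],
              sqrt(mean(x$residuals^2))))
  invisible(x)
}
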