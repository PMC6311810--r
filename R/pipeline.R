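#' Feature columns belonging to each domain
#'
#' @param domains one of `"both"`, `"time"`, `"freq"`.
#' @return Character vector of feature column names.
#' @export
domain_columns <- function(domains = c("both", "time", "freq")) {
  domains <- match.arg(domains)
  switch(domains,
         both = FEATURE_NAMES,
         time = FEATURE_NAMES[1:6],
         freq = FEATURE_NAMES[7:12])
}

#' Generate a synthetic blood-pressure benchmark dataset
#'
#' Simulates `n_records` independent pulse recordings, each with its own
#' beat shape drawn from documented physiological ranges, and runs every
#' one through the real measurement pipeline (band-pass conditioning,
#' beat segmentation, fiducial detection, feature extraction) to obtain
#' one fused 12-feature window per record. Labels are the generator's
#' ground-truth pressures plus Gaussian reference noise mimicking the
#' reading error of an oscillometric cuff.
#'
#' Per-record beat-shape draws (uniform): main amplitude 0.7–1.3, first
#' rebound ratio 0.3–0.7, second rebound ratio 0.1–0.4, first rebound
#' delay 0.18–0.28 s, second delay = first + 0.12–0.20 s, heart rate
#' 0.9–1.5 Hz; component widths scale with the period so morphology stays
#' comparable across heart rates. Records carry 0.3 Hz respiration at 5%
#' of the main amplitude, 1% additive noise and 2% beat-to-beat jitter —
#' the generator defaults.
#'
#' On top of the physiological amplitude, each record receives an
#' independent multiplicative sensor-coupling gain (log-normal, 10%
#' coefficient of variation): the recorded excursion depends on how the
#' sensor sits on the wrist and on the applied contact force — the very
#' variability the BMI-based optimal-pressure calibration exists to tame —
#' so absolute recorded amplitude is not a reliable correlate of blood
#' pressure. The gain scales the waveform only; labels come from the
#' physiological parameters.
#'
#' @param n_records number of recordings (one 5-beat window each).
#' @param seed master integer seed; all per-record seeds derive from it.
#' @param label_noise_sd reference-label noise, mmHg.
#' @param fs simulation sampling rate, Hz.
#' @param n_beats beats per simulated record (needs >= 7 to guarantee one
#'   complete 5-beat window after segmentation).
#' @return List of class `bp_dataset`: `features` (QC-accepted feature
#'   data.frame), `labels` (noisy mmHg matrix), `labels_clean`,
#'   `params` (per-record beat parameters), `qc_report`, `n_failed`
#'   (records the pipeline could not process).
#' @export
make_bp_dataset <- function(n_records = 1200, seed = 1,
                            label_noise_sd = 0.5, fs = 250, n_beats = 7L) {
  if (n_records < 1) stop_param("n_records must be >= 1")
  draws <- with_seed(seed, {
    list(
      amp = stats::runif(n_records, 0.7, 1.3),
      r1 = stats::runif(n_records, 0.3, 0.7),
      r2 = stats::runif(n_records, 0.1, 0.4),
      d1 = stats::runif(n_records, 0.18, 0.28),
      dgap = stats::runif(n_records, 0.12, 0.20),
      hr = stats::runif(n_records, 0.9, 1.5),
      gain = exp(stats::rnorm(n_records, 0, sqrt(log(1 + 0.1^2)))),
      rec_seed = sample.int(.Machine$integer.max - 1L, n_records),
      label_eps = matrix(stats::rnorm(2L * n_records, 0, label_noise_sd),
                         ncol = 2L)
    )
  })

  feats <- vector("list", n_records)
  labels <- matrix(NA_real_, n_records, 2L,
                   dimnames = list(NULL, c("sbp", "dbp")))
  labels_clean <- labels
  params <- vector("list", n_records)
  n_failed <- 0L
  for (i in seq_len(n_records)) {
    period <- 1 / draws$hr[i]
    wscale <- period / 0.83
    bp <- beat_params(
      amplitude_main = draws$amp[i],
      amp_ratio_rebound1 = draws$r1[i],
      amp_ratio_rebound2 = draws$r2[i],
      delay_rebound1 = draws$d1[i],
      delay_rebound2 = draws$d1[i] + draws$dgap[i],
      width_main = 0.08 * wscale,
      width_r1 = 0.05 * wscale,
      width_r2 = 0.05 * wscale,
      period = period
    )
    bp_rec <- bp
    bp_rec$amplitude_main <- bp$amplitude_main * draws$gain[i]
    spec <- record_spec(
      heart_rate = draws$hr[i], noise_sd = 0.01 * bp_rec$amplitude_main,
      n_beats = n_beats, fs = fs, seed = draws$rec_seed[i],
      beat_params = bp_rec
    )
    rec <- simulate_record(spec)
    row <- tryCatch(
      extract_features(rec)[1L, , drop = FALSE],
      error = function(e) NULL
    )
    if (is.null(row)) {
      n_failed <- n_failed + 1L
      next
    }
    feats[[i]] <- row
    labels_clean[i, ] <- bp_from_params(bp)   # physiological, gain-free
    labels[i, ] <- labels_clean[i, ] + draws$label_eps[i, ]
    params[[i]] <- bp
  }
  ok <- !vapply(feats, is.null, logical(1))
  features <- do.call(rbind, feats[ok])
  features$record_id <- which(ok)
  qc <- qc_filter(features, threshold_matrix())
  keep <- qc$accepted$record_id
  structure(
    list(
      features = qc$accepted,
      labels = labels[keep, , drop = FALSE],
      labels_clean = labels_clean[keep, , drop = FALSE],
      params = params[keep],
      qc_report = qc$report,
      n_failed = n_failed
    ),
    class = "bp_dataset"
  )
}

#' Train and evaluate a blood-pressure model on a feature dataset
#'
#' Convenience wrapper tying together the modelling stages: select the
#' requested feature domain(s), split 70/15/15, fit the normalization on
#' the training split, train the network with validation early stopping,
#' and evaluate on the held-out test split.
#'
#' @param features feature data.frame (QC-accepted).
#' @param labels mmHg target matrix (columns SBP, DBP), one row per
#'   feature row.
#' @param domains `"both"` (12 inputs), `"time"` or `"freq"` (6 inputs).
#' @param fractions train/validation/test fractions.
#' @param seed integer seed for the split and weight initialization.
#' @param hidden hidden-layer width.
#' @param ... further arguments to [train_ann()].
#' @return List of class `bp_fit`: `model`, `split`, `evaluation`,
#'   `domains`.
#' @export
fit_bp_model <- function(features, labels, domains = "both",
                         fractions = c(0.7, 0.15, 0.15), seed = 1,
                         hidden = 30L, ...) {
  cols <- domain_columns(domains)
  X <- as.matrix(features[, cols, drop = FALSE])
  y <- as.matrix(labels)
  if (nrow(X) != nrow(y)) stop_param("features and labels disagree in length")
  sp <- split_data(nrow(X), fractions, seed = seed)
  norm <- normalize_fit(X[sp$train, , drop = FALSE])
  Xtr <- norm$X
  Xval <- normalize_apply(norm, X[sp$validation, , drop = FALSE])
  Xte <- normalize_apply(norm, X[sp$test, , drop = FALSE])
  model <- train_ann(Xtr, y[sp$train, ], Xval, y[sp$validation, ],
                     hidden = hidden, seed = seed, norm = norm, ...)
  model$feature_names <- cols
  ev <- evaluate_model(model, Xte, y[sp$test, , drop = FALSE],
                       normalized = TRUE)
  structure(list(model = model, split = sp, evaluation = ev,
                 domains = domains), class = "bp_fit")
}

#' Run the full estimation pipeline on pulse records
#'
#' End-to-end driver: condition each record, segment, detect fiducials,
#' extract fused feature windows, apply threshold-matrix QC, then train
#' and evaluate the network against the supplied reference pressures
#' (each record's label is attached to all of its windows). Per-stage
#' counts are reported.
#'
#' @param records list of `pulse_record` objects (or paths readable by
#'   [read_record()]).
#' @param labels mmHg matrix/data.frame with one (SBP, DBP) row per
#'   record.
#' @param config list of options: `beats_per_window` (5), `fractions`
#'   (0.7/0.15/0.15), `seed` (1), `hidden` (30), `domains` ("both"), and
#'   any [train_ann()] argument.
#' @return List of class `bp_pipeline_report`: `fit` (a `bp_fit`),
#'   `counts` (per-stage), `qc_report`.
#' @export
run_pipeline <- function(records, labels, config = list()) {
  cfg <- utils::modifyList(
    list(beats_per_window = 5L, fractions = c(0.7, 0.15, 0.15),
         seed = 1, hidden = 30L, domains = "both"),
    config
  )
  labels <- as.matrix(labels)
  if (length(records) != nrow(labels)) {
    stop_param("need one label row per record")
  }
  feats <- vector("list", length(records))
  for (i in seq_along(records)) {
    rec <- records[[i]]
    if (is.character(rec)) rec <- read_record(rec)
    fw <- tryCatch(
      extract_features(rec, beats_per_window = cfg$beats_per_window),
      error = function(e) {
        stop_data("record ", i, ": ", conditionMessage(e))
      }
    )
    fw$record_id <- i
    feats[[i]] <- fw
  }
  all_feats <- do.call(rbind, feats)
  qc <- qc_filter(all_feats, threshold_matrix())
  acc <- qc$accepted
  y <- labels[acc$record_id, , drop = FALSE]
  fit <- fit_bp_model(acc, y, domains = cfg$domains,
                      fractions = cfg$fractions, seed = cfg$seed,
                      hidden = cfg$hidden)
  structure(
    list(
      fit = fit,
      counts = c(records = length(records),
                 windows = nrow(all_feats),
                 accepted = nrow(acc),
                 rejected = nrow(all_feats) - nrow(acc),
                 train = length(fit$split$train),
                 validation = length(fit$split$validation),
                 test = length(fit$split$test)),
      qc_report = qc$report
    ),
    class = "bp_pipeline_report"
  )
}

#' @export
print.bp_pipeline_report <- function(x, ...) {
  cat("<bp_pipeline_report>\n  counts:",
      paste(names(x$counts), x$counts, sep = "=", collapse = " "), "\n")
  print(x$fit$evaluation)
  invisible(x)
}
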