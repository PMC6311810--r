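# CSV/JSON readers and writers for the artifacts exchanged between
# pipeline stages. All floats are serialized at full double precision.

#' Write a pulse record to CSV (with an optional truth sidecar)
#'
#' The record dialect is a small CSV: metadata lines `fs,<Hz>` and
#' `seed,<int>` first, then an `amplitude` header and one sample per
#' line. Ground truth, when present, goes to `<path>.truth.json`.
#'
#' @param record a `pulse_record`.
#' @param path output CSV path.
#' @param truth write the truth sidecar if the record carries truth?
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path, truth = TRUE) {
  con <- file(path, "w")
  on.exit(close(con))
  seed <- if (!is.null(record$spec)) record$spec$seed else NA
  writeLines(c(
    sprintf("fs,%s", format(record$fs, digits = 17)),
    sprintf("seed,%s", seed),
    "amplitude",
    format(record$samples, digits = 17, trim = TRUE, scientific = FALSE)
  ), con)
  if (truth && !is.null(record$truth)) {
    tr <- record$truth
    tr$beat_params <- unclass(tr$beat_params)
    jsonlite::write_json(tr, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a pulse record from CSV
#'
#' @param path CSV path in the [write_record()] dialect.
#' @return A `pulse_record` (with `truth` when the sidecar exists).
#' @export
read_record <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 4L || !startsWith(lines[1L], "fs,")) {
    stop_data("line 1: expected 'fs,<sampling rate>' header in ", path)
  }
  fs <- suppressWarnings(as.numeric(sub("^fs,", "", lines[1L])))
  if (!is.finite(fs)) stop_data("line 1: unparseable sampling rate in ", path)
  i <- 2L
  if (startsWith(lines[i], "seed,")) i <- i + 1L
  if (lines[i] != "amplitude") {
    stop_data("line ", i, ": expected 'amplitude' column header in ", path)
  }
  samples <- suppressWarnings(as.numeric(lines[(i + 1L):length(lines)]))
  if (anyNA(samples)) {
    bad <- which(is.na(samples))[1L] + i
    stop_data("line ", bad, ": unparseable sample value in ", path)
  }
  truth <- NULL
  sidecar <- paste0(path, ".truth.json")
  if (file.exists(sidecar)) {
    truth <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    truth$onsets <- as.integer(truth$onsets)
  }
  structure(list(samples = samples, fs = fs, truth = truth),
            class = "pulse_record")
}

#' Write / read a contact-pressure sweep table
#' @param sweep a `pressure_sweep` data.frame.
#' @param path CSV path.
#' @return `path` (write) or the sweep data.frame (read), with class
#'   `pressure_sweep` restored.
#' @export
write_sweep <- function(sweep, path) {
  utils::write.csv(as.data.frame(sweep), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sweep
#' @export
read_sweep <- function(path) {
  out <- utils::read.csv(path)
  if (!"level_N" %in% names(out)) {
    stop_data("sweep CSV must have a level_N column: ", path)
  }
  class(out) <- c("pressure_sweep", "data.frame")
  out
}

#' Write / read feature windows
#' @param vectors feature data.frame from [extract_features()].
#' @param path CSV path.
#' @export
write_features <- function(vectors, path) {
  utils::write.csv(vectors, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  out <- utils::read.csv(path)
  missing_cols <- setdiff(FEATURE_NAMES, names(out))
  if (length(missing_cols)) {
    stop_data("feature CSV missing column(s): ",
              paste(missing_cols, collapse = ", "))
  }
  out
}

#' Read reference blood-pressure labels
#'
#' Accepts a CSV with `sbp,dbp` columns, or a headerless two-column file
#' where each row is `SBP,DBP` in mmHg.
#'
#' @param path CSV path.
#' @return Numeric matrix with columns `sbp`, `dbp`.
#' @export
read_labels <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("[A-Za-z]", first)
  df <- utils::read.csv(path, header = has_header)
  if (has_header) {
    names(df) <- tolower(names(df))
    if (!all(c("sbp", "dbp") %in% names(df))) {
      stop_data("labels CSV needs sbp and dbp columns: ", path)
    }
    m <- cbind(sbp = df$sbp, dbp = df$dbp)
  } else {
    if (ncol(df) < 2L) stop_data("labels CSV needs two columns: ", path)
    m <- cbind(sbp = df[[1L]], dbp = df[[2L]])
  }
  if (!all(is.finite(m))) stop_data("non-numeric label values in ", path)
  m
}

#' Serialize / restore a trained model as JSON
#'
#' Stores architecture, weights, biases, feature and target normalization
#' statistics, the threshold matrix and the training configuration at
#' full double precision.
#'
#' @param model a `bp_model`.
#' @param path JSON path.
#' @export
write_model <- function(model, path) {
  payload <- list(
    architecture = model$architecture,
    hidden = model$hidden,
    seed = model$seed,
    # weights flattened column-major; reshaped on read
    W1 = as.numeric(model$W1), b1 = as.numeric(model$b1),
    W2 = as.numeric(model$W2), b2 = as.numeric(model$b2),
    y_center = as.list(model$y_center), y_scale = as.list(model$y_scale),
    feature_names = model$feature_names,
    norm = if (!is.null(model$norm)) {
      list(center = as.list(model$norm$center),
           scale = as.list(model$norm$scale))
    },
    threshold_matrix = if (!is.null(model$threshold_matrix)) {
      as.data.frame(model$threshold_matrix)
    },
    val_rmse = model$val_rmse
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- as.integer(sub("-.*", "", p$architecture))
  hid <- as.integer(p$hidden)
  model <- list(
    architecture = p$architecture,
    hidden = hid,
    seed = p$seed,
    W1 = matrix(unlist(p$W1), d, hid),
    b1 = as.numeric(unlist(p$b1)),
    W2 = matrix(unlist(p$W2), hid, 2L),
    b2 = as.numeric(unlist(p$b2)),
    y_center = unlist(p$y_center),
    y_scale = unlist(p$y_scale),
    feature_names = p$feature_names,
    norm = if (!is.null(p$norm)) {
      structure(list(center = unlist(p$norm$center),
                     scale = unlist(p$norm$scale)),
                class = "feature_norm")
    },
    threshold_matrix = if (!is.null(p$threshold_matrix)) {
      tm <- as.data.frame(p$threshold_matrix)
      class(tm) <- c("threshold_matrix", "data.frame")
      tm
    },
    val_rmse = p$val_rmse
  )
  class(model) <- "bp_model"
  model
}
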