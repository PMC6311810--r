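#' Default threshold matrix for feature quality control
#'
#' Per-quantity acceptance bounds applied to each feature window before
#' training or prediction; a window violating any bound is considered
#' abnormal (sensor slip, motion artifact, mis-segmentation) and
#' discarded. Monitored quantities are the raw beat period and main-peak
#' amplitude plus the bounded time-domain ratios. Amplitude bounds
#' default to (0, Inf) and can be tightened to a multiple of the training
#' median via `amplitude_ref`.
#'
#' @param amplitude_ref optional reference amplitude (e.g. the training
#'   median); when given, amplitude bounds become
#'   `amplitude_ref * c(1/5, 5)`.
#' @return A data.frame of class `threshold_matrix` with columns
#'   `quantity`, `lower`, `upper`.
#' @export
threshold_matrix <- function(amplitude_ref = NULL) {
  amp_bounds <- if (is.null(amplitude_ref)) {
    c(0, Inf)
  } else {
    amplitude_ref * c(1 / 5, 5)
  }
  # feature bounds reflect attainable radial-pulse morphology: the
  # systolic upstroke peaks in the first 60% of the beat, the dicrotic
  # notch falls in the first 75%, the systolic area fraction cannot
  # approach 0 or 1, and a rebound peak is never taller than the main
  # peak nor vanishingly small when detected
  tm <- data.frame(
    quantity = c("period", "amplitude", "FC", "Sss", "Sds", "Tft", "Tst",
                 "SL"),
    lower = c(0.3, amp_bounds[1], 0.02, 0.20, 0.05, 0.15, 0.05, 0),
    upper = c(2.0, amp_bounds[2], 0.98, 0.95, 0.80, 0.80, 0.60, Inf)
  )
  if (any(tm$lower >= tm$upper)) stop_param("threshold rows need lower < upper")
  class(tm) <- c("threshold_matrix", "data.frame")
  tm
}

#' Filter feature windows through a threshold matrix
#'
#' @param vectors a data.frame of feature windows (as produced by
#'   [extract_features()]); only columns named in the threshold matrix
#'   are monitored.
#' @param tm a [threshold_matrix()].
#' @return List with `accepted` (the surviving rows, with a `qc_pass`
#'   column set to `TRUE`), `rejected` (dropped rows plus a `qc_reason`
#'   column), and `report` (per-rule rejection counts).
#' @export
qc_filter <- function(vectors, tm = threshold_matrix()) {
  if (any(tm$lower >= tm$upper)) stop_param("invalid threshold matrix")
  n <- nrow(vectors)
  if (is.null(n) || n == 0L) {
    return(list(accepted = vectors, rejected = vectors[0, ],
                report = stats::setNames(integer(nrow(tm)), tm$quantity)))
  }
  reason <- rep(NA_character_, n)
  for (i in seq_len(nrow(tm))) {
    q <- tm$quantity[i]
    if (!q %in% names(vectors)) next
    v <- vectors[[q]]
    bad <- !is.finite(v) | v < tm$lower[i] | v > tm$upper[i]
    reason[bad & is.na(reason)] <- q
  }
  # non-finite feature values fail QC regardless of named rules
  feat_cols <- intersect(FEATURE_NAMES, names(vectors))
  if (length(feat_cols)) {
    nf <- !apply(is.finite(as.matrix(vectors[, feat_cols])), 1L, all)
    reason[nf & is.na(reason)] <- "non_finite"
  }
  ok <- is.na(reason)
  accepted <- vectors[ok, , drop = FALSE]
  accepted$qc_pass <- TRUE
  rejected <- vectors[!ok, , drop = FALSE]
  rejected$qc_reason <- reason[!ok]
  counts <- table(factor(reason[!ok], levels = c(tm$quantity, "non_finite")))
  list(accepted = accepted, rejected = rejected,
       report = stats::setNames(as.integer(counts), names(counts)))
}

#' Fit mean-shift and scale normalization
#'
#' Column-wise standardization of the fused feature matrix: subtract the
#' mean and divide by the population (1/n) standard deviation. The fitted
#' statistics are stored with the model and re-applied verbatim at
#' prediction time. Zero-variance columns get scale 1 and a warning.
#'
#' @param X numeric matrix (rows = windows, columns = features).
#' @return List of class `feature_norm`: `X` (normalized matrix),
#'   `center`, `scale`.
#' @export
normalize_fit <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop_param("need at least 2 rows to normalize")
  center <- colMeans(X)
  sc <- sqrt(colMeans(sweep(X, 2L, center)^2))
  zero <- sc < .Machine$double.eps * 100
  if (any(zero)) {
    warning("zero-variance column(s): ",
            paste(colnames(X)[zero], collapse = ", "),
            "; scale set to 1", call. = FALSE)
    sc[zero] <- 1
  }
  structure(
    list(X = sweep(sweep(X, 2L, center), 2L, sc, "/"),
         center = center, scale = sc),
    class = "feature_norm"
  )
}

#' Apply stored normalization statistics
#' @param norm a `feature_norm` (or any list with `center` and `scale`).
#' @param X matrix or vector on the raw scale.
#' @return Normalized matrix.
#' @export
normalize_apply <- function(norm, X) {
  X <- if (is.null(dim(X))) matrix(X, nrow = 1L) else as.matrix(X)
  sweep(sweep(X, 2L, norm$center), 2L, norm$scale, "/")
}

#' Invert stored normalization statistics
#' @param norm a `feature_norm`.
#' @param Xn matrix on the normalized scale.
#' @return Matrix on the raw scale.
#' @export
denormalize <- function(norm, Xn) {
  Xn <- if (is.null(dim(Xn))) matrix(Xn, nrow = 1L) else as.matrix(Xn)
  sweep(sweep(Xn, 2L, norm$scale, "*"), 2L, norm$center, "+")
}

#' Random train/validation/test split
#'
#' Randomly partitions row indices into training, validation and test
#' sets (default 70/15/15). Validation and test sizes are floor-rounded;
#' the remainder goes to training, so the three sets are disjoint and
#' exhaustive for every n.
#'
#' @param n number of rows.
#' @param fractions length-3 numeric summing to 1:
#'   (train, validation, test).
#' @param seed integer RNG seed.
#' @return List with integer index vectors `train`, `validation`, `test`.
#' @export
split_data <- function(n, fractions = c(0.7, 0.15, 0.15), seed = 1) {
  if (length(fractions) != 3L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    stop_param("fractions must be 3 non-negative numbers summing to 1")
  }
  if (!is.numeric(n) || n < 10) stop_param("need n >= 10 rows to split")
  n <- as.integer(n)
  n_val <- floor(fractions[2] * n)
  n_test <- floor(fractions[3] * n)
  perm <- with_seed(seed, sample.int(n))
  list(
    train = sort(perm[seq_len(n - n_val - n_test)]),
    validation = sort(perm[(n - n_val - n_test + 1L):(n - n_test)]),
    test = sort(perm[(n - n_test + 1L):n])
  )
}

# --- feed-forward network internals ------------------------------------

ann_unpack <- function(theta, d, hidden, out = 2L) {
  i1 <- d * hidden
  i2 <- i1 + hidden
  i3 <- i2 + hidden * out
  list(
    W1 = matrix(theta[1:i1], d, hidden),
    b1 = theta[(i1 + 1L):i2],
    W2 = matrix(theta[(i2 + 1L):i3], hidden, out),
    b2 = theta[(i3 + 1L):(i3 + out)]
  )
}

ann_forward <- function(w, X) {
  A <- 1 / (1 + exp(-(X %*% w$W1 + rep(w$b1, each = nrow(X)))))
  list(A = A, Y = A %*% w$W2 + rep(w$b2, each = nrow(X)))
}

# weight-decay mask: L2 penalty applies to connection weights, not biases
ann_decay_mask <- function(d, hidden, out) {
  c(rep(1, d * hidden), rep(0, hidden), rep(1, hidden * out), rep(0, out))
}

ann_loss <- function(theta, X, Y, d, hidden, decay = 0) {
  w <- ann_unpack(theta, d, hidden, ncol(Y))
  fw <- ann_forward(w, X)
  mean((fw$Y - Y)^2) +
    decay * sum((theta * ann_decay_mask(d, hidden, ncol(Y)))^2)
}

ann_grad <- function(theta, X, Y, d, hidden, decay = 0) {
  n <- nrow(X)
  out <- ncol(Y)
  w <- ann_unpack(theta, d, hidden, out)
  fw <- ann_forward(w, X)
  E <- (fw$Y - Y) * (2 / (n * out))
  gW2 <- crossprod(fw$A, E)
  gb2 <- colSums(E)
  dZ <- (E %*% t(w$W2)) * fw$A * (1 - fw$A)
  gW1 <- crossprod(X, dZ)
  gb1 <- colSums(dZ)
  c(gW1, gb1, gW2, gb2) +
    2 * decay * theta * ann_decay_mask(d, hidden, out)
}

#' Train the blood-pressure regression network
#'
#' Fits a feed-forward network with one logistic-sigmoid hidden layer and
#' a linear two-unit output (SBP, DBP) by minimizing the joint
#' mean-squared error with the BFGS quasi-Newton optimizer. Optimization
#' runs in short stages; after each stage the validation RMSE is checked
#' and training stops once it has failed to improve for `patience`
#' consecutive checks (classical early stopping at the validation-error
#' minimum), returning the weights from the best check. Inputs must
#' already be normalized ([normalize_fit()]); targets are standardized
#' internally for optimizer conditioning and the statistics stored in the
#' model.
#'
#' @param X_train,y_train normalized training features (n x d) and mmHg
#'   targets (n x 2, columns SBP, DBP).
#' @param X_val,y_val validation split on the same scales.
#' @param hidden hidden-layer width (default 30).
#' @param seed integer seed for the scaled-uniform (Glorot) weight
#'   initialization; training is deterministic given seed and data.
#' @param max_iter total BFGS iteration cap per restart.
#' @param check_every BFGS iterations per early-stopping stage.
#' @param patience consecutive non-improving checks tolerated.
#' @param restarts number of independent weight initializations (seeds
#'   `seed`, `seed + 1`, ...); the restart with the lowest validation
#'   RMSE wins. Restarting guards against poor local minima of the
#'   non-convex loss while staying fully deterministic.
#' @param decay L2 weight-decay coefficient on connection weights (not
#'   biases), on the standardized target scale; regularizes the network
#'   when training sets are small. A vector is recycled across restarts
#'   (one decay per restart), so validation selection picks the
#'   best-regularized run as well as the best initialization.
#' @param norm optional `feature_norm` of the inputs, stored in the model
#'   so [predict.bp_model()] can accept raw-scale features.
#' @param tm optional [threshold_matrix()] stored with the model.
#' @return Object of class `bp_model`: weights, normalization statistics,
#'   architecture tag, and a training log (per-check iteration count,
#'   training MSE, validation RMSE).
#' @export
train_ann <- function(X_train, y_train, X_val, y_val,
                      hidden = 30L, seed = 1, max_iter = 1000L,
                      check_every = 25L, patience = 6L, restarts = 3L,
                      decay = c(1e-3, 3e-4, 3e-3), norm = NULL, tm = NULL) {
  X_train <- as.matrix(X_train); y_train <- as.matrix(y_train)
  X_val <- as.matrix(X_val); y_val <- as.matrix(y_val)
  d <- ncol(X_train)
  out <- ncol(y_train)
  if (!all(is.finite(X_train)) || !all(is.finite(y_train))) {
    stop_param("non-finite values in training data")
  }

  # standardize targets for conditioning
  y_center <- colMeans(y_train)
  y_scale <- sqrt(colMeans(sweep(y_train, 2L, y_center)^2))
  y_scale[y_scale < .Machine$double.eps] <- 1
  Yt <- sweep(sweep(y_train, 2L, y_center), 2L, y_scale, "/")

  val_rmse <- function(th) {
    w <- ann_unpack(th, d, hidden, out)
    pred <- sweep(sweep(ann_forward(w, X_val)$Y, 2L, y_scale, "*"),
                  2L, y_center, "+")
    sqrt(mean((pred - y_val)^2))
  }

  run_one <- function(rseed, rdecay) {
    theta <- with_seed(rseed, {
      r1 <- sqrt(6 / (d + hidden))
      r2 <- sqrt(6 / (hidden + out))
      c(stats::runif(d * hidden, -r1, r1), rep(0, hidden),
        stats::runif(hidden * out, -r2, r2), rep(0, out))
    })
    best_theta <- theta
    best_val <- val_rmse(theta)
    bad <- 0L
    iters <- 0L
    log <- list()
    while (iters < max_iter) {
      fit <- stats::optim(theta, ann_loss, ann_grad,
                          X = X_train, Y = Yt, d = d, hidden = hidden,
                          decay = rdecay, method = "BFGS",
                          control = list(maxit = check_every, reltol = 1e-12))
      if (!is.finite(fit$value)) {
        stop_data("training diverged: non-finite loss at iteration ", iters)
      }
      theta <- fit$par
      iters <- iters + check_every
      v <- val_rmse(theta)
      log[[length(log) + 1L]] <- data.frame(
        restart = rseed - seed + 1L, iter = iters,
        train_mse = fit$value, val_rmse = v
      )
      if (v < best_val - 1e-10) {
        best_val <- v
        best_theta <- theta
        bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= patience) break
      }
      if (fit$convergence == 0) break    # BFGS converged before the cap
    }
    list(theta = best_theta, val = best_val, log = do.call(rbind, log))
  }

  decays <- rep_len(decay, restarts)
  runs <- lapply(seq_len(restarts), function(i) {
    run_one(seed + i - 1L, decays[i])
  })
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "val"))]]
  best_theta <- best$theta
  best_val <- best$val
  log <- lapply(runs, `[[`, "log")

  w <- ann_unpack(best_theta, d, hidden, out)
  structure(
    list(
      architecture = sprintf("%d-%d-%d", d, hidden, out),
      W1 = w$W1, b1 = w$b1, W2 = w$W2, b2 = w$b2,
      y_center = y_center, y_scale = y_scale,
      norm = norm, threshold_matrix = tm,
      feature_names = colnames(X_train),
      seed = seed, hidden = hidden,
      training_log = do.call(rbind, log),
      val_rmse = best_val
    ),
    class = "bp_model"
  )
}

#' @export
print.bp_model <- function(x, ...) {
  cat(sprintf("<bp_model> %s network, %d training checks, val RMSE %.3f mmHg\n",
              x$architecture, nrow(x$training_log), x$val_rmse))
  invisible(x)
}

#' Predict blood pressure from feature vectors
#'
#' Applies the stored feature normalization (when the model carries one)
#' and the trained network, returning mmHg pressures. Rows flagged
#' `qc_pass = FALSE` are refused; predictions outside the plausible
#' 40–250 mmHg range trigger a warning.
#'
#' @param object a `bp_model`.
#' @param newdata matrix/data.frame of feature vectors on the raw scale
#'   when the model stores normalization statistics, otherwise on the
#'   normalized scale. A data.frame may carry a `qc_pass` column.
#' @param normalized set `TRUE` if `newdata` is already normalized.
#' @param ... unused.
#' @return Numeric matrix with columns `sbp`, `dbp` (mmHg).
#' @export
predict.bp_model <- function(object, newdata, normalized = FALSE, ...) {
  if (is.data.frame(newdata)) {
    if ("qc_pass" %in% names(newdata) && any(!newdata$qc_pass)) {
      stop_data("refusing to predict on rows that failed QC (qc_pass FALSE)")
    }
    cols <- if (!is.null(object$feature_names)) {
      object$feature_names
    } else {
      intersect(FEATURE_NAMES, names(newdata))
    }
    newdata <- as.matrix(newdata[, cols, drop = FALSE])
  }
  X <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1L) else as.matrix(newdata)
  if (!normalized && !is.null(object$norm)) {
    X <- normalize_apply(object$norm, X)
  }
  Yn <- ann_forward(object, X)$Y
  Y <- sweep(sweep(Yn, 2L, object$y_scale, "*"), 2L, object$y_center, "+")
  colnames(Y) <- c("sbp", "dbp")
  if (any(Y < 40 | Y > 250)) {
    warning("prediction(s) outside the plausible 40-250 mmHg range",
            call. = FALSE)
  }
  Y
}

#' Evaluate a trained model on a held-out test set
#'
#' @param model a `bp_model` (or any function-like predictor: a matrix of
#'   predictions may be passed directly as `predictions`).
#' @param X_test test features (same scale convention as
#'   [predict.bp_model()]).
#' @param y_test mmHg targets, n x 2 (SBP, DBP).
#' @param normalized passed through to [predict.bp_model()].
#' @param predictions optional precomputed n x 2 prediction matrix,
#'   bypassing the model.
#' @param bin_width signed-error histogram bin width, mmHg.
#' @return List of class `bp_evaluation`: per-output signed errors,
#'   histograms (0.5 mmHg bins), `max_abs_error`, `rmse`, Pearson
#'   `correlation` (NA with `constant_target` flag when a target column
#'   is constant), pooled absolute-error percentiles (`p95`), and n.
#' @export
evaluate_model <- function(model, X_test = NULL, y_test = NULL,
                           normalized = FALSE, predictions = NULL,
                           bin_width = 0.5) {
  if (is.null(y_test) || length(y_test) == 0L || nrow(as.matrix(y_test)) == 0L) {
    stop_param("empty test set")
  }
  y_test <- as.matrix(y_test)
  if (is.null(predictions)) {
    predictions <- predict(model, X_test, normalized = normalized)
  }
  predictions <- as.matrix(predictions)
  err <- predictions - y_test
  colnames(err) <- c("sbp", "dbp")

  hist_of <- function(e) {
    lim <- max(abs(e), bin_width)
    breaks <- seq(-(ceiling(lim / bin_width) + 1) * bin_width,
                  (ceiling(lim / bin_width) + 1) * bin_width, by = bin_width)
    h <- graphics::hist(e, breaks = breaks, plot = FALSE)
    data.frame(mid = h$mids, count = h$counts)
  }
  cors <- vapply(1:2, function(j) {
    if (stats::sd(y_test[, j]) == 0) NA_real_ else
      stats::cor(predictions[, j], y_test[, j])
  }, numeric(1))
  abs_pool <- abs(as.numeric(err))
  structure(
    list(
      errors = err,
      histogram = list(sbp = hist_of(err[, 1]), dbp = hist_of(err[, 2])),
      max_abs_error = c(sbp = max(abs(err[, 1])), dbp = max(abs(err[, 2])),
                        pooled = max(abs_pool)),
      rmse = c(sbp = sqrt(mean(err[, 1]^2)), dbp = sqrt(mean(err[, 2]^2)),
               pooled = sqrt(mean(err^2))),
      correlation = c(sbp = cors[1], dbp = cors[2]),
      constant_target = is.na(cors),
      p95 = stats::quantile(abs_pool, 0.95, names = FALSE),
      n = nrow(y_test)
    ),
    class = "bp_evaluation"
  )
}

#' @export
print.bp_evaluation <- function(x, ...) {
  cat(sprintf(
    paste0("<bp_evaluation> n=%d  RMSE %.2f/%.2f mmHg (SBP/DBP)  ",
           "max|err| %.2f  P95|err| %.2f  r %.3f/%.3f\n"),
    x$n, x$rmse["sbp"], x$rmse["dbp"], x$max_abs_error["pooled"],
    x$p95, x$correlation["sbp"], x$correlation["dbp"]
  ))
  invisible(x)
}
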