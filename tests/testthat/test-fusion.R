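fake_vectors <- function(n = 100, seed = 1) {
  pulsebp:::with_seed(seed, data.frame(
    window_id = seq_len(n),
    FC = runif(n, 0.2, 0.8), Sss = runif(n, 0.4, 0.8),
    Sds = runif(n, 0.1, 0.5), Tft = runif(n, 0.3, 0.7),
    Tst = runif(n, 0.2, 0.5), SL = runif(n, 2, 10),
    A1 = runif(n, 0.2, 0.6), A2 = runif(n, 0.1, 0.3),
    A3 = runif(n, 0.05, 0.2), P1 = runif(n, -2, -1),
    P2 = runif(n, -3, 3), P3 = runif(n, 0, 1),
    period = runif(n, 0.6, 1.1), amplitude = runif(n, 0.8, 1.2)
  ))
}

test_that("threshold-matrix QC rejects exactly the planted violations", {
  v <- fake_vectors(100)
  tm <- threshold_matrix(amplitude_ref = 1)
  planted <- c(3, 10, 25, 40, 61, 77, 99)
  v$amplitude[planted] <- 10              # outside 5x the reference
  res <- qc_filter(v, tm)
  expect_equal(nrow(res$accepted), 93L)
  expect_equal(res$report[["amplitude"]], 7L)
  expect_true(all(res$rejected$qc_reason == "amplitude"))
  expect_setequal(res$rejected$window_id, planted)

  # all-clean input passes untouched
  clean <- qc_filter(fake_vectors(50, seed = 2), tm)
  expect_equal(nrow(clean$accepted), 50L)
  expect_true(all(clean$accepted$qc_pass))

  # a single period violation is rejected for that reason
  v2 <- fake_vectors(20, seed = 3)
  v2$period[5] <- 2.5
  res2 <- qc_filter(v2, threshold_matrix())
  expect_equal(res2$rejected$window_id, 5L)
  expect_equal(res2$rejected$qc_reason, "period")

  # empty input -> empty output
  empty <- qc_filter(fake_vectors(0), tm)
  expect_equal(nrow(empty$accepted), 0L)
})

test_that("normalization centres, scales, round-trips and flags constants", {
  expect_equal(unname(normalize_fit(matrix(c(1, 3), ncol = 1))$X[, 1]),
               c(-1, 1))                  # population sd convention
  X <- pulsebp:::with_seed(4, matrix(rnorm(60, 5, 3), ncol = 3))
  nf <- normalize_fit(X)
  expect_lt(max(abs(colMeans(nf$X))), 1e-12)
  expect_equal(unname(apply(nf$X, 2, function(c) sqrt(mean((c - mean(c))^2)))),
               rep(1, 3), tolerance = 1e-12)
  # idempotence on already-normalized data
  nf2 <- normalize_fit(nf$X)
  expect_equal(nf2$X, nf$X, tolerance = 1e-12, ignore_attr = TRUE)
  # round trip
  expect_equal(denormalize(nf, normalize_apply(nf, X)), X,
               tolerance = 1e-12, ignore_attr = TRUE)
  # constant column
  expect_warning(nfc <- normalize_fit(cbind(a = rep(2, 5), b = 1:5)),
                 "zero-variance")
  expect_equal(unname(nfc$X[, "a"]), rep(0, 5))
})

test_that("splits are sized, disjoint, exhaustive and reproducible", {
  sp <- split_data(100, seed = 1)
  expect_equal(lengths(sp), c(train = 70L, validation = 15L, test = 15L))
  sp10 <- split_data(10, seed = 1)
  expect_equal(lengths(sp10), c(train = 8L, validation = 1L, test = 1L))
  expect_identical(split_data(57, seed = 9), split_data(57, seed = 9))
  for (n in c(10, 11, 37, 100, 101)) {
    for (seed in 1:3) {
      sp <- split_data(n, seed = seed)
      all_idx <- c(sp$train, sp$validation, sp$test)
      expect_equal(sort(all_idx), seq_len(n))
      expect_equal(length(unique(all_idx)), n)
    }
  }
  expect_error(split_data(100, fractions = c(0.5, 0.2, 0.2)),
               class = "pulsebp_param_error")
  expect_error(split_data(5), class = "pulsebp_param_error")
})

test_that("training converges on trivial targets and is seed-deterministic", {
  X <- pulsebp:::with_seed(5, matrix(rnorm(240), ncol = 6))
  y <- cbind(sbp = rep(120, 40), dbp = rep(80, 40))
  m <- train_ann(X[1:30, ], y[1:30, ], X[31:40, ], y[31:40, ],
                 hidden = 5L, seed = 1, restarts = 1L)
  expect_lt(m$val_rmse, 1e-3)

  y2 <- cbind(120 + 5 * X[, 1], 80 + 3 * X[, 2])
  m1 <- train_ann(X[1:30, ], y2[1:30, ], X[31:40, ], y2[31:40, ],
                  hidden = 8L, seed = 3)
  m2 <- train_ann(X[1:30, ], y2[1:30, ], X[31:40, ], y2[31:40, ],
                  hidden = 8L, seed = 3)
  expect_identical(m1$W1, m2$W1)
  expect_identical(m1$W2, m2$W2)
  expect_true(is.data.frame(m1$training_log))
  expect_true(all(c("iter", "train_mse", "val_rmse") %in%
                    names(m1$training_log)))
})

test_that("prediction is deterministic, refuses QC failures and warns out of range", {
  X <- pulsebp:::with_seed(6, matrix(rnorm(240), ncol = 6))
  y <- cbind(120 + 5 * X[, 1], 80 + 3 * X[, 2])
  m <- train_ann(X[1:30, ], y[1:30, ], X[31:40, ], y[31:40, ],
                 hidden = 8L, seed = 2)
  p1 <- predict(m, X[1:5, ], normalized = TRUE)
  p2 <- predict(m, X[1:5, ], normalized = TRUE)
  expect_identical(p1, p2)
  expect_identical(p1[3, ], predict(m, X[3, , drop = FALSE],
                                    normalized = TRUE)[1, ])

  df <- as.data.frame(X[1:2, ])
  names(df) <- paste0("V", 1:6)
  m$feature_names <- names(df)
  df$qc_pass <- c(TRUE, FALSE)
  expect_error(predict(m, df), class = "pulsebp_data_error")

  # a degenerate model whose output sits outside plausible pressures
  mx <- structure(list(architecture = "2-2-2", hidden = 2L,
                       W1 = matrix(0, 2, 2), b1 = c(0, 0),
                       W2 = matrix(0, 2, 2), b2 = c(300, 10),
                       y_center = c(0, 0), y_scale = c(1, 1),
                       norm = NULL, feature_names = NULL),
                  class = "bp_model")
  expect_warning(predict(mx, matrix(0, 1, 2), normalized = TRUE),
                 "40-250")
})

test_that("evaluation reports exact error statistics and histogram bins", {
  y <- cbind(sbp = c(120, 125, 130, 118), dbp = c(80, 82, 85, 79))
  ev0 <- evaluate_model(NULL, y_test = y, predictions = y)
  expect_equal(unname(ev0$max_abs_error["pooled"]), 0)
  expect_equal(unname(ev0$rmse["pooled"]), 0)
  expect_equal(unname(ev0$p95), 0)

  ev1 <- evaluate_model(NULL, y_test = y, predictions = y + 1)
  expect_equal(unname(ev1$max_abs_error["pooled"]), 1)
  expect_equal(unname(ev1$rmse["pooled"]), 1)
  expect_equal(diff(ev1$histogram$sbp$mid[1:2]), 0.5)

  # constant targets flag the correlation as undefined
  yc <- cbind(sbp = rep(120, 4), dbp = rep(80, 4))
  evc <- evaluate_model(NULL, y_test = yc, predictions = yc)
  expect_true(all(evc$constant_target))
  expect_true(all(is.na(evc$correlation)))

  expect_error(evaluate_model(NULL, y_test = NULL, predictions = y),
               class = "pulsebp_param_error")
})

test_that("model JSON serialization round-trips predictions exactly", {
  X <- pulsebp:::with_seed(8, matrix(rnorm(240), ncol = 6))
  y <- cbind(120 + 5 * X[, 1], 80 + 3 * X[, 2])
  m <- train_ann(X[1:30, ], y[1:30, ], X[31:40, ], y[31:40, ],
                 hidden = 8L, seed = 2,
                 norm = normalize_fit(matrix(rnorm(12), 2, 6)))
  path <- tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  expect_equal(predict(m2, X[1:5, ], normalized = TRUE),
               predict(m, X[1:5, ], normalized = TRUE), tolerance = 1e-12)
  expect_identical(m2$architecture, m$architecture)
})

test_that("the noiseless synthetic mapping is learned to about a millimetre of mercury", {
  ds <- get_benchmark()
  fit <- fit_bp_model(ds$features, ds$labels_clean, domains = "both", seed = 1)
  expect_lte(fit$evaluation$rmse[["pooled"]], 1)
})

test_that("widening the hidden layer beyond 30 nodes buys almost nothing", {
  ds <- get_benchmark()
  f30 <- fit_bp_model(ds$features, ds$labels, domains = "both", seed = 1,
                      hidden = 30L)
  f50 <- fit_bp_model(ds$features, ds$labels, domains = "both", seed = 1,
                      hidden = 50L)
  expect_lte(f30$model$val_rmse - f50$model$val_rmse, 0.2)
})

test_that("the BFGS trainer matches an independent network implementation", {
  skip_if_not_installed("nnet")
  X <- pulsebp:::with_seed(31, matrix(runif(1200, -1, 1), ncol = 6))
  y <- cbind(sbp = 120 + 8 * tanh(X[, 1]) + 5 * X[, 2] * X[, 3],
             dbp = 80 + 4 * X[, 1] - 3 * sin(X[, 2]))
  sp <- split_data(nrow(X), seed = 1)
  m <- train_ann(X[sp$train, ], y[sp$train, ],
                 X[sp$validation, ], y[sp$validation, ],
                 hidden = 10L, seed = 1)
  ours <- sqrt(mean((predict(m, X[sp$test, ], normalized = TRUE) -
                       y[sp$test, ])^2))
  ref <- pulsebp:::with_seed(1, {
    fit <- nnet::nnet(X[sp$train, ], y[sp$train, ], size = 10,
                      linout = TRUE, decay = 1e-3, maxit = 500,
                      trace = FALSE)
    sqrt(mean((predict(fit, X[sp$test, ]) - y[sp$test, ])^2))
  })
  # same problem, same family of model: errors agree in magnitude
  expect_lt(ours, max(2 * ref, ref + 0.5))
  expect_lt(ours, 0.1 * sd(y))
})
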