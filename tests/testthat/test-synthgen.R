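test_that("a beat without rebounds is a single unimodal bump peaking at the main kernel", {
  p <- beat_params(amp_ratio_rebound1 = 0, amp_ratio_rebound2 = 0)
  y <- simulate_beat(p, fs = 500)
  ext <- pulsebp:::local_extrema(y)
  expect_length(ext$maxima, 1L)
  # argmax at the main-kernel centre, 3 widths after onset
  expect_equal(which.max(y), round(3 * p$width_main * 500) + 1L,
               tolerance = 0, ignore_attr = TRUE)
  # near-zero endpoints
  expect_lt(y[1], 0.05 * max(y))
  expect_lt(y[length(y)], 0.05 * max(y))
})

test_that("the standard beat shows the main peak and two rebound peaks", {
  y <- simulate_beat(beat_params(), fs = 500)
  ext <- pulsebp:::local_extrema(y)
  expect_length(ext$maxima, 3L)          # points c, e, g
  expect_length(ext$minima, 2L)          # points d, f
  # global maximum belongs to the main kernel
  expect_equal(which.max(y), ext$maxima[1])
})

test_that("beat superposition is homogeneous in the main amplitude", {
  y1 <- simulate_beat(beat_params(amplitude_main = 1), fs = 500)
  y2 <- simulate_beat(beat_params(amplitude_main = 2), fs = 500)
  expect_equal(y2, 2 * y1, tolerance = 1e-12)
})

test_that("invalid beat parameters are rejected", {
  expect_error(beat_params(period = -1), class = "pulsebp_param_error")
  expect_error(beat_params(delay_rebound1 = 0.4, delay_rebound2 = 0.3),
               class = "pulsebp_param_error")
  expect_error(beat_params(width_main = 0.5), class = "pulsebp_param_error")
  expect_error(beat_params(amp_ratio_rebound1 = 1),
               class = "pulsebp_param_error")
})

test_that("noiseless records are periodic, reproducible and length-conserving", {
  # fs / heart_rate integer so periodicity is exact
  spec <- record_spec(heart_rate = 1.25, n_beats = 8, fs = 500,
                      noise_sd = 0, resp_amp = 0, beat_jitter = 0, seed = 3)
  rec <- simulate_record(spec)
  per <- 500 / 1.25
  expect_equal(length(rec$samples), round(8 * 500 / 1.25))
  head_part <- rec$samples[1:per]
  for (k in 1:7) {
    expect_equal(rec$samples[k * per + seq_len(per)], head_part,
                 tolerance = 1e-9)
  }
  # seed determinism, bit-identical
  rec2 <- simulate_record(spec)
  expect_identical(rec$samples, rec2$samples)
  # different seed with noise differs
  s2 <- record_spec(heart_rate = 1.25, n_beats = 8, fs = 500,
                    noise_sd = 0.01, seed = 4)
  expect_false(identical(simulate_record(s2)$samples, rec$samples))
})

test_that("record spectra carry the heart-rate fundamental and harmonics", {
  rec <- simulate_record(record_spec(heart_rate = 1.2, n_beats = 30,
                                     fs = 500, noise_sd = 0,
                                     resp_amp = 0.05, beat_jitter = 0,
                                     seed = 1))
  on <- rec$truth$onsets
  w <- rec$samples[on[1]:(on[6] - 1L)]
  ff <- extract_freq_features(w, 500)
  bin <- 500 / length(w)
  pf <- attr(ff, "peak_freqs")
  for (k in 1:3) expect_lt(abs(pf[k] - k * 1.2), bin)
  # 4.8 Hz line also present in the full-record magnitude spectrum
  n <- length(rec$samples)
  mag <- Mod(stats::fft(rec$samples))[1:(n %/% 2)]
  freqs <- (0:(n %/% 2 - 1)) * 500 / n
  i48 <- which.min(abs(freqs - 4.8))
  expect_gt(mag[i48], mag[i48 - 3])
  expect_gt(mag[i48], mag[i48 + 3])
})

test_that("record_spec validates its physiological ranges", {
  expect_error(record_spec(heart_rate = 0.2), class = "pulsebp_param_error")
  expect_error(record_spec(resp_rate = 2), class = "pulsebp_param_error")
  expect_error(record_spec(n_beats = 0), class = "pulsebp_param_error")
  expect_error(record_spec(fs = 50), class = "pulsebp_param_error")
})

test_that("ground-truth map is anchored at 120/80 and stays in the physiological box", {
  ref <- bp_from_params(beat_params())
  expect_equal(unname(ref["sbp"]), 120, tolerance = 1e-9)
  expect_equal(unname(ref["dbp"]), 80, tolerance = 1e-9)
  # determinism
  expect_identical(ref, bp_from_params(beat_params()))

  # grid check over the generator's parameter box
  grid <- expand.grid(a = c(0.7, 1, 1.3), r1 = c(0.3, 0.5, 0.7),
                      r2 = c(0.1, 0.25, 0.4), d1 = c(0.18, 0.28),
                      dg = c(0.12, 0.2), hr = c(0.9, 1.2, 1.5))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    bp <- bp_from_params(beat_params(
      amplitude_main = g$a, amp_ratio_rebound1 = g$r1,
      amp_ratio_rebound2 = g$r2, delay_rebound1 = g$d1,
      delay_rebound2 = g$d1 + g$dg, period = 1 / g$hr,
      width_main = 0.08 / (0.83 * g$hr), width_r1 = 0.05 / (0.83 * g$hr),
      width_r2 = 0.05 / (0.83 * g$hr)
    ))
    expect_gte(bp[["sbp"]], 90); expect_lte(bp[["sbp"]], 160)
    expect_gte(bp[["dbp"]], 55); expect_lte(bp[["dbp"]], 100)
    expect_gte(bp[["sbp"]] - bp[["dbp"]], 20)
  }
})

test_that("SBP increases strictly with the first rebound ratio", {
  r1_grid <- seq(0.05, 0.9, by = 0.05)
  sbp <- vapply(r1_grid, function(r) {
    bp_from_params(beat_params(amp_ratio_rebound1 = r))[["sbp"]]
  }, numeric(1))
  expect_true(all(diff(sbp) > 0))
})

test_that("pressure sweeps follow the 20-sample protocol and peak at the true OP", {
  sw <- simulate_pressure_sweep(22, seed = 1)
  expect_equal(sw$level_N, seq(2, 14, by = 0.5))
  expect_equal(sum(grepl("^sample_", names(sw))), 20L)
  expect_equal(nrow(sw), 25L)
  # quality peaks at the grid point nearest the cubic's value at BMI 22
  expect_equal(sw$level_N[which.max(sw$quality)], 4.5)
  # zero noise: per-level mean equals the level exactly
  sw0 <- simulate_pressure_sweep(22, seed = 1, noise_sd = 0)
  m <- rowMeans(as.matrix(sw0[, paste0("sample_", 1:20)]))
  expect_equal(m, sw0$level_N, tolerance = 1e-12, ignore_attr = TRUE)
  # errors
  expect_error(simulate_pressure_sweep(22, levels = numeric(0)),
               class = "pulsebp_param_error")
  expect_error(simulate_pressure_sweep(22, levels = c(5, 4)),
               class = "pulsebp_param_error")
})
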