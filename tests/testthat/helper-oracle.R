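# Independent, deliberately naive re-implementations used as oracles.
# They share nothing with the package's vectorized code paths: plain
# loops over samples, no shared helpers.

# time-domain features recomputed by explicit loops from the same beat
# samples and fiducial indices
oracle_time_features <- function(samples, fs, fid) {
  base <- samples[fid$b]
  H <- samples[fid$c] - base
  h <- samples[fid$e] - base

  area_loop <- function(from, to) {
    a <- 0
    for (i in from:(to - 1L)) {
      a <- a + (samples[i] - base + samples[i + 1L] - base) / 2
    }
    a / fs
  }
  S1 <- area_loop(fid$b, fid$d)
  S2 <- area_loop(fid$d, length(samples))
  Sss <- S1 / (S1 + S2)

  sl <- -Inf
  for (i in fid$b:(fid$c - 1L)) {
    s <- (samples[i + 1L] - samples[i]) * fs
    if (s > sl) sl <- s
  }
  Tt <- length(samples) / fs
  c(
    FC = h / H,
    Sss = Sss,
    Sds = 1 - Sss,
    Tft = ((fid$d - fid$b) / fs) / Tt,
    Tst = ((fid$c - fid$b) / fs) / Tt,
    SL = sl
  )
}

# random valid beat-shape draws matching the benchmark generator's ranges
random_beat_params <- function(n, seed) {
  pulsebp:::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      hr <- stats::runif(1, 0.9, 1.5)
      period <- 1 / hr
      ws <- period / 0.83
      d1 <- stats::runif(1, 0.18, 0.28)
      beat_params(
        amplitude_main = stats::runif(1, 0.7, 1.3),
        amp_ratio_rebound1 = stats::runif(1, 0.3, 0.7),
        amp_ratio_rebound2 = stats::runif(1, 0.1, 0.4),
        delay_rebound1 = d1,
        delay_rebound2 = d1 + stats::runif(1, 0.12, 0.20),
        width_main = 0.08 * ws,
        width_r1 = 0.05 * ws,
        width_r2 = 0.05 * ws,
        period = period
      )
    })
  })
}

# shared synthetic benchmark, built once per test run
benchmark_env <- new.env(parent = emptyenv())
get_benchmark <- function() {
  if (is.null(benchmark_env$ds)) {
    benchmark_env$ds <- make_bp_dataset(n_records = 1200, seed = 1)
  }
  benchmark_env$ds
}
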