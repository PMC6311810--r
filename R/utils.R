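# internal helpers shared across modules

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

stop_param <- function(...) {
  stop(errorCondition(paste0(...), class = c("pulsebp_param_error", "error")))
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("pulsebp_data_error", "error")))
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_param(name, " must be a finite numeric scalar")
  }
  if (strict_lower && x <= lower) {
    stop_param(name, " must be > ", lower)
  }
  if (!strict_lower && x < lower) {
    stop_param(name, " must be >= ", lower)
  }
  if (x > upper) {
    stop_param(name, " must be <= ", upper)
  }
  invisible(x)
}

# trapezoidal integral of y sampled at uniform spacing dx
trapz_uniform <- function(y, dx) {
  n <- length(y)
  if (n < 2L) return(0)
  dx * (sum(y) - (y[1L] + y[n]) / 2)
}
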