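# Internal helpers shared across modules.

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# sample skewness (bias-uncorrected; only the sign is ever used)
skewness <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) return(0)
  mean((x - m)^3) / s^3
}

# circularly shift a vector so the DC bin of an FFT ends up centred
fftshift <- function(x) {
  n <- length(x)
  idx <- c(seq(floor(n / 2) + 1L, n), seq_len(floor(n / 2)))
  x[idx]
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name),
          class = "sgmotion_invalid_parameter")
  }
  invisible(x)
}

check_positive <- function(x, name) {
  stopifnot_scalar_number(x, name)
  if (x <= 0) {
    abort(sprintf("`%s` must be positive (got %g).", name, x),
          class = "sgmotion_invalid_parameter")
  }
  invisible(x)
}

check_non_negative <- function(x, name) {
  stopifnot_scalar_number(x, name)
  if (x < 0) {
    abort(sprintf("`%s` must be non-negative (got %g).", name, x),
          class = "sgmotion_invalid_parameter")
  }
  invisible(x)
}

check_in_range <- function(x, name, lo, hi) {
  stopifnot_scalar_number(x, name)
  if (x < lo || x > hi) {
    abort(sprintf("`%s` must lie in [%g, %g] (got %g).", name, lo, hi, x),
          class = "sgmotion_invalid_parameter")
  }
  invisible(x)
}

# run code under a local RNG state so callers' streams are untouched
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    set.seed(seed)
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
  }
  force(code)
}
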