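#' @importFrom stats rnorm runif rpois median sd approx smooth.spline fitted
#'   convolve qr.solve rbinom predict quantile
#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic child seeds below 2^31 derived from one master seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be > 0.", name))
  }
  invisible(x)
}

# Linear convolution of a signal with a kernel, truncated to length(x).
convolve_truncate <- function(x, kernel) {
  n <- length(x)
  out <- convolve(x, rev(kernel), type = "open")
  out[seq_len(n)]
}

sigmoid <- function(x) 1 / (1 + exp(-x))

`%||%` <- function(a, b) if (is.null(a)) b else a
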