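# Internal helpers shared across the package.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a master seed and a stream index; keeps results
# inside the 32-bit integer range required by set.seed().
child_seed <- function(master, stream) {
  as.integer((as.double(master) * 48271 + as.double(stream) * 7919) %% 2147483587) + 1L
}

#' Discrete analytic signal of a real series
#'
#' Computes the analytic signal `x + i * H(x)` (with `H` the Hilbert
#' transform) via the one-sided spectrum construction: the FFT of `x` has its
#' negative-frequency half zeroed and its positive-frequency half doubled.
#' The modulus of the result is the instantaneous amplitude envelope.
#'
#' @param x numeric vector.
#' @return complex vector of the same length.
#' @keywords internal
analytic_signal <- function(x) {
  n <- length(x)
  if (n == 0L) stop("empty series")
  if (n == 1L) return(complex(real = x, imaginary = 0))
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[n / 2L + 1L] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

assert_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be TRUE or FALSE", name))
  }
  x
}

assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop(sprintf("'%s' must be a single finite number in [%s, %s]", name, lower, upper))
  }
  as.double(x)
}
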