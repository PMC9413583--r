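#' Sliding-window epoch grid
#'
#' Analysis epochs of `window_s` seconds with fractional overlap
#' `overlap` between consecutive epochs (default 1-s windows, 50% overlap).
#'
#' @param window_s window length in seconds (default 1).
#' @param overlap overlap fraction in `[0, 1)` (default 0.5).
#' @param srate sampling rate in Hz.
#' @return an object of class `epoch_grid` with integer `window` and `hop`
#'   sample counts.
#' @examples
#' epoch_grid(1, 0.5, 128)
#' @export
epoch_grid <- function(window_s = 1, overlap = 0.5, srate = 128) {
  window_s <- assert_number(window_s, "window_s", lower = 1e-9)
  overlap <- assert_number(overlap, "overlap", lower = 0, upper = 1 - 1e-9)
  srate <- assert_number(srate, "srate", lower = 1e-9)
  window <- as.integer(round(window_s * srate))
  hop <- max(1L, as.integer(round(window * (1 - overlap))))
  if (window < 1L) stop("window shorter than one sample")
  structure(list(window_s = window_s, overlap = overlap, srate = srate,
                 window = window, hop = hop),
            class = "epoch_grid")
}

#' @export
print.epoch_grid <- function(x, ...) {
  cat(sprintf("<epoch_grid> %g s window (%d samples), %.0f%% overlap (hop %d)\n",
              x$window_s, x$window, 100 * x$overlap, x$hop))
  invisible(x)
}

# Epochs fully contained in a signal of length n: floor((n - W)/H) + 1.
n_epochs <- function(n, window, hop) {
  if (n < window) 0L else as.integer((n - window) %/% hop + 1L)
}

#' Segment a signal into overlapping epochs
#'
#' @param signal a `band_signal` or numeric vector.
#' @param grid an [epoch_grid].
#' @return list with `epochs` (matrix, one column per epoch), `starts`
#'   (1-based start sample of each epoch) and `start_s` (start times in
#'   seconds).
#' @examples
#' segment_epochs(sin(1:256), epoch_grid(1, 0.5, 128))
#' @export
segment_epochs <- function(signal, grid) {
  stopifnot(inherits(grid, "epoch_grid"))
  v <- if (inherits(signal, "band_signal")) signal$values else signal
  ne <- n_epochs(length(v), grid$window, grid$hop)
  if (ne < 1L) {
    stop(sprintf("signal (%d samples) shorter than one window (%d samples)",
                 length(v), grid$window))
  }
  starts <- 1L + (seq_len(ne) - 1L) * grid$hop
  epochs <- vapply(starts, function(s) v[s:(s + grid$window - 1L)],
                   numeric(grid$window))
  list(epochs = matrix(epochs, nrow = grid$window), starts = starts,
       start_s = (starts - 1L) / grid$srate)
}

#' Amplitude of the upper envelope (AUE) of an epoch
#'
#' The upper envelope is the modulus of the analytic signal
#' `x + i * H(x)` of the (optionally demeaned) epoch. Demeaning is on by
#' default: the min-max normalization step leaves a positive offset whose
#' analytic modulus would be dominated by the offset rather than by the
#' oscillation amplitude.
#'
#' @param epoch numeric vector (one analysis window).
#' @param demean subtract the epoch mean before the transform (default
#'   `TRUE`).
#' @return numeric vector of non-negative envelope amplitudes, same length
#'   as `epoch`.
#' @examples
#' compute_aue(sin(2 * pi * 8 * (0:127) / 128))
#' @export
compute_aue <- function(epoch, demean = TRUE) {
  if (length(epoch) == 0L) stop("empty epoch")
  assert_flag(demean, "demean")
  if (demean) epoch <- epoch - mean(epoch)
  Mod(analytic_signal(epoch))
}

#' Coefficient of variation of the upper envelope (CVUE), in percent
#'
#' `CVUE = sd(AUE) / mean(AUE) * 100` with the sample (n-1) standard
#' deviation. Scale-free: multiplying the envelope by any positive constant
#' leaves it unchanged.
#'
#' @param envelope numeric vector of envelope amplitudes (from
#'   [compute_aue()]).
#' @return CVUE in percent.
#' @examples
#' compute_cvue(c(1, 3))  # 70.71%
#' @export
compute_cvue <- function(envelope) {
  if (length(envelope) < 2L) stop("envelope needs at least 2 samples")
  m <- mean(envelope)
  if (m <= 0) stop("degenerate epoch: mean envelope is not positive")
  sd(envelope) / m * 100
}

#' Savitzky-Golay smoothing of a CVUE trace
#'
#' Polynomial least-squares smoothing for display of per-epoch traces;
#' never used for inference. A polynomial of degree at most `poly_order`
#' passes through unchanged.
#'
#' @param trace numeric vector of per-epoch CVUE values, or a `cvue_fit`
#'   (every trace is smoothed).
#' @param poly_order polynomial order (default 5, as used for resting
#'   traces; 15 for active traces).
#' @param window_length odd window length in epochs, greater than
#'   `poly_order` and at most the trace length (default 11).
#' @return same type as the input, smoothed.
#' @examples
#' smooth_trace(rnorm(50, 10), poly_order = 3, window_length = 7)
#' @export
smooth_trace <- function(trace, poly_order = 5, window_length = 11) {
  poly_order <- as.integer(assert_number(poly_order, "poly_order", lower = 0))
  window_length <- as.integer(assert_number(window_length, "window_length",
                                            lower = 1))
  if (window_length %% 2L == 0L) stop("window_length must be odd")
  if (window_length <= poly_order) {
    stop("window_length must exceed poly_order")
  }
  if (inherits(trace, "cvue_fit")) {
    trace$trace$cvue_pct <- stats::ave(
      trace$trace$cvue_pct,
      interaction(trace$trace$channel, trace$trace$band),
      FUN = function(v) smooth_trace(v, poly_order, window_length))
    trace$settings$smoothed <- c(poly_order = poly_order,
                                 window_length = window_length)
    return(trace)
  }
  if (window_length > length(trace)) {
    stop("window_length exceeds trace length")
  }
  as.numeric(signal::sgolayfilt(trace, p = poly_order, n = window_length))
}
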