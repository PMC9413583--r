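#' Remove the DC voltage offset from a channel
#'
#' Consumer EEG amplifiers report voltages riding on a large hardware DC
#' offset (around 4200 uV for the headset emulated here). The offset is
#' removed by subtracting the channel mean from the entire channel.
#'
#' @param channel numeric vector of samples in microvolts.
#' @return the centred channel (`channel - mean(channel)`).
#' @examples
#' remove_dc_offset(c(4201, 4199, 4200))
#' @export
remove_dc_offset <- function(channel) {
  if (length(channel) == 0L) stop("empty series")
  channel - mean(channel)
}

#' Detect amplitude outliers by the quartile fence rule
#'
#' Flags samples lying more than `factor` interquartile ranges above the
#' upper quartile or below the lower quartile. Quartiles use the linear
#' interpolation between order statistics ("type 7") convention. Fences are
#' computed once over the whole channel, which treats blink and EMG
#' transients as rare excursions from a stationary background.
#'
#' @param channel numeric vector, length at least 4.
#' @param factor fence multiplier in IQR units (default 1.5).
#' @return an object of class `outlier_mask`: list with `flag` (logical per
#'   sample), `bounds` (lower, upper fence), `quartiles` (Q1, Q3) and
#'   `factor`.
#' @examples
#' detect_outliers(c(1:9, 100))
#' @export
detect_outliers <- function(channel, factor = 1.5) {
  if (length(channel) < 4L) stop("series too short (need >= 4 samples)")
  factor <- assert_number(factor, "factor", lower = 0)
  q <- quantile(channel, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  bounds <- c(lower = q[1] - factor * iqr, upper = q[2] + factor * iqr)
  structure(
    list(flag = channel < bounds[1] | channel > bounds[2],
         bounds = bounds,
         quartiles = c(Q1 = q[1], Q3 = q[2]),
         factor = factor),
    class = "outlier_mask"
  )
}

#' @export
print.outlier_mask <- function(x, ...) {
  cat(sprintf("<outlier_mask> %d/%d flagged; fences [%.4g, %.4g] (Q1 %.4g, Q3 %.4g, %.3g IQR)\n",
              sum(x$flag), length(x$flag), x$bounds[1], x$bounds[2],
              x$quartiles[1], x$quartiles[2], x$factor))
  invisible(x)
}

#' Replace flagged outliers by linear interpolation
#'
#' Each flagged sample is replaced by linear interpolation between its
#' nearest non-flagged neighbours; unflagged samples are never modified.
#' Flagged runs touching the first or last sample have no neighbour on one
#' side and take the nearest clean value instead.
#'
#' @param channel numeric vector.
#' @param mask an `outlier_mask` from [detect_outliers()], or a logical
#'   vector of the same length as `channel`.
#' @return the repaired channel.
#' @examples
#' replace_outliers(c(0, 99, 99, 3), c(FALSE, TRUE, TRUE, FALSE))
#' @export
replace_outliers <- function(channel, mask) {
  flag <- if (inherits(mask, "outlier_mask")) mask$flag else as.logical(mask)
  if (length(flag) != length(channel)) {
    stop("mask length does not match channel length")
  }
  if (!any(flag)) return(channel)
  clean <- which(!flag)
  if (length(clean) < 2L) stop("fewer than two clean samples; cannot interpolate")
  out <- channel
  out[flag] <- approx(x = clean, y = channel[clean], xout = which(flag),
                      method = "linear", rule = 2)$y
  out
}

#' Standard preprocessing of one channel
#'
#' DC-offset removal followed by quartile-fence outlier detection and
#' linear-interpolation replacement, in that order.
#'
#' @inheritParams detect_outliers
#' @return list with `values` (clean channel), `mask` (the `outlier_mask`).
#' @export
preprocess_channel <- function(channel, factor = 1.5) {
  centred <- remove_dc_offset(channel)
  mask <- detect_outliers(centred, factor = factor)
  list(values = replace_outliers(centred, mask), mask = mask)
}
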