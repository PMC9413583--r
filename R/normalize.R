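#' Min-max normalization of a band signal
#'
#' Linear transformation mapping the minimum of the whole band-filtered
#' segment to 0 and its maximum to 1, preserving the ordering of samples.
#' The extrema are taken over the full analyzed segment (not per epoch).
#'
#' @param band_signal a `band_signal` from [apply_bandpass()], or a plain
#'   numeric vector.
#' @return same type as the input, with values in `[0, 1]`.
#' @examples
#' min_max_normalize(c(2, 4, 6))
#' @export
min_max_normalize <- function(band_signal) {
  v <- if (inherits(band_signal, "band_signal")) band_signal$values else band_signal
  lo <- min(v); hi <- max(v)
  if (hi - lo < .Machine$double.eps * max(1, abs(hi))) {
    stop("degenerate input: segment is constant (max == min)")
  }
  out <- (v - lo) / (hi - lo)
  if (inherits(band_signal, "band_signal")) {
    band_signal$values <- out
    band_signal$provenance$normalized <- "min-max"
    band_signal
  } else {
    out
  }
}

#' Normalization reference context
#'
#' Defines the reference interval whose mean min-max value (`MRf`) rescales
#' the signal in the unity-normalization step. At rest the reference is the
#' first second of the recording; for active (task) recordings it is the
#' 60-s resting baseline of the same subject, supplied as `reference_values`.
#'
#' @param condition `"rest"` or `"active"`.
#' @param reference_s length of the in-signal reference interval in seconds
#'   (rest default 1).
#' @param reference_values optional numeric vector of min-max-normalized
#'   baseline values to use as the reference (required for `"active"`).
#' @return an object of class `norm_context`.
#' @export
norm_context <- function(condition = c("rest", "active"), reference_s = 1,
                         reference_values = NULL) {
  condition <- match.arg(condition)
  reference_s <- assert_number(reference_s, "reference_s", lower = 1e-9)
  if (condition == "active" && is.null(reference_values)) {
    stop("active normalization requires 'reference_values' (the 60-s baseline)")
  }
  structure(list(condition = condition, reference_s = reference_s,
                 reference_values = reference_values),
            class = "norm_context")
}

# Mean of the min-max values over the reference interval.
reference_mean <- function(minmax_values, srate, context) {
  if (!is.null(context$reference_values)) {
    mean(context$reference_values)
  } else {
    k <- min(length(minmax_values), max(1L, round(context$reference_s * srate)))
    mean(minmax_values[seq_len(k)])
  }
}

#' Unity normalization against a reference interval
#'
#' Divides every min-max-normalized value by `MRf`, the mean of min-max
#' values over the reference interval, so that the signal is expressed in
#' units of its own reference level (the reference interval averages to 1).
#'
#' @param minmax_signal a min-max-normalized `band_signal` or numeric
#'   vector.
#' @param context a [norm_context]; default is the resting-state rule
#'   (first second of the signal).
#' @param srate sampling rate in Hz, required when `minmax_signal` is a
#'   plain vector.
#' @param eps smallest usable reference mean (default 1e-6).
#' @return same type as the input.
#' @examples
#' unity_normalize(c(0.2, 0.4, 0.6, 0.8),
#'                 norm_context(reference_values = NULL, reference_s = 2),
#'                 srate = 1)
#' @export
unity_normalize <- function(minmax_signal, context = norm_context(),
                            srate = NULL, eps = 1e-6) {
  is_bs <- inherits(minmax_signal, "band_signal")
  v <- if (is_bs) minmax_signal$values else minmax_signal
  if (is_bs) srate <- minmax_signal$srate
  if (is.null(srate)) stop("'srate' is required for plain numeric input")
  stopifnot(inherits(context, "norm_context"))
  mrf <- reference_mean(v, srate, context)
  if (!is.finite(mrf) || mrf <= eps) {
    stop(sprintf("unusable reference: MRf = %.3g <= %.3g", mrf, eps))
  }
  out <- v / mrf
  if (is_bs) {
    minmax_signal$values <- out
    minmax_signal$provenance$normalized <- "min-max + unity"
    minmax_signal$provenance$MRf <- mrf
    minmax_signal
  } else {
    out
  }
}
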