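#' Per-epoch CVUE trace for one channel and band
#'
#' Runs the complete single-channel pipeline: DC-offset removal and
#' quartile outlier repair, Butterworth band decomposition, min-max and
#' unity normalization, epoching, per-epoch analytic-signal envelope, and
#' the CVUE statistic.
#'
#' @param recording an [eeg_recording].
#' @param channel channel label to analyse.
#' @param band a [band_spec].
#' @param grid an [epoch_grid]; defaults to 1-s windows with 50% overlap at
#'   the recording's sampling rate.
#' @param context a [norm_context]; defaults to the resting-state rule.
#' @param demean demean each epoch before the Hilbert transform (default
#'   `TRUE`).
#' @param preprocess apply DC removal and outlier repair (default `TRUE`).
#' @param iqr_factor fence multiplier for outlier detection (default 1.5).
#' @param zero_phase zero-phase band filtering (default `TRUE`).
#' @return data frame with columns `channel`, `band`, `epoch`,
#'   `t_start_s`, `cvue_pct`.
#' @export
cvue_trace <- function(recording, channel, band,
                       grid = epoch_grid(1, 0.5, recording$srate),
                       context = norm_context(),
                       demean = TRUE, preprocess = TRUE, iqr_factor = 1.5,
                       zero_phase = TRUE) {
  stopifnot(inherits(recording, "eeg_recording"), inherits(band, "band_spec"))
  if (!channel %in% recording$channels) {
    stop("unknown channel: ", channel)
  }
  x <- recording$data[, channel]
  if (preprocess) x <- preprocess_channel(x, factor = iqr_factor)$values
  bs <- apply_bandpass(x, band, recording$srate, zero_phase = zero_phase)
  bs <- min_max_normalize(bs)
  bs <- unity_normalize(bs, context)
  segs <- segment_epochs(bs, grid)
  cv <- apply(segs$epochs, 2, function(e) compute_cvue(compute_aue(e, demean)))
  data.frame(channel = channel, band = band$name,
             epoch = seq_along(cv), t_start_s = segs$start_s,
             cvue_pct = as.numeric(cv), stringsAsFactors = FALSE)
}

#' Fit CVUE traces to a recording
#'
#' The main fitting function: computes per-epoch CVUE traces for every
#' requested channel and frequency band of a recording and returns a
#' `cvue_fit` object with `print`, `summary`, `coef` and `plot` methods.
#'
#' @inheritParams cvue_trace
#' @param channels channel labels to analyse (default `c("FC5", "T7")`,
#'   intersected with the channels present).
#' @param bands named list of [band_spec] objects (default [eeg_bands()]).
#' @param window_s,overlap epoch window length (s) and overlap fraction.
#' @param baseline optional [eeg_recording]: the 60-s resting baseline used
#'   as the unity-normalization reference for active (task) recordings.
#'   When supplied, `MRf` is the mean min-max value of the baseline's own
#'   band-filtered signal.
#' @return an object of class `cvue_fit`.
#' @examples
#' spec <- cohort_spec(n_per_group = c(CFP = 1), duration_s = 20, seed = 1)
#' rec <- generate_recording(spec, "CFP", subject_seed = 1)
#' fit <- cvue(rec)
#' coef(fit)
#' @export
cvue <- function(recording, channels = c("FC5", "T7"), bands = eeg_bands(),
                 window_s = 1, overlap = 0.5, demean = TRUE,
                 preprocess = TRUE, iqr_factor = 1.5, zero_phase = TRUE,
                 baseline = NULL) {
  stopifnot(inherits(recording, "eeg_recording"))
  missing_ch <- setdiff(channels, recording$channels)
  if (length(missing_ch)) {
    stop("unknown channel(s): ", paste(missing_ch, collapse = ", "))
  }
  grid <- epoch_grid(window_s, overlap, recording$srate)
  condition <- recording$meta$condition %||% "rest"
  traces <- list()
  for (ch in channels) {
    for (bname in names(bands)) {
      band <- bands[[bname]]
      context <- if (!is.null(baseline)) {
        ref <- baseline$data[, ch]
        if (preprocess) ref <- preprocess_channel(ref, iqr_factor)$values
        ref_bs <- apply_bandpass(ref, band, baseline$srate,
                                 zero_phase = zero_phase)
        norm_context("active", reference_values = min_max_normalize(ref_bs)$values)
      } else {
        norm_context("rest")
      }
      traces[[paste(ch, bname)]] <- cvue_trace(
        recording, ch, band, grid, context,
        demean = demean, preprocess = preprocess,
        iqr_factor = iqr_factor, zero_phase = zero_phase)
    }
  }
  structure(
    list(trace = do.call(rbind, c(traces, list(make.row.names = FALSE))),
         settings = list(channels = channels,
                         bands = lapply(bands, unclass),
                         window_s = window_s, overlap = overlap,
                         demean = demean, preprocess = preprocess,
                         iqr_factor = iqr_factor, zero_phase = zero_phase,
                         baseline_used = !is.null(baseline)),
         condition = condition,
         meta = recording$meta,
         srate = recording$srate),
    class = "cvue_fit"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cvue_fit <- function(x, ...) {
  ne <- max(x$trace$epoch)
  cat(sprintf("<cvue_fit> %d epoch(s) x %d channel(s) x %d band(s), condition %s\n",
              ne, length(unique(x$trace$channel)),
              length(unique(x$trace$band)), x$condition))
  print(round(coef(x), 2))
  invisible(x)
}

#' @export
coef.cvue_fit <- function(object, ...) {
  with(object$trace,
       tapply(cvue_pct, list(channel = channel, band = band), mean))
}

#' @export
summary.cvue_fit <- function(object, ...) {
  tr <- object$trace
  agg <- aggregate(cvue_pct ~ channel + band, data = tr,
                   FUN = function(v) c(mean = mean(v), sd = sd(v),
                                       min = min(v), max = max(v)))
  out <- cbind(agg[c("channel", "band")], as.data.frame(agg$cvue_pct))
  out$n_epochs <- max(tr$epoch)
  structure(list(table = out, condition = object$condition,
                 subject = object$meta$subject, group = object$meta$group),
            class = "summary.cvue_fit")
}

#' @export
print.summary.cvue_fit <- function(x, ...) {
  cat(sprintf("CVUE summary (%%), condition %s", x$condition))
  if (!is.null(x$subject)) cat(sprintf(", subject %s", x$subject))
  if (!is.null(x$group)) cat(sprintf(", group %s", x$group))
  cat("\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.cvue_fit <- function(x, channel = NULL, smooth = FALSE, poly_order = 5,
                          window_length = 11, threshold = NULL, ...) {
  tr <- x$trace
  if (!is.null(channel)) tr <- tr[tr$channel == channel, ]
  bands <- unique(tr$band)
  old <- par(mfrow = c(length(bands), 1), mar = c(3.5, 4, 2, 1))
  on.exit(par(old))
  for (b in bands) {
    sub <- tr[tr$band == b, ]
    chs <- unique(sub$channel)
    ylim <- range(sub$cvue_pct)
    first <- TRUE
    for (i in seq_along(chs)) {
      v <- sub$cvue_pct[sub$channel == chs[i]]
      t <- sub$t_start_s[sub$channel == chs[i]]
      if (smooth && length(v) >= window_length) {
        v <- smooth_trace(v, poly_order, window_length)
      }
      if (first) {
        plot(t, v, type = "l", col = i, ylim = ylim, main = b,
             xlab = "time (s)", ylab = "CVUE (%)", ...)
        first <- FALSE
      } else {
        lines(t, v, col = i)
      }
    }
    if (!is.null(threshold)) abline(h = threshold, lty = 2)
    legend("topright", legend = chs, col = seq_along(chs), lty = 1,
           bty = "n", cex = 0.8)
  }
  invisible(x)
}

#' @export
as.data.frame.cvue_fit <- function(x, ...) {
  tr <- x$trace
  tr$subject <- x$meta$subject %||% NA_character_
  tr$group <- x$meta$group %||% NA_character_
  tr$condition <- x$condition
  tr[c("subject", "group", "condition", "channel", "band", "epoch",
       "t_start_s", "cvue_pct")]
}
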