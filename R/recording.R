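#' Multichannel EEG recording
#'
#' Container for a multichannel EEG time series in microvolts. Channels are
#' columns of a numeric matrix and carry 10-20-system labels; the sampling
#' rate and free-form subject metadata (subject id, group, condition,
#' provenance) travel with the data.
#'
#' @param data numeric matrix, one column per channel, one row per sample
#'   (a plain numeric vector is accepted for a single channel).
#' @param channels character vector of unique channel labels, e.g.
#'   `c("FC5", "T7")`. Defaults to the column names of `data`.
#' @param srate sampling rate in Hz (nominal acquisition rate 128 Hz).
#' @param meta named list of metadata. Recognised entries: `subject`,
#'   `group` (e.g. `"CFP"`, `"HWIP"`, `"HWNp"`), `condition` (`"rest"` or
#'   `"active"`), plus anything else (ground truth from the synthetic
#'   generator, filter provenance, units).
#'
#' @return an object of class `eeg_recording`.
#' @examples
#' x <- eeg_recording(cbind(FC5 = sin(1:256), T7 = cos(1:256)), srate = 128)
#' x
#' @export
eeg_recording <- function(data, channels = colnames(data), srate,
                          meta = list()) {
  if (is.null(dim(data))) data <- matrix(as.double(data), ncol = 1L)
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(channels)) stop("channel labels are required")
  channels <- as.character(channels)
  if (length(channels) != ncol(data)) {
    stop("length of 'channels' must match the number of data columns")
  }
  if (ncol(data) < 1L) stop("recording must contain at least one channel")
  if (anyDuplicated(channels)) {
    stop("duplicate channel labels: ",
         paste(unique(channels[duplicated(channels)]), collapse = ", "))
  }
  srate <- assert_number(srate, "srate", lower = 1e-9)
  if (!is.list(meta)) stop("'meta' must be a list")
  if (is.null(meta$units)) meta$units <- "uV"
  colnames(data) <- channels
  structure(
    list(data = data, channels = channels, srate = srate, meta = meta),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channel(s) x %d samples @ %g Hz (%.2f s)\n",
              ncol(x$data), nrow(x$data), x$srate, nrow(x$data) / x$srate))
  cat("  channels:", paste(x$channels, collapse = ", "), "\n")
  for (key in c("subject", "group", "condition")) {
    if (!is.null(x$meta[[key]])) cat(sprintf("  %s: %s\n", key, x$meta[[key]]))
  }
  invisible(x)
}

#' @export
plot.eeg_recording <- function(x, channels = x$channels, max_s = 10, ...) {
  idx <- seq_len(min(nrow(x$data), round(max_s * x$srate)))
  t <- (idx - 1) / x$srate
  old <- par(mfrow = c(length(channels), 1), mar = c(2.5, 4, 1, 1))
  on.exit(par(old))
  for (ch in channels) {
    plot(t, x$data[idx, ch], type = "l", xlab = "time (s)",
         ylab = sprintf("%s (uV)", ch), ...)
  }
  invisible(x)
}

#' Number of samples in a recording
#' @param x an `eeg_recording`.
#' @return integer sample count.
#' @export
n_samples <- function(x) {
  stopifnot(inherits(x, "eeg_recording"))
  nrow(x$data)
}

#' Restrict a recording to a set of channels
#'
#' Returns the recording restricted to the requested channels, in the
#' requested order, leaving sample values untouched. The analysis montage of
#' the pain pipeline keeps only the left fronto-central (FC5) and left
#' temporal (T7) electrodes.
#'
#' @param recording an `eeg_recording`.
#' @param labels character vector of channel labels to keep.
#' @return an `eeg_recording` with the requested channels.
#' @examples
#' r <- eeg_recording(cbind(FC5 = rnorm(128), T7 = rnorm(128), O1 = rnorm(128)),
#'                    srate = 128)
#' select_channels(r, c("FC5", "T7"))
#' @export
select_channels <- function(recording, labels) {
  stopifnot(inherits(recording, "eeg_recording"))
  labels <- as.character(labels)
  missing <- setdiff(labels, recording$channels)
  if (length(missing)) {
    stop("unknown channel(s): ", paste(missing, collapse = ", "))
  }
  eeg_recording(recording$data[, labels, drop = FALSE], labels,
                recording$srate, recording$meta)
}
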