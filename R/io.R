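#' Read a multichannel EEG recording from disk
#'
#' Two interchange formats are supported. CSV: one header row of channel
#' labels followed by one row per sample, comma-delimited, full-precision
#' decimal, no index column; metadata are read from a `<path>.meta.json`
#' sidecar when present. EDF: the European Data Format per its published
#' standard, with microvolt scaling applied from the physical/digital ranges
#' declared in the header.
#'
#' @param path file path.
#' @param format `"csv"` or `"edf"`; defaults to the file extension.
#' @param srate sampling rate in Hz for CSV input (EDF carries its own);
#'   default 128.
#' @return an [eeg_recording].
#' @seealso [write_recording()]
#' @export
read_recording <- function(path, format = c("auto", "csv", "edf"),
                           srate = 128) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
    csv = read_recording_csv(path, srate),
    edf = read_edf_recording(path)
  )
}

#' Write a multichannel EEG recording to disk
#'
#' Inverse of [read_recording()]. CSV output stores samples at full decimal
#' precision (`%.17g`) so that read-write round trips are bit-stable, with
#' metadata in a JSON sidecar. EDF output quantizes each channel to the
#' 16-bit digital range of its own physical extrema, so round trips agree to
#' within half a quantization step; subject/group/condition are stored in
#' the EDF patient and recording header fields.
#'
#' @param recording an [eeg_recording].
#' @param path output file path.
#' @param format `"csv"` or `"edf"`; defaults to the file extension.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path, format = c("auto", "csv", "edf")) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (nrow(recording$data) < 1L) stop("recording has no samples")
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  switch(format,
    csv = write_recording_csv(recording, path),
    edf = write_edf_recording(recording, path)
  )
  invisible(path)
}

read_recording_csv <- function(path, srate) {
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  header <- trimws(header)
  if (length(header) < 1L || any(header == "")) {
    stop("CSV header must contain one non-empty label per channel")
  }
  if (anyDuplicated(header)) {
    stop("duplicate channel labels in CSV header: ",
         paste(unique(header[duplicated(header)]), collapse = ", "))
  }
  raw <- utils::read.table(path, sep = ",", skip = 1L, header = FALSE,
                           colClasses = "numeric")
  if (ncol(raw) != length(header)) {
    stop("CSV rows have ", ncol(raw), " fields but header has ", length(header))
  }
  meta <- list()
  sidecar <- paste0(path, ".meta.json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$srate)) srate <- meta$srate
  }
  eeg_recording(as.matrix(raw), header, srate, meta)
}

write_recording_csv <- function(recording, path) {
  cols <- lapply(seq_along(recording$channels),
                 function(j) sprintf("%.17g", recording$data[, j]))
  lines <- c(paste(recording$channels, collapse = ","),
             do.call(paste, c(cols, sep = ",")))
  writeLines(lines, path)
  meta <- recording$meta
  meta$srate <- recording$srate
  keep <- !vapply(meta, function(v) is.matrix(v) || is.function(v), logical(1))
  jsonlite::write_json(meta[keep], paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
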