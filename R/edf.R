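# Minimal European Data Format (EDF) reader/writer.
#
# EDF stores a fixed-width ASCII header (256 bytes plus 256 per signal)
# followed by data records of 16-bit little-endian integers. Each signal
# declares a physical range (here microvolts) and a digital range; samples
# are affine-mapped between the two, so a write-read round trip is exact up
# to half of one 16-bit quantization step of the declared physical range.
# Subject, group and condition are carried in the patient and recording
# identification fields.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop("EDF field too long: '", x, "'")
  formatC(x, width = -width, flag = " ")
}

# Format a number into at most 8 ASCII characters, as EDF requires.
edf_num8 <- function(x) {
  for (digits in 7:1) {
    s <- sprintf("%.*g", digits, x)
    if (nchar(s) <= 8L) return(s)
  }
  stop("cannot represent ", x, " in 8 characters")
}

write_edf_recording <- function(recording, path) {
  data <- recording$data
  n <- nrow(data)
  ns <- ncol(data)
  srate <- recording$srate
  # one-second records when the length divides evenly, else a single record
  if (srate == round(srate) && n %% srate == 0L) {
    spr <- as.integer(srate)
    n_rec <- n %/% spr
    rec_dur <- 1
  } else {
    spr <- n
    n_rec <- 1L
    rec_dur <- n / srate
  }
  meta <- recording$meta
  patient <- if (!is.null(meta$subject)) as.character(meta$subject) else "X"
  rec_field <- paste(
    c(if (!is.null(meta$group)) paste0("group=", meta$group),
      if (!is.null(meta$condition)) paste0("condition=", meta$condition)),
    collapse = " ")
  if (rec_field == "") rec_field <- "X"

  dig_min <- -32768; dig_max <- 32767
  pmin <- apply(data, 2, min)
  pmax <- apply(data, 2, max)
  flat <- pmax - pmin < .Machine$double.eps
  pmin[flat] <- pmin[flat] - 1
  pmax[flat] <- pmax[flat] + 1
  # round-trip the physical range through its 8-character representation so
  # that quantization uses exactly the values a reader will parse
  pmin_s <- vapply(pmin, edf_num8, character(1))
  pmax_s <- vapply(pmax, edf_num8, character(1))
  pmin <- as.numeric(pmin_s)
  pmax <- as.numeric(pmax_s)

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)
  wr(edf_pad("0", 8))
  wr(edf_pad(patient, 80))
  wr(edf_pad(rec_field, 80))
  wr(edf_pad("01.01.00", 8))
  wr(edf_pad("00.00.00", 8))
  wr(edf_pad(256L * (ns + 1L), 8))
  wr(edf_pad("", 44))
  wr(edf_pad(n_rec, 8))
  wr(edf_pad(edf_num8(rec_dur), 8))
  wr(edf_pad(ns, 4))
  widths <- c(16, 80, 8, 8, 8, 8, 8, 80, 8, 32)
  fields <- list(recording$channels, rep("", ns), rep("uV", ns),
                 pmin_s, pmax_s,
                 rep(as.character(dig_min), ns), rep(as.character(dig_max), ns),
                 rep("", ns), rep(as.character(spr), ns), rep("", ns))
  for (k in seq_along(fields)) {
    for (j in seq_len(ns)) wr(edf_pad(fields[[k]][j], widths[k]))
  }

  scale <- (dig_max - dig_min) / (pmax - pmin)
  dig <- matrix(0L, n, ns)
  for (j in seq_len(ns)) {
    d <- round((data[, j] - pmin[j]) * scale[j] + dig_min)
    dig[, j] <- as.integer(pmin(pmax(d, dig_min), dig_max))
  }
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1L) * spr + 1L):(r * spr)
    for (j in seq_len(ns)) {
      writeBin(dig[rows, j], con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

read_edf_recording <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nc) trimws(readChar(con, nc, useBytes = TRUE))
  version <- rd(8)
  patient <- rd(80)
  rec_field <- rd(80)
  rd(8); rd(8)                                   # start date / time
  header_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L) stop("unreadable EDF header: bad signal count")
  rdv <- function(nc) vapply(seq_len(ns), function(i) rd(nc), character(1))
  labels <- rdv(16)
  rdv(80)                                        # transducer
  rdv(8)                                         # physical dimension
  pmin <- as.numeric(rdv(8))
  pmax <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8))
  dmax <- as.numeric(rdv(8))
  rdv(80)                                        # prefiltering
  spr <- as.integer(rdv(8))
  rdv(32)
  if (anyDuplicated(labels)) {
    stop("duplicate channel labels in EDF header: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  if (length(unique(spr)) != 1L) {
    stop("EDF signals with differing sampling rates are not supported")
  }
  seek(con, header_bytes)
  total <- n_rec * sum(spr)
  raw <- readBin(con, "integer", n = total, size = 2L, signed = TRUE,
                 endian = "little")
  if (length(raw) != total) stop("unreadable EDF: truncated data records")
  data <- matrix(0, n_rec * spr[1], ns)
  pos <- 0L
  for (r in seq_len(n_rec)) {
    for (j in seq_len(ns)) {
      block <- raw[(pos + 1L):(pos + spr[j])]
      data[((r - 1L) * spr[j] + 1L):(r * spr[j]), j] <-
        (block - dmin[j]) / (dmax[j] - dmin[j]) * (pmax[j] - pmin[j]) + pmin[j]
      pos <- pos + spr[j]
    }
  }
  meta <- list(provenance = sprintf("EDF v%s", version))
  if (patient != "" && patient != "X") meta$subject <- patient
  for (tok in strsplit(rec_field, " ", fixed = TRUE)[[1]]) {
    kv <- strsplit(tok, "=", fixed = TRUE)[[1]]
    if (length(kv) == 2L && kv[1] %in% c("group", "condition")) {
      meta[[kv[1]]] <- kv[2]
    }
  }
  eeg_recording(data, labels, spr[1] / rec_dur, meta)
}
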