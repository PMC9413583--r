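#' Synthetic EEG cohort specification
#'
#' Generative parameters for an EEG-like cohort with known band-envelope
#' variability. Each study arm (e.g. `CFP`, `HWIP`, `HWNp`) has its own
#' envelope modulation depths; each band component is a narrowband carrier
#' multiplied by a slowly varying envelope `1 + depth * m(t)` where `m` is
#' low-pass (< 2 Hz) Gaussian noise standardized to unit variance. The
#' per-epoch coefficient of variation of that envelope is a monotone,
#' approximately linear function of `depth` (measured mapping: mean CVUE in
#' percent is about `82 * depth` plus a small leakage floor), which makes
#' the generated ground truth recoverable by the analysis pipeline.
#'
#' Default depths place the healthy no-pain arm near 7% beta-band CVUE and
#' both pain arms near 23%, reproducing the reported separation of pain and
#' no-pain groups around the 10% decision threshold; sample sizes default to
#' the study design (4 chronic-pain, 7 healthy subjects, the latter serving
#' both as induced-pain and no-pain arms).
#'
#' @param n_per_group named integer vector: subjects per arm.
#' @param duration_s recording length in seconds; `duration_s * sampling_rate_hz`
#'   must be a whole number of samples.
#' @param sampling_rate_hz sampling rate (default 128 Hz).
#' @param band_mod_depth named list: arm -> named numeric of per-band
#'   envelope modulation depths in `[0, 1)`.
#' @param band_base_amp_uv named numeric of carrier amplitudes in uV.
#' @param dc_offset_uv hardware DC offset (default 4200 uV).
#' @param blink_rate_per_min,emg_burst_rate_per_min artifact event rates.
#' @param carrier `"tone"` (pure sinusoid at an integer-Hz band-centre
#'   frequency; deterministic envelope) or `"noise"` (band-limited Gaussian
#'   noise of bandwidth `carrier_bw_hz`; stochastic Rayleigh-type envelope).
#' @param carrier_bw_hz carrier bandwidth for `carrier = "noise"`.
#' @param subject_sd_depth between-subject standard deviation of the
#'   modulation depth (default 0.03).
#' @param hardware_chain emulate the acquisition chain (0.2-45 Hz bandpass
#'   plus 60 Hz notch) as a final step (default `TRUE`).
#' @param channels channel labels to synthesize (default FC5, T7).
#' @param seed master seed; all per-subject randomness derives from it.
#' @return an object of class `eeg_cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(CFP = 4, HWIP = 7, HWNp = 7),
                        duration_s = 60,
                        sampling_rate_hz = 128,
                        band_mod_depth = list(
                          CFP  = c(alpha = 0.12, beta = 0.27, gamma = 0.12),
                          HWIP = c(alpha = 0.12, beta = 0.27, gamma = 0.12),
                          HWNp = c(alpha = 0.05, beta = 0.05, gamma = 0.05)),
                        band_base_amp_uv = c(alpha = 20, beta = 10, gamma = 5),
                        dc_offset_uv = 4200,
                        blink_rate_per_min = 3,
                        emg_burst_rate_per_min = 1,
                        carrier = c("tone", "noise"),
                        carrier_bw_hz = 2,
                        subject_sd_depth = 0.03,
                        hardware_chain = TRUE,
                        channels = c("FC5", "T7"),
                        seed = 1L) {
  carrier <- match.arg(carrier)
  duration_s <- assert_number(duration_s, "duration_s", lower = 1e-9)
  sampling_rate_hz <- assert_number(sampling_rate_hz, "sampling_rate_hz",
                                    lower = 1e-9)
  n <- duration_s * sampling_rate_hz
  if (abs(n - round(n)) > 1e-8) {
    stop("duration_s * sampling_rate_hz must be a whole number of samples")
  }
  n_per_group <- unlist(n_per_group)            # tolerate YAML/JSON lists
  band_mod_depth <- lapply(band_mod_depth, unlist)
  band_base_amp_uv <- unlist(band_base_amp_uv)
  band_mod_depth <- band_mod_depth[names(n_per_group)]
  if (is.null(names(n_per_group)) || any(!nzchar(names(n_per_group)))) {
    stop("'n_per_group' must be a named vector of arm sizes")
  }
  if (any(n_per_group < 1)) stop("n_per_group must be >= 1 for every arm")
  if (any(vapply(band_mod_depth, is.null, logical(1)))) {
    stop("'band_mod_depth' must have an entry for every arm in 'n_per_group'")
  }
  depths <- unlist(band_mod_depth)
  if (any(depths < 0) || any(depths >= 1)) {
    stop("modulation depths must lie in [0, 1)")
  }
  if (any(band_base_amp_uv <= 0)) stop("carrier amplitudes must be > 0")
  structure(
    list(n_per_group = n_per_group, duration_s = duration_s,
         sampling_rate_hz = sampling_rate_hz,
         band_mod_depth = band_mod_depth,
         band_base_amp_uv = band_base_amp_uv,
         dc_offset_uv = assert_number(dc_offset_uv, "dc_offset_uv"),
         blink_rate_per_min = assert_number(blink_rate_per_min,
                                            "blink_rate_per_min", lower = 0),
         emg_burst_rate_per_min = assert_number(emg_burst_rate_per_min,
                                                "emg_burst_rate_per_min",
                                                lower = 0),
         carrier = carrier, carrier_bw_hz = carrier_bw_hz,
         subject_sd_depth = assert_number(subject_sd_depth,
                                          "subject_sd_depth", lower = 0),
         hardware_chain = assert_flag(hardware_chain, "hardware_chain"),
         channels = channels, seed = as.integer(seed)),
    class = "eeg_cohort_spec"
  )
}

#' @export
print.eeg_cohort_spec <- function(x, ...) {
  cat(sprintf("<eeg_cohort_spec> %s; %g s @ %g Hz, %s carrier, seed %d\n",
              paste(sprintf("%s n=%d", names(x$n_per_group), x$n_per_group),
                    collapse = ", "),
              x$duration_s, x$sampling_rate_hz, x$carrier, x$seed))
  for (g in names(x$band_mod_depth)) {
    cat(sprintf("  %s depths: %s\n", g,
                paste(sprintf("%s=%.2f", names(x$band_mod_depth[[g]]),
                              x$band_mod_depth[[g]]), collapse = " ")))
  }
  invisible(x)
}

# Integer-Hz carrier frequency inside a band. Integer frequencies complete
# whole cycles in every 1-s epoch at 128 Hz, so a tone carrier has an
# exactly constant per-epoch envelope. The alpha carrier sits at 9 Hz,
# one hertz below the band centre, to keep its leakage through the 12-Hz
# beta filter edge below the zero-modulation CVUE floor.
band_carrier_freq <- function(band_name, band) {
  known <- c(alpha = 9, beta = 20, gamma = 36)
  if (band_name %in% names(known)) return(known[[band_name]])
  round((band$low_hz + band$high_hz) / 2)
}

# Low-pass (< cutoff Hz) Gaussian modulator, standardized to unit variance.
slow_modulator <- function(n, srate, cutoff = 2) {
  ba <- signal::butter(4, cutoff / (srate / 2), type = "low")
  filt <- list(b = ba$b, a = ba$a, srate = srate)
  m <- apply_zero_phase(rnorm(n), filt)
  (m - mean(m)) / sd(m)
}

hardware_chain_filter <- function(x, srate) {
  nyq <- srate / 2
  hi <- min(45, 0.98 * nyq)
  ba <- signal::butter(5, c(0.2, hi) / nyq, type = "pass")
  y <- apply_zero_phase(x, list(b = ba$b, a = ba$a, srate = srate))
  if (nyq > 62) {
    notch <- signal::butter(2, c(58, 62) / nyq, type = "stop")
    y <- apply_zero_phase(y, list(b = notch$b, a = notch$a, srate = srate))
  }
  y
}

#' Generate one synthetic EEG recording
#'
#' Synthesizes one multichannel recording for a given study arm: per band,
#' a narrowband carrier multiplied by the arm's modulation envelope; then
#' blink/EMG artifacts, the emulated acquisition chain, and the hardware DC
#' offset. All generation parameters and the exact per-band envelopes are
#' stored in `meta$ground_truth`.
#'
#' @param spec an [cohort_spec].
#' @param condition arm label; must be a key of `spec$band_mod_depth`.
#' @param subject_seed integer seed for this recording.
#' @param subject_id optional subject identifier stored in the metadata.
#' @return an [eeg_recording] with ground-truth metadata.
#' @export
generate_recording <- function(spec, condition, subject_seed,
                               subject_id = NULL) {
  stopifnot(inherits(spec, "eeg_cohort_spec"))
  if (!condition %in% names(spec$band_mod_depth)) {
    stop("unknown condition label: ", condition)
  }
  if (spec$duration_s <= 0) stop("non-positive duration")
  srate <- spec$sampling_rate_hz
  n <- as.integer(round(spec$duration_s * srate))
  t <- (seq_len(n) - 1) / srate
  bands <- eeg_bands()
  band_names <- intersect(names(spec$band_base_amp_uv), names(bands))
  depths <- spec$band_mod_depth[[condition]]

  rec <- with_seed(subject_seed, {
    # subject-level depth heterogeneity, shared across channels
    subj_depths <- vapply(band_names, function(b) {
      d <- depths[[b]] + rnorm(1, 0, spec$subject_sd_depth)
      min(max(d, 0), 0.95)
    }, numeric(1))
    envelopes <- list()
    data <- matrix(0, n, length(spec$channels),
                   dimnames = list(NULL, spec$channels))
    for (ch in spec$channels) {
      envelopes[[ch]] <- list()
      for (b in band_names) {
        band <- bands[[b]]
        amp <- spec$band_base_amp_uv[[b]]
        env <- pmax(1 + subj_depths[[b]] * slow_modulator(n, srate), 0.05)
        carrier <- if (spec$carrier == "tone") {
          f0 <- band_carrier_freq(b, band)
          sin(2 * pi * f0 * t + runif(1, 0, 2 * pi))
        } else {
          f0 <- band_carrier_freq(b, band)
          bw <- spec$carrier_bw_hz / 2
          lo <- max(band$low_hz, f0 - bw)
          hi <- min(band$high_hz, f0 + bw)
          ba <- signal::butter(5, c(lo, hi) / (srate / 2), type = "pass")
          w <- apply_zero_phase(rnorm(n), list(b = ba$b, a = ba$a,
                                               srate = srate))
          w / sd(w) / sqrt(2)
        }
        data[, ch] <- data[, ch] + amp * env * carrier
        envelopes[[ch]][[b]] <- env
      }
    }
    meta <- list(
      subject = subject_id, group = condition, condition = "rest",
      provenance = "synthetic",
      ground_truth = list(depths = subj_depths, envelopes = envelopes,
                          carrier = spec$carrier,
                          spec_seed = spec$seed, subject_seed = subject_seed)
    )
    eeg_recording(data, spec$channels, srate, meta)
  })

  if (spec$blink_rate_per_min > 0 || spec$emg_burst_rate_per_min > 0) {
    rec <- inject_artifacts(rec, spec$blink_rate_per_min,
                            spec$emg_burst_rate_per_min,
                            seed = child_seed(subject_seed, 17L))
  }
  if (spec$hardware_chain) {
    for (j in seq_len(ncol(rec$data))) {
      rec$data[, j] <- hardware_chain_filter(rec$data[, j], srate)
    }
    rec$meta$provenance <- paste(rec$meta$provenance,
                                 "+ hardware chain (0.2-45 Hz bandpass, 60 Hz notch)")
  }
  rec$data <- rec$data + spec$dc_offset_uv
  rec
}

#' Inject blink and EMG artifacts into a recording
#'
#' Blink events are 0.3-s raised-cosine transients with peak amplitude 10
#' background standard deviations; EMG bursts are 0.5-s broadband Gaussian
#' segments with 5-SD amplitude. Event times are Poisson; the same events
#' hit every channel (amplitudes scale with each channel's own background
#' SD). Ground-truth event onsets and affected sample indices are appended
#' to `meta$artifacts`. Zero rates return the input unchanged.
#'
#' @param recording an [eeg_recording].
#' @param blink_rate_per_min,emg_burst_rate_per_min event rates (>= 0).
#' @param seed integer seed.
#' @param blink_amp_sd,emg_amp_sd event amplitudes in units of the
#'   channel's background standard deviation (defaults 10 and 5).
#' @return the recording with artifacts added and ground truth in
#'   `meta$artifacts`.
#' @export
inject_artifacts <- function(recording, blink_rate_per_min,
                             emg_burst_rate_per_min, seed,
                             blink_amp_sd = 10, emg_amp_sd = 5) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (blink_rate_per_min < 0 || emg_burst_rate_per_min < 0) {
    stop("artifact rates must be >= 0")
  }
  if (blink_rate_per_min == 0 && emg_burst_rate_per_min == 0) {
    return(recording)
  }
  srate <- recording$srate
  n <- nrow(recording$data)
  dur_min <- n / srate / 60
  with_seed(seed, {
    blink_len <- max(2L, round(0.3 * srate))
    emg_len <- max(2L, round(0.5 * srate))
    blink_wave <- (1 - cos(2 * pi * seq_len(blink_len) / (blink_len + 1))) / 2
    n_blink <- rpois(1, blink_rate_per_min * dur_min)
    n_emg <- rpois(1, emg_burst_rate_per_min * dur_min)
    blink_on <- sort(sample.int(max(n - blink_len, 1L), n_blink,
                                replace = TRUE))
    emg_on <- sort(sample.int(max(n - emg_len, 1L), n_emg, replace = TRUE))
    emg_noise <- lapply(seq_len(n_emg), function(i) rnorm(emg_len))
    for (j in seq_len(ncol(recording$data))) {
      bg_sd <- sd(recording$data[, j] - mean(recording$data[, j]))
      for (on in blink_on) {
        idx <- on:(on + blink_len - 1L)
        recording$data[idx, j] <- recording$data[idx, j] +
          blink_amp_sd * bg_sd * blink_wave
      }
      for (i in seq_along(emg_on)) {
        idx <- emg_on[i]:(emg_on[i] + emg_len - 1L)
        recording$data[idx, j] <- recording$data[idx, j] +
          emg_amp_sd * bg_sd * emg_noise[[i]]
      }
    }
    blink_idx <- unique(unlist(lapply(blink_on,
                                      function(on) on:(on + blink_len - 1L))))
    emg_idx <- unique(unlist(lapply(emg_on,
                                    function(on) on:(on + emg_len - 1L))))
    recording$meta$artifacts <- list(
      blink_onsets = blink_on, blink_idx = blink_idx,
      blink_len = blink_len,
      emg_onsets = emg_on, emg_idx = emg_idx, emg_len = emg_len,
      seed = seed)
    recording
  })
}

#' Generate a full synthetic cohort
#'
#' One recording per subject per arm, plus a metadata table with the
#' ground-truth modulation depths actually drawn for each subject.
#'
#' @param spec an [cohort_spec].
#' @return an object of class `eeg_cohort`: list with `recordings` (named
#'   list of [eeg_recording]) and `metadata` (data frame).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "eeg_cohort_spec"))
  recordings <- list()
  meta_rows <- list()
  counter <- 0L
  for (g in names(spec$n_per_group)) {
    for (i in seq_len(spec$n_per_group[[g]])) {
      counter <- counter + 1L
      id <- sprintf("%s_%02d", g, i)
      s <- child_seed(spec$seed, counter)
      rec <- generate_recording(spec, g, s, subject_id = id)
      recordings[[id]] <- rec
      row <- data.frame(subject = id, group = g, condition = "rest",
                        seed = s, stringsAsFactors = FALSE)
      for (b in names(rec$meta$ground_truth$depths)) {
        row[[paste0("depth_", b)]] <- rec$meta$ground_truth$depths[[b]]
      }
      meta_rows[[id]] <- row
    }
  }
  structure(list(recordings = recordings,
                 metadata = do.call(rbind, c(meta_rows,
                                             list(make.row.names = FALSE))),
                 spec = spec),
            class = "eeg_cohort")
}

#' @export
print.eeg_cohort <- function(x, ...) {
  cat(sprintf("<eeg_cohort> %d recording(s): %s\n", length(x$recordings),
              paste(sprintf("%s n=%d", names(x$spec$n_per_group),
                            x$spec$n_per_group), collapse = ", ")))
  invisible(x)
}

#' Simulate cohorts from a specification
#'
#' @param object an [cohort_spec].
#' @param nsim number of cohorts.
#' @param seed optional master seed overriding `object$seed`.
#' @param ... unused.
#' @return a single `eeg_cohort` when `nsim = 1`, else a list of them.
#' @export
simulate.eeg_cohort_spec <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) object$seed <- as.integer(seed)
  if (nsim == 1) return(generate_cohort(object))
  lapply(seq_len(nsim), function(k) {
    sp <- object
    sp$seed <- child_seed(object$seed, 100000L + k)
    generate_cohort(sp)
  })
}

#' Ground-truth envelope CV of a generated recording
#'
#' Mean per-epoch coefficient of variation (in percent) of the stored
#' generator envelope for one channel and band -- the quantity the analysis
#' pipeline is expected to recover.
#'
#' @param recording a synthetic [eeg_recording] with ground-truth metadata.
#' @param channel,band_name channel label and band name.
#' @param grid an [epoch_grid].
#' @return mean envelope CV in percent.
#' @export
ground_truth_cvue <- function(recording, channel = "FC5",
                              band_name = "beta",
                              grid = epoch_grid(1, 0.5, recording$srate)) {
  gt <- recording$meta$ground_truth
  if (is.null(gt)) stop("recording carries no ground-truth metadata")
  env <- gt$envelopes[[channel]][[band_name]]
  if (is.null(env)) stop("no stored envelope for ", channel, "/", band_name)
  segs <- segment_epochs(env, grid)
  mean(apply(segs$epochs, 2, function(e) sd(e) / mean(e) * 100))
}
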