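test_that("generation is bit-identical under fixed seeds", {
  spec <- cohort_spec(duration_s = 10, seed = 4)
  r1 <- generate_recording(spec, "CFP", 99)
  r2 <- generate_recording(spec, "CFP", 99)
  expect_identical(r1$data, r2$data)
  expect_identical(r1$meta$ground_truth$depths, r2$meta$ground_truth$depths)
  co1 <- generate_cohort(cohort_spec(duration_s = 5, seed = 21,
                                     n_per_group = c(CFP = 2, HWNp = 2)))
  co2 <- generate_cohort(cohort_spec(duration_s = 5, seed = 21,
                                     n_per_group = c(CFP = 2, HWNp = 2)))
  expect_identical(co1$metadata, co2$metadata)
  expect_identical(co1$recordings[["CFP_02"]]$data,
                   co2$recordings[["CFP_02"]]$data)
})

test_that("the hardware DC offset is reproduced near 4200 uV", {
  spec <- cohort_spec(duration_s = 10, seed = 2)
  rec <- generate_recording(spec, "HWNp", 31)
  for (ch in rec$channels) {
    expect_lt(abs(mean(rec$data[, ch]) - 4200) / 4200, 0.01)
  }
})

test_that("invalid specifications are refused", {
  expect_error(cohort_spec(duration_s = 10.003), "whole number")
  expect_error(cohort_spec(n_per_group = c(CFP = 0)), ">= 1")
  expect_error(cohort_spec(band_mod_depth = list(
    CFP = c(alpha = 0.1, beta = 1.2, gamma = 0.1),
    HWIP = c(alpha = 0.1, beta = 0.1, gamma = 0.1),
    HWNp = c(alpha = 0.1, beta = 0.1, gamma = 0.1))), "\\[0, 1\\)")
  spec <- cohort_spec(duration_s = 5)
  expect_error(generate_recording(spec, "unknown_arm", 1), "unknown condition")
})

test_that("zero-modulation artifact-free recordings have near-constant envelopes", {
  spec <- flat_spec(duration_s = 30, seed = 6)
  rec <- generate_recording(spec, "flat", 11)
  fit <- cvue(rec)
  expect_lt(max(fit$trace$cvue_pct), 2)     # every band, every epoch
})

test_that("zero artifact rates leave a recording untouched", {
  spec <- flat_spec(duration_s = 5, seed = 8)
  rec <- generate_recording(spec, "flat", 3)
  expect_identical(inject_artifacts(rec, 0, 0, seed = 1), rec)
})

test_that("artifact event counts follow the configured Poisson rates", {
  spec <- flat_spec(duration_s = 240, seed = 1)   # 4 minutes
  rec <- generate_recording(spec, "flat", 12)
  counts <- vapply(1:100, function(s) {
    out <- inject_artifacts(rec, blink_rate_per_min = 3,
                            emg_burst_rate_per_min = 0, seed = s)
    length(out$meta$artifacts$blink_onsets)
  }, numeric(1))
  # expectation 12 events; Monte-Carlo mean within ~3.2 standard errors
  expect_lt(abs(mean(counts) - 12), 3.2 * sqrt(12 / 100))
})

test_that("huge blinks have every sample above the detection fence", {
  spec <- flat_spec(duration_s = 20, seed = 9)
  rec <- generate_recording(spec, "flat", 7)
  out <- inject_artifacts(rec, blink_rate_per_min = 6,
                          emg_burst_rate_per_min = 0, seed = 5,
                          blink_amp_sd = 1000)
  gt <- out$meta$artifacts
  expect_gt(length(gt$blink_idx), 0)
  mask <- detect_outliers(remove_dc_offset(out$data[, "FC5"]))
  expect_true(all(mask$flag[gt$blink_idx]))
})

test_that("default-amplitude artifact events are caught by the fence detector", {
  spec <- cohort_spec(duration_s = 60, n_per_group = c(CFP = 1, HWNp = 1),
                      seed = 14)
  detected <- 0L; total <- 0L
  for (arm in c("CFP", "HWNp")) {
    rec <- generate_recording(spec, arm, 1400L + match(arm, c("CFP", "HWNp")))
    gt <- rec$meta$artifacts
    if (is.null(gt) || length(gt$blink_onsets) == 0) next
    mask <- detect_outliers(remove_dc_offset(rec$data[, "FC5"]))
    for (on in gt$blink_onsets) {
      total <- total + 1L
      if (any(mask$flag[on:(on + gt$blink_len - 1L)])) detected <- detected + 1L
    }
  }
  expect_gt(total, 0L)
  expect_identical(detected, total)
})

test_that("cohorts have one recording per subject with ground-truth depths", {
  spec <- cohort_spec(duration_s = 5, seed = 33)
  co <- generate_cohort(spec)
  expect_length(co$recordings, 4 + 7 + 7)
  expect_identical(as.vector(table(co$metadata$group)[c("CFP", "HWIP", "HWNp")]),
                   c(4L, 7L, 7L))
  expect_true(all(c("depth_alpha", "depth_beta", "depth_gamma") %in%
                    names(co$metadata)))
  expect_identical(co$metadata$subject[1], "CFP_01")
  sim <- simulate(spec, nsim = 1)
  expect_identical(sim$metadata, co$metadata)
})

test_that("the pipeline recovers the stored generator envelope CV", {
  spec <- cohort_spec(duration_s = 30, n_per_group = c(CFP = 2, HWNp = 2),
                      blink_rate_per_min = 0, emg_burst_rate_per_min = 0,
                      seed = 10)
  co <- generate_cohort(spec)
  for (id in names(co$recordings)) {
    rec <- co$recordings[[id]]
    fit <- cvue(rec, channels = "FC5", bands = eeg_bands()["beta"])
    truth <- ground_truth_cvue(rec, "FC5", "beta")
    err <- abs(mean(fit$trace$cvue_pct) - truth)
    expect_lt(err, max(1, 0.10 * truth))
  }
})

test_that("mean beta CVUE increases monotonically with modulation depth", {
  for (s in 1:10) {
    lo <- generate_recording(flat_spec(10, depths = c(alpha = 0.05, beta = 0.1,
                                                      gamma = 0.05)),
                             "flat", s)
    hi <- generate_recording(flat_spec(10, depths = c(alpha = 0.05, beta = 0.3,
                                                      gamma = 0.05)),
                             "flat", s)   # paired seed
    m_lo <- mean(cvue(lo, channels = "FC5",
                      bands = eeg_bands()["beta"])$trace$cvue_pct)
    m_hi <- mean(cvue(hi, channels = "FC5",
                      bands = eeg_bands()["beta"])$trace$cvue_pct)
    expect_gt(m_hi, m_lo)
  }
})

test_that("noise carriers produce valid recordings with stochastic envelopes", {
  spec <- cohort_spec(duration_s = 10, n_per_group = c(flat = 1),
                      band_mod_depth = list(flat = c(alpha = 0, beta = 0,
                                                     gamma = 0)),
                      carrier = "noise", blink_rate_per_min = 0,
                      emg_burst_rate_per_min = 0, subject_sd_depth = 0,
                      seed = 12)
  rec <- generate_recording(spec, "flat", 44)
  fit <- cvue(rec, channels = "FC5", bands = eeg_bands()["beta"])
  # a stochastic narrowband carrier fluctuates well above the tone floor
  expect_gt(mean(fit$trace$cvue_pct), 2)
})
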