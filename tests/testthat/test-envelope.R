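test_that("epoch counts follow the sliding-window formula", {
  grid <- epoch_grid(1, 0.5, 128)
  segs <- segment_epochs(rnorm(7680), grid)
  expect_equal(ncol(segs$epochs), 119)                  # 60 s at 128 Hz
  expect_equal(segs$starts[2] - segs$starts[1], 64)
  expect_equal(ncol(segment_epochs(rnorm(128), grid)$epochs), 1)
  expect_error(segment_epochs(rnorm(127), grid), "shorter")
  # consecutive epochs share exactly the overlap fraction of samples
  x <- seq_len(512)
  s <- segment_epochs(x, grid)
  expect_identical(s$epochs[65:128, 1], s$epochs[1:64, 2])
})

test_that("epoch counts match brute-force enumeration on random grids", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(10:3000, 1)
    w <- sample(2:200, 1)
    h <- sample(1:w, 1)
    expected <- n_epochs_oracle(n, w, h)
    grid <- epoch_grid(w, 1 - h / w, 1)   # srate 1 => window_s = w samples
    expect_identical(grid$window, w)
    expect_identical(grid$hop, h)
    if (expected == 0) {
      expect_error(segment_epochs(rnorm(n), grid))
    } else {
      expect_identical(ncol(segment_epochs(rnorm(n), grid)$epochs), expected)
    }
  }
})

test_that("the analytic envelope of a whole-cycle sinusoid is flat", {
  t <- (0:127) / 128
  a <- compute_aue(sin(2 * pi * 8 * t))
  interior <- a[6:(length(a) - 5)]
  expect_true(all(abs(interior - 1) < 0.02))
  # positive scaling passes straight through
  epoch <- sin(2 * pi * 8 * t + 0.3)
  expect_equal(compute_aue(3.7 * epoch), 3.7 * compute_aue(epoch),
               tolerance = 1e-12)
})

test_that("the envelope tracks a known amplitude modulator", {
  srate <- 128
  t <- (0:(4 * srate - 1)) / srate
  modulator <- 1 + 0.5 * sin(2 * pi * 1 * t)
  x <- modulator * sin(2 * pi * 20 * t)
  a <- compute_aue(x)
  core <- (srate / 4):(length(a) - srate / 4)    # away from epoch edges
  rel_err <- abs(a[core] - modulator[core]) / modulator[core]
  expect_lt(max(rel_err), 0.05)
})

test_that("CVUE is the percent coefficient of variation with n-1 std", {
  expect_equal(compute_cvue(rep(2.5, 10)), 0)
  expect_equal(compute_cvue(c(1, 3)), sqrt(2) / 2 * 100)
  expect_equal(round(compute_cvue(c(1, 3)), 2), 70.71)
  a <- abs(rnorm(64)) + 0.1
  expect_equal(compute_cvue(5.5 * a), compute_cvue(a), tolerance = 1e-12)
  expect_error(compute_cvue(rep(0, 8)), "degenerate")
})

test_that("pipeline CVUE matches the explicit-DFT oracle", {
  set.seed(13)
  for (i in 1:100) {
    n <- sample(c(64, 128), 1)
    epoch <- rnorm(n) + sin(2 * pi * sample(5:20, 1) * (0:(n - 1)) / n)
    mine <- compute_cvue(compute_aue(epoch))
    oracle <- cvue_oracle(aue_oracle(epoch))
    expect_lt(abs(mine - oracle) / oracle, 1e-9)
  }
})

test_that("CVUE traces are invariant to positive rescaling of the raw data", {
  spec <- flat_spec(duration_s = 10, seed = 5,
                    depths = c(alpha = 0.1, beta = 0.2, gamma = 0.1))
  rec <- generate_recording(spec, "flat", 77)
  fit1 <- cvue(rec)
  set.seed(1)
  for (c_scale in exp(runif(3, -3, 3))) {
    rec2 <- rec
    rec2$data <- rec2$data * c_scale
    fit2 <- cvue(rec2)
    expect_equal(fit2$trace$cvue_pct, fit1$trace$cvue_pct, tolerance = 1e-9)
  }
})

test_that("Savitzky-Golay smoothing has the polynomial reproduction property", {
  t <- seq(-1, 1, length.out = 101)
  poly <- 3 + 2 * t - t^2 + 0.5 * t^3
  sm <- smooth_trace(poly, poly_order = 5, window_length = 11)
  interior <- 6:96
  expect_equal(sm[interior], poly[interior], tolerance = 1e-9)
  expect_equal(smooth_trace(rep(4.2, 51), 5, 11), rep(4.2, 51),
               tolerance = 1e-9)
  set.seed(2)
  for (i in 1:20) {
    z <- rnorm(101)
    expect_lt(var(smooth_trace(z, 3, 11)), var(z))
  }
  expect_error(smooth_trace(rnorm(50), 5, 10), "odd")
  expect_error(smooth_trace(rnorm(50), 5, 5), "exceed")
  expect_error(smooth_trace(rnorm(5), 3, 7), "trace length")
})

test_that("smoothing a fit smooths every channel-band trace", {
  spec <- flat_spec(duration_s = 20, seed = 3,
                    depths = c(alpha = 0.1, beta = 0.3, gamma = 0.1))
  fit <- cvue(generate_recording(spec, "flat", 5))
  sm <- smooth_trace(fit, poly_order = 3, window_length = 7)
  expect_s3_class(sm, "cvue_fit")
  raw_beta <- fit$trace$cvue_pct[fit$trace$band == "beta" &
                                   fit$trace$channel == "FC5"]
  sm_beta <- sm$trace$cvue_pct[sm$trace$band == "beta" &
                                 sm$trace$channel == "FC5"]
  expect_equal(sm_beta, smooth_trace(raw_beta, 3, 7))
})
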