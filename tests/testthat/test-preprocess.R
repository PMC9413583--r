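test_that("DC offset removal recentres a channel exactly", {
  expect_equal(remove_dc_offset(c(4201, 4199, 4200)), c(1, -1, 0))
  x <- c(-2, 0, 2)
  expect_equal(remove_dc_offset(x), x)    # zero-mean input unchanged
  expect_error(remove_dc_offset(numeric(0)), "empty")
  for (i in 1:20) {
    set.seed(i)
    y <- remove_dc_offset(rnorm(500, mean = runif(1, -5000, 5000), sd = 50))
    expect_lt(abs(mean(y)), 1e-9)
  }
})

test_that("quartile fences flag exactly the out-of-fence samples", {
  x <- c(1:9, 100)
  mask <- detect_outliers(x)
  expect_identical(which(mask$flag), 10L)
  # fences from hand-computed type-7 quartiles: Q1 3.25, Q3 7.75, IQR 4.5
  expect_equal(unname(mask$quartiles), c(3.25, 7.75))
  expect_equal(unname(mask$bounds), c(3.25 - 6.75, 7.75 + 6.75))

  const <- detect_outliers(rep(5, 10))
  expect_false(any(const$flag))           # IQR = 0, fences at the constant

  inside <- detect_outliers(c(4, 5, 6, 5, 4, 6))
  expect_false(any(inside$flag))
  expect_error(detect_outliers(c(1, 2, 3)), "too short")
})

test_that("fence detection matches the brute-force oracle on random series", {
  for (i in 1:1000) {
    set.seed(i)
    n <- sample(4:60, 1)
    x <- rnorm(n, sd = sample(c(1, 10, 100), 1))
    if (i %% 7 == 0) x[sample(n, 1)] <- x[sample(n, 1)] * 50  # plant spikes
    expect_identical(detect_outliers(x)$flag, outlier_oracle(x))
  }
})

test_that("outlier replacement interpolates linearly and touches nothing else", {
  expect_equal(replace_outliers(c(0, 10, 0), c(FALSE, TRUE, FALSE)),
               c(0, 0, 0))
  expect_equal(replace_outliers(c(0, 99, 99, 3), c(FALSE, TRUE, TRUE, FALSE)),
               c(0, 1, 2, 3))
  x <- rnorm(50)
  expect_identical(replace_outliers(x, rep(FALSE, 50)), x)
  # leading/trailing runs take the nearest clean value
  expect_equal(replace_outliers(c(99, 99, 1, 2), c(TRUE, TRUE, FALSE, FALSE)),
               c(1, 1, 1, 2))
  expect_equal(replace_outliers(c(1, 2, 99), c(FALSE, FALSE, TRUE)),
               c(1, 2, 2))
  expect_error(replace_outliers(c(9, 9, 1), c(TRUE, TRUE, FALSE)),
               "two clean")
})

test_that("replacement is bounded by clean neighbours and idempotent", {
  for (i in 1:50) {
    set.seed(100 + i)
    x <- rnorm(200)
    spikes <- sample(10:190, 5)
    x[spikes] <- x[spikes] + sample(c(-1, 1), 5, replace = TRUE) * 25
    mask <- detect_outliers(x)
    y <- replace_outliers(x, mask)
    expect_identical(y[!mask$flag], x[!mask$flag])
    # repaired values stay inside the clean range
    expect_true(all(y >= min(x[!mask$flag]) & y <= max(x[!mask$flag])))
    # re-detection with frozen fences flags nothing
    expect_false(any(y < mask$bounds[1] | y > mask$bounds[2]))
  }
})
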