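test_that("fully separated 4-vs-7 groups give the exact enumeration p-value", {
  a <- c(20, 22, 25, 23)
  b <- c(5, 6, 7, 8, 6, 5, 7)
  res <- permutation_test(a, b, n_permutations = 5000, seed = 1)
  expect_identical(res$scheme, "exact_enumeration")
  expect_identical(res$n_permutations, 330L)          # choose(11, 4)
  expect_equal(res$p_value, 1 / 330)
  expect_equal(res$statistic, abs(mean(a) - mean(b)))
})

test_that("identical groups give statistic 0 and p 1", {
  v <- c(3, 4, 5)
  res <- permutation_test(v, v, seed = 2)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_error(permutation_test(1, c(2, 3)), "at least 2")
})

test_that("p-values are invariant to exchanging the group labels", {
  set.seed(5)
  a <- rnorm(5, 1); b <- rnorm(6)
  expect_equal(permutation_test(a, b, seed = 3)$p_value,
               permutation_test(b, a, seed = 3)$p_value)
})

test_that("Monte-Carlo p-values converge to the exact enumeration", {
  set.seed(7)
  a <- rnorm(8, mean = 1.2)
  b <- rnorm(8)
  # exact reference by full enumeration (choose(16,8) = 12870 relabelings)
  pooled <- c(a, b)
  obs <- abs(mean(a) - mean(b))
  combos <- combn(16, 8)
  null_stats <- apply(combos, 2, function(idx) {
    abs(mean(pooled[idx]) - mean(pooled[-idx]))
  })
  p_exact <- mean(null_stats >= obs - 1e-12)
  res <- permutation_test(a, b, n_permutations = 5000, seed = 11)
  expect_identical(res$scheme, "monte_carlo")
  se <- sqrt(p_exact * (1 - p_exact) / 5000)
  expect_lt(abs(res$p_value - p_exact), 2 * se + 1 / 5001)
})

test_that("Spearman rho handles monotone and tied data", {
  expect_equal(spearman_perm(1:6, (1:6)^3)$rho, 1)
  expect_equal(spearman_perm(1:6, -exp(1:6))$rho, -1)
  # hand rank arithmetic with one tie: ranks y = 2.5, 2.5, 4, 1
  res <- spearman_perm(1:4, c(2, 2, 3, 1))
  expect_equal(res$rho, -1.5 / sqrt(5 * 4.5), tolerance = 1e-12)
  expect_identical(res$scheme, "exact_enumeration")
  expect_true(res$p_value > 0 && res$p_value <= 1)
  expect_error(spearman_perm(rep(1, 4), 1:4), "constant")
  expect_error(spearman_perm(1:2, 1:2), "3 pairs")
})

test_that("Spearman permutation p agrees with the exact null at small n", {
  set.seed(9)
  x <- rnorm(5); y <- rnorm(5)
  res <- spearman_perm(x, y)
  # independent check: exhaustive null via cor over all 120 permutations
  perms <- cvue:::all_permutations(5)
  null_rho <- vapply(perms,
                     function(p) cor(rank(x), rank(y)[p]), numeric(1))
  expect_equal(res$p_value,
               mean(abs(null_rho) >= abs(res$rho) - 1e-12))
})

test_that("the pain call thresholds mean beta CVUE at FC5 strictly", {
  expect_true(classify_pain(c(23.07))$present)
  expect_false(classify_pain(c(5))$present)
  expect_false(classify_pain(c(10))$present)           # boundary: strict >
  expect_true(classify_pain(c(10 + 1e-9))$present)
  call <- classify_pain(c(20, 26.14))
  expect_equal(call$evidence_pct, 23.07)
  expect_true(call$present)
  expect_error(classify_pain(c(12), band = "alpha"), "beta")
  expect_error(classify_pain(c(12), channel = "T7"), "FC5")
  expect_error(classify_pain(c(12), condition = "active"), "rest")
})

test_that("the pain call works directly on a fitted object", {
  spec <- flat_spec(duration_s = 10, seed = 2,
                    depths = c(alpha = 0.05, beta = 0.3, gamma = 0.05))
  fit <- cvue(generate_recording(spec, "flat", 21))
  call <- classify_pain(fit)
  expect_equal(call$evidence_pct,
               mean(fit$trace$cvue_pct[fit$trace$band == "beta" &
                                         fit$trace$channel == "FC5"]))
})

test_that("the normality screen reports a standard test object", {
  set.seed(1)
  expect_s3_class(normality_screen(rnorm(20)), "htest")
})
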