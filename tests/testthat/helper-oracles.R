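# Independent oracles used by property and acceptance tests. These
# deliberately take slow, explicit routes (O(n^2) DFT sums, sort-based
# quantiles) so that they share no code path with the package internals.

# Explicit DFT (no FFT).
dft_slow <- function(x) {
  n <- length(x)
  k <- 0:(n - 1)
  W <- exp(-2i * pi * outer(k, k) / n)
  as.vector(W %*% x)
}

idft_slow <- function(X) {
  n <- length(X)
  k <- 0:(n - 1)
  W <- exp(2i * pi * outer(k, k) / n)
  as.vector(W %*% X) / n
}

# Analytic-signal envelope via the explicit DFT.
aue_oracle <- function(epoch, demean = TRUE) {
  if (demean) epoch <- epoch - sum(epoch) / length(epoch)
  n <- length(epoch)
  X <- dft_slow(epoch)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(idft_slow(X * h))
}

# CVUE with explicit sums.
cvue_oracle <- function(a) {
  m <- sum(a) / length(a)
  s <- sqrt(sum((a - m)^2) / (length(a) - 1))
  s / m * 100
}

# Sort-based type-7 quantile.
quantile7_oracle <- function(x, p) {
  xs <- sort(x)
  h <- (length(xs) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

# Explicit fence comparison.
outlier_oracle <- function(x, factor = 1.5) {
  q1 <- quantile7_oracle(x, 0.25)
  q3 <- quantile7_oracle(x, 0.75)
  iqr <- q3 - q1
  x < q1 - factor * iqr | x > q3 + factor * iqr
}

# Brute-force epoch count: enumerate candidate start positions.
n_epochs_oracle <- function(n, window, hop) {
  count <- 0L
  s <- 1L
  while (s + window - 1L <= n) {
    count <- count + 1L
    s <- s + hop
  }
  count
}

# Small artifact-free tone cohort spec used across tests.
flat_spec <- function(duration_s = 20, seed = 1, depths = c(alpha = 0, beta = 0, gamma = 0)) {
  cohort_spec(n_per_group = c(flat = 1),
              duration_s = duration_s,
              band_mod_depth = list(flat = depths),
              blink_rate_per_min = 0, emg_burst_rate_per_min = 0,
              subject_sd_depth = 0, seed = seed)
}
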