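#' Permutation test for a difference in group means
#'
#' Two-sided nonparametric test of a group difference in subject-level
#' values (here: per-subject mean CVUE). The statistic is the absolute
#' difference of group means; the null distribution is built by relabeling
#' subjects. When the number of distinct relabelings `choose(na+nb, na)` is
#' at most `n_permutations`, the full enumeration is used and the p-value
#' is the exact proportion of relabelings with a statistic at least as
#' large as observed; otherwise `n_permutations` Monte-Carlo relabelings
#' are drawn and the p-value uses the add-one correction
#' `(#{null >= obs} + 1) / (n + 1)`.
#'
#' @param group_a,group_b numeric vectors of subject-level values, each of
#'   length at least 2.
#' @param n_permutations permutation budget (default 5000).
#' @param seed integer seed for the Monte-Carlo scheme.
#' @return an object of class `cvue_permtest`: list with `statistic`,
#'   `p_value`, `scheme` (`"exact_enumeration"` or `"monte_carlo"`),
#'   `n_permutations` (size of the null set actually used), `n_a`, `n_b`,
#'   `seed`.
#' @examples
#' permutation_test(c(20, 22, 25, 23), c(5, 6, 7, 8, 6, 5, 7), seed = 1)
#' @export
permutation_test <- function(group_a, group_b, n_permutations = 5000,
                             seed = 1L) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 subjects")
  }
  pooled <- c(group_a, group_b)
  na <- length(group_a)
  nb <- length(group_b)
  obs <- abs(mean(group_a) - mean(group_b))
  total <- choose(na + nb, na)
  sum_all <- sum(pooled)
  stat_for <- function(idx_a) {
    ma <- sum(pooled[idx_a]) / na
    mb <- (sum_all - sum(pooled[idx_a])) / nb
    abs(ma - mb)
  }
  if (total <= n_permutations) {
    combos <- utils::combn(na + nb, na)
    null_stats <- apply(combos, 2, stat_for)
    p <- mean(null_stats >= obs - 1e-12)
    scheme <- "exact_enumeration"
    n_used <- as.integer(total)
  } else {
    null_stats <- with_seed(seed, {
      vapply(seq_len(n_permutations),
             function(k) stat_for(sample.int(na + nb, na)), numeric(1))
    })
    p <- (sum(null_stats >= obs - 1e-12) + 1) / (n_permutations + 1)
    scheme <- "monte_carlo"
    n_used <- as.integer(n_permutations)
  }
  structure(list(statistic = obs, p_value = p, scheme = scheme,
                 n_permutations = n_used, n_a = na, n_b = nb,
                 seed = as.integer(seed)),
            class = "cvue_permtest")
}

#' @export
print.cvue_permtest <- function(x, ...) {
  cat(sprintf("Permutation test (%s, %d relabelings)\n",
              x$scheme, x$n_permutations))
  cat(sprintf("  |mean difference| = %.4g, p = %.5g (n = %d vs %d)\n",
              x$statistic, x$p_value, x$n_a, x$n_b))
  invisible(x)
}

#' Spearman correlation with permutation p-value
#'
#' Spearman's rho (average ranks, then product-moment correlation) with a
#' two-sided permutation p-value: all pairings are enumerated when the
#' number of distinct permutations is within the budget (n <= 7 at the
#' default), otherwise Monte-Carlo with the add-one correction.
#'
#' @param x,y paired numeric vectors, at least 3 pairs.
#' @param n_permutations permutation budget (default 10000).
#' @param seed integer seed.
#' @return list with `rho`, `p_value`, `scheme`, `n`.
#' @examples
#' spearman_perm(1:4, c(2, 2, 3, 1), seed = 1)
#' @export
spearman_perm <- function(x, y, n_permutations = 10000, seed = 1L) {
  n <- length(x)
  if (n != length(y)) stop("x and y must be paired (equal length)")
  if (n < 3L) stop("need at least 3 pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    stop("undefined correlation: constant input")
  }
  rho <- cor(x, y, method = "spearman")
  rx <- rank(x); ry <- rank(y)
  rho_of <- function(perm) cor(rx, ry[perm], method = "pearson")
  if (factorial(n) <= n_permutations) {
    perms <- all_permutations(n)
    null_rho <- vapply(perms, rho_of, numeric(1))
    p <- mean(abs(null_rho) >= abs(rho) - 1e-12)
    scheme <- "exact_enumeration"
  } else {
    null_rho <- with_seed(seed, {
      vapply(seq_len(n_permutations), function(k) rho_of(sample.int(n)),
             numeric(1))
    })
    p <- (sum(abs(null_rho) >= abs(rho) - 1e-12) + 1) / (n_permutations + 1)
    scheme <- "monte_carlo"
  }
  list(rho = rho, p_value = p, scheme = scheme, n = n)
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) {
    for (pos in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

#' Binary pain call from a beta-band FC5 resting CVUE trace
#'
#' The decision rule: pain is called present when the mean per-epoch
#' beta-band CVUE at electrode FC5, at rest, strictly exceeds the decision
#' threshold (default 10%). Reported group values place no-pain subjects
#' below 10% and pain conditions up to about 20% and above; the threshold
#' is the 10% separation, with the larger values serving as effect-size
#' context.
#'
#' @param trace a `cvue_fit` (its beta/FC5 trace is used), or a numeric
#'   vector of per-epoch CVUE percentages together with explicit `band`,
#'   `channel` and `condition` arguments.
#' @param threshold_pct decision threshold in percent (default 10).
#' @param band,channel,condition provenance of a numeric trace; the rule is
#'   defined only for `beta`/`FC5`/`rest` and other inputs are an error.
#' @return an object of class `pain_call`: list with `present`,
#'   `evidence_pct` (mean CVUE), `threshold_pct`.
#' @examples
#' classify_pain(c(22, 24, 23), band = "beta", channel = "FC5",
#'               condition = "rest")
#' @export
classify_pain <- function(trace, threshold_pct = 10, band = "beta",
                          channel = "FC5", condition = "rest") {
  threshold_pct <- assert_number(threshold_pct, "threshold_pct", lower = 0)
  if (inherits(trace, "cvue_fit")) {
    condition <- trace$condition
    sub <- trace$trace[trace$trace$band == "beta" &
                         trace$trace$channel == "FC5", ]
    if (nrow(sub) == 0L) {
      stop("fit contains no beta/FC5 trace; the pain rule is defined for beta at FC5")
    }
    values <- sub$cvue_pct
  } else {
    values <- as.numeric(trace)
  }
  if (length(values) == 0L) stop("empty trace")
  if (!identical(band, "beta") || !identical(channel, "FC5") ||
      !identical(condition, "rest")) {
    stop(sprintf(
      "pain rule is defined only for band=beta, channel=FC5, condition=rest (got %s/%s/%s)",
      band, channel, condition))
  }
  evidence <- mean(values)
  structure(list(present = evidence > threshold_pct,
                 evidence_pct = evidence,
                 threshold_pct = threshold_pct),
            class = "pain_call")
}

#' @export
print.pain_call <- function(x, ...) {
  cat(sprintf("Pain %s: mean resting CVUE_beta(FC5) = %.2f%% (threshold %g%%)\n",
              if (x$present) "PRESENT" else "absent",
              x$evidence_pct, x$threshold_pct))
  invisible(x)
}

#' Shapiro-Wilk normality screen
#'
#' Optional report line for group values; the permutation test is used for
#' inference regardless of the outcome.
#'
#' @param values numeric vector.
#' @return the `htest` object from [stats::shapiro.test()].
#' @export
normality_screen <- function(values) stats::shapiro.test(values)
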