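#' Visuo-motor task performance index
#'
#' Ratio of the number of task cycles performed to the total time allocated
#' for the task, in seconds (default 240 s, i.e. 4 min). One cycle per
#' second -- the maximal achievable rate -- gives a perfect index of 1.
#'
#' @param n_cycles number of completed cycles (>= 0).
#' @param duration_s allocated task time in seconds (default 240).
#' @return the performance index (cycles per second of allocated time).
#' @examples
#' task_performance_index(240)        # perfect performance: 1
#' task_performance_index(120, 240)   # 0.5
#' @export
task_performance_index <- function(n_cycles, duration_s = 240) {
  n_cycles <- assert_number(n_cycles, "n_cycles", lower = 0)
  duration_s <- assert_number(duration_s, "duration_s", lower = 1e-9)
  n_cycles / duration_s
}

#' Detect the capsaicin pain plateau in an NRS series
#'
#' The pain plateau is reached at the moment the participant gives the same
#' numerical rating scale (NRS, 0-10) intensity three times consecutively;
#' ratings are collected every 2 minutes after application. Returns the
#' time of the third reading of the first such run, and the plateau score;
#' `NULL` when no run of three equal readings exists.
#'
#' @param times_min reading times in minutes, strictly increasing.
#' @param scores integer NRS scores in `[0, 10]`.
#' @return list with `plateau_time_min` and `plateau_score`, or `NULL`.
#' @examples
#' detect_plateau(c(2, 4, 6, 8, 10), c(2, 3, 4, 4, 4))  # time 10, score 4
#' @export
detect_plateau <- function(times_min, scores) {
  if (length(scores) == 0L) stop("empty series")
  if (length(times_min) != length(scores)) {
    stop("times and scores must have equal length")
  }
  if (any(diff(times_min) <= 0)) stop("times must be strictly increasing")
  if (any(scores < 0 | scores > 10)) stop("NRS scores must lie in [0, 10]")
  if (length(scores) < 3L) return(NULL)
  for (i in 3:length(scores)) {
    if (scores[i] == scores[i - 1] && scores[i] == scores[i - 2]) {
      return(list(plateau_time_min = times_min[i], plateau_score = scores[i]))
    }
  }
  NULL
}

#' Size-weighted pooled mean of subgroup means
#'
#' Pools subgroup summary means into a cohort mean weighted by subgroup
#' size: `sum(mean_i * n_i) / sum(n_i)`.
#'
#' @param means numeric vector of subgroup means.
#' @param n integer vector of subgroup sizes (>= 1).
#' @return the pooled mean.
#' @examples
#' pooled_group_mean(c(3.83, 5), c(6, 1))  # about 4
#' @export
pooled_group_mean <- function(means, n) {
  if (length(means) == 0L) stop("empty list of subgroups")
  if (length(means) != length(n)) stop("means and n must have equal length")
  if (any(n < 1)) stop("all subgroup sizes must be >= 1")
  sum(means * n) / sum(n)
}
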