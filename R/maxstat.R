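#' Log-rank scores for right-censored survival data
#'
#' Assigns each subject its log-rank (Savage-type) score
#' `a_i = delta_i - Lambda_hat(t_i)`, where `Lambda_hat` is the Nelson-Aalen
#' cumulative-hazard estimate at the subject's observed time. The two-sample
#' log-rank statistic for any dichotomisation of a marker is then a linear
#' rank statistic in these scores, which is what makes maximal selection
#' over all candidate cut-points cheap.
#'
#' @param time Observed times (months).
#' @param event Event indicator (1 = disease-specific death, 0 = censored).
#' @return Numeric vector of scores, one per subject.
#' @export
logrank_scores <- function(time, event) {
  stopifnot(length(time) == length(event))
  if (any(!is.finite(time)) || any(time < 0)) {
    stop("times must be finite and >= 0", call. = FALSE)
  }
  if (!all(event %in% c(0, 1))) stop("event must be 0/1", call. = FALSE)
  n <- length(time)
  ut <- sort(unique(time[event == 1]))
  # Nelson-Aalen increments d_j / n_j at each distinct event time
  d <- vapply(ut, function(t) sum(time == t & event == 1), 0)
  r <- vapply(ut, function(t) sum(time >= t), 0)
  inc <- d / r
  cumhaz_at <- function(t) {
    k <- findInterval(t, ut)
    c(0, cumsum(inc))[k + 1L]
  }
  event - cumhaz_at(time)
}

# standardized linear rank statistic for the split {x <= cut} vs {x > cut}:
# (S - E) / sqrt(V) with the permutation mean/variance of the score sum
std_linear_rank <- function(in_group, scores) {
  n <- length(scores)
  m <- sum(in_group)
  if (m == 0L || m == n) return(NA_real_)
  abar <- mean(scores)
  s2 <- sum((scores - abar)^2)
  v <- m * (n - m) / (n * (n - 1)) * s2
  if (v <= 0) return(NA_real_)
  (sum(scores[in_group]) - m * abar) / sqrt(v)
}

#' Optimal survival cut-point by the maximally selected rank statistic
#'
#' Scans every candidate dichotomisation of a continuous marker (midpoints
#' between consecutive distinct values whose left-group proportion lies in
#' `[minprop, 1 - minprop]`), computes the standardized two-group log-rank
#' statistic for each split, and returns the cut-point maximising its
#' absolute value. Because the maximum is selected over many correlated
#' candidate tests, the p-value must account for multiplicity: the default
#' is a permutation test that recomputes the maximal statistic under random
#' reassignment of the marker values.
#'
#' @param values Numeric marker (e.g. largest single myxoid stroma area in a
#'   margin, mm^2).
#' @param time,event Survival outcome as in [logrank_scores()].
#' @param minprop Minimum proportion of subjects on each side of any
#'   candidate cut-point (default 0.1).
#' @param p_method `"permutation"` (default) or `"none"`.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Seed for the permutation draw.
#' @return A `maxstat_result` list: `best_cutpoint`, `statistic`
#'   (standardized, at the optimum), `p_value`, `candidates`,
#'   `statistics` (per candidate), `minprop`.
#' @export
maxstat_cutpoint <- function(values, time, event, minprop = 0.1,
                             p_method = c("permutation", "none"),
                             n_perm = 10000L, seed = 1L) {
  p_method <- match.arg(p_method)
  stopifnot(length(values) == length(time))
  if (!is.numeric(values) || any(!is.finite(values))) {
    stop("marker values must be finite numeric", call. = FALSE)
  }
  if (minprop <= 0 || minprop >= 0.5) stop("minprop must lie in (0, 0.5)", call. = FALSE)
  if (sum(event) < 1) stop("need at least one event", call. = FALSE)
  n <- length(values)
  ux <- sort(unique(values))
  if (length(ux) < 2L) stop("marker is constant; no candidate cut-points", call. = FALSE)
  scores <- logrank_scores(time, event)

  ord <- order(values)
  xs <- values[ord]
  cs <- cumsum(scores[ord])
  # candidate cuts at midpoints between consecutive distinct values, with the
  # left group holding a proportion within [minprop, 1 - minprop]
  mids <- (ux[-length(ux)] + ux[-1L]) / 2
  n_left <- vapply(mids, function(c) sum(xs <= c), 0)  # == positions of distinct steps
  keep <- n_left / n >= minprop & n_left / n <= 1 - minprop
  if (!any(keep)) stop("no candidate cut-points within the minprop range", call. = FALSE)
  mids <- mids[keep]
  n_left <- n_left[keep]

  abar <- mean(scores)
  s2 <- sum((scores - abar)^2)
  v <- n_left * (n - n_left) / (n * (n - 1)) * s2
  stats <- (cs[n_left] - n_left * abar) / sqrt(v)
  obs <- max(abs(stats))
  best <- which.max(abs(stats))

  p <- NA_real_
  if (p_method == "permutation") {
    p <- with_seed(seed, {
      hits <- 0L
      for (b in seq_len(n_perm)) {
        cp <- cumsum(sample(scores))
        mx <- max(abs((cp[n_left] - n_left * abar) / sqrt(v)))
        if (mx >= obs) hits <- hits + 1L
      }
      (hits + 1L) / (n_perm + 1L)
    })
  }
  structure(list(best_cutpoint = mids[best],
                 statistic = obs,
                 p_value = p,
                 candidates = mids,
                 statistics = stats,
                 minprop = minprop,
                 n = n),
            class = "maxstat_result")
}
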