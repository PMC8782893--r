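#' Select one subject per nuclear family
#'
#' Applies the cohort-construction rule: within each family, if any member
#' reported more than zero symptoms (either dimension, either timepoint),
#' selection is restricted to those members; within the deciding subset the
#' member with the smallest motion averaged over the two scans is chosen.
#' Ties on motion are broken by the lexicographically smallest subject id
#' and logged via a message.
#'
#' @param cohort cohort table with `family_id`, symptom and motion columns.
#' @return the selected rows, one per family, in family order; attribute
#'   `"n_removed"` carries the number of dropped subjects.
#' @export
select_family_member <- function(cohort) {
  if (anyNA(cohort$motion_t1) || anyNA(cohort$motion_t2))
    stopf("motion must be present for both scans of every candidate")
  total <- cohort$inatt_t1 + cohort$inatt_t2 + cohort$hyper_t1 + cohort$hyper_t2
  avg_motion <- (cohort$motion_t1 + cohort$motion_t2) / 2
  picks <- vapply(split(seq_len(nrow(cohort)), cohort$family_id), function(rows) {
    symptomatic <- rows[total[rows] > 0]
    pool <- if (length(symptomatic)) symptomatic else rows
    best <- pool[avg_motion[pool] == min(avg_motion[pool])]
    if (length(best) > 1L) {
      best <- best[order(cohort$subject_id[best])]
      message(sprintf("motion tie in family %s resolved by subject id (%s chosen)",
                      cohort$family_id[best[1]], cohort$subject_id[best[1]]))
    }
    best[1]
  }, integer(1))
  out <- cohort[sort(picks), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- nrow(cohort) - nrow(out)
  out
}

#' DSM-5 symptom-count diagnosis
#'
#' A subject meets the symptom-count criterion when reporting six or more
#' symptoms of inattention, six or more of hyperactivity/impulsivity, or
#' both. (Clinical impairment is not operationalizable from counts and is
#' not modeled.)
#'
#' @param inatt,hyper integer symptom counts in 0-9 (vectorized).
#' @return logical vector.
#' @export
dsm5_diagnosis <- function(inatt, hyper) {
  for (v in list(inatt, hyper))
    if (any(!is.finite(v)) || any(v < 0) || any(v > 9) || any(v != round(v)))
      stopf("symptom counts must be integers in [0, 9]")
  inatt >= 6 | hyper >= 6
}

#' Wilcoxon signed-rank test for within-subject symptom change
#'
#' Paired signed-rank test on `t1 - t2`. Zero differences are discarded
#' (signed-rank convention); tied absolute differences share average ranks.
#' The p-value is exact (computed by convolution of the rank-sum
#' distribution over all sign assignments) for up to 25 nonzero differences,
#' and uses the normal approximation with continuity and tie corrections
#' otherwise. Two-sided.
#'
#' @param t1,t2 paired count vectors (length >= 5).
#' @return object of class `signed_rank_test`: `statistic` (V, the sum of
#'   ranks of positive differences), `p`, `n_effective`, `method`. When all
#'   differences are zero, `statistic = 0`, `p = 1`, `n_effective = 0`.
#' @export
wilcoxon_change <- function(t1, t2) {
  if (length(t1) != length(t2)) stopf("paired vectors must have equal length")
  if (length(t1) < 5L) stopf("need at least 5 pairs")
  d <- t1 - t2
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(structure(list(statistic = 0, p = 1, n_effective = 0L,
                          method = "degenerate"), class = "signed_rank_test"))
  r <- rank(abs(d), ties.method = "average")
  V <- sum(r[d > 0])
  if (n <= 25L) {
    # exact: distribution of V via convolution over doubled (integer) ranks
    w <- as.integer(round(2 * r))
    f <- c(1, rep(0, sum(w)))
    for (wi in w) {
      g <- f
      g[(wi + 1):length(f)] <- g[(wi + 1):length(f)] + f[1:(length(f) - wi)]
      f <- g
    }
    probs <- f / 2^n
    v2 <- round(2 * V)
    p_le <- sum(probs[seq_len(v2 + 1)])
    p_ge <- sum(probs[(v2 + 1):length(probs)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (V - mu - 0.5 * sign(V - mu)) / sqrt(sig2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal"
  }
  structure(list(statistic = V, p = p, n_effective = n, method = method),
            class = "signed_rank_test")
}

#' @export
print.signed_rank_test <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank: V = %g, p = %.4g (n nonzero = %d, %s)\n",
              x$statistic, x$p, x$n_effective, x$method))
  invisible(x)
}

#' Exclude subjects with zero symptoms at both timepoints
#'
#' @param cohort cohort table.
#' @param dimension `"inattention"` or `"hyperactivity"`.
#' @return retained rows; attribute `"n_removed"` gives the removed count.
#' @export
exclude_zero_subjects <- function(cohort, dimension = c("inattention", "hyperactivity")) {
  dimension <- match.arg(dimension)
  cols <- switch(dimension, inattention = c("inatt_t1", "inatt_t2"),
                 hyperactivity = c("hyper_t1", "hyper_t2"))
  drop <- cohort[[cols[1]]] == 0 & cohort[[cols[2]]] == 0
  out <- cohort[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(drop)
  out
}

#' Trim subjects with extreme interscan intervals
#'
#' Removes the `floor(frac * n)` subjects with the shortest intervals and
#' the same number with the longest (ties broken by subject id), the
#' standard sensitivity analysis for heterogeneous between-scan durations.
#' With `frac = 0.15`, a 167-subject cohort with distinct intervals retains
#' 117 subjects.
#'
#' @param cohort cohort table with `interval` (years).
#' @param frac per-tail trimming fraction in `[0, 0.5)`.
#' @return retained rows; attributes `"n_removed"` and `"interval_range"`.
#' @export
trim_interscan <- function(cohort, frac = 0.15) {
  if (!is.numeric(frac) || frac < 0 || frac >= 0.5) stopf("frac must be in [0, 0.5)")
  if (anyNA(cohort$interval)) stopf("intervals must be present")
  n <- nrow(cohort)
  k <- floor(frac * n)
  if (k == 0L) {
    out <- cohort
  } else {
    ord <- order(cohort$interval, cohort$subject_id)
    keep <- sort(ord[(k + 1):(n - k)])
    out <- cohort[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "n_removed") <- n - nrow(out)
  attr(out, "interval_range") <- range(out$interval)
  out
}
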