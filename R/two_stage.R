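#' Estimate the crossing point by a sign-change weighted log-rank scan
#'
#' For each candidate split row \eqn{k} (excluding the first and last
#' risk-table rows, where no sign change is possible), computes the
#' standardized weighted log-rank statistic with weight +1 on rows
#' \eqn{j \le k} and -1 on rows \eqn{j > k}, and returns the split
#' maximizing the absolute standardized statistic.
#'
#' @param table A \code{risk_table} with at least 3 rows before the
#'   truncation index.
#' @return A list with \code{index} (the selected row), \code{time}
#'   (its event time) and \code{statistic} (the maximal absolute
#'   standardized split statistic).
#' @export
estimate_crossing <- function(table) {
  tau <- table$tau_index
  if (tau < 3L)
    stop("crossing estimation needs at least 3 risk-table rows before tau")
  j <- seq_len(tau)
  cum <- cumsum(rt_oe(table)[j])
  V <- sum(rt_hyper_var(table)[j])
  ks <- 2:(tau - 1L)
  z <- if (V > 0) abs(2 * cum[ks] - cum[tau]) / sqrt(V) else rep(0, length(ks))
  best <- which.max(z)
  list(index = ks[best], time = table$event_times[ks[best]],
       statistic = z[best])
}

split_scan_stat <- function(pf, cnt) {
  tau <- cnt$tau
  if (tau < 3L) return(0)
  j <- seq_len(tau)
  oe <- cnt$d1[j] - cnt$n1[j] * pf$d[j] / pf$n[j]
  V <- sum(frame_hyper_var(pf, cnt$n1)[j])
  if (V <= 0) return(0)
  cum <- cumsum(oe)
  ks <- 2:(tau - 1L)
  max(abs(2 * cum[ks] - cum[tau])) / sqrt(V)
}

#' Qiu-Sheng two-stage test for crossing hazards
#'
#' Stage 1 is the ordinary log-rank test at level
#' \eqn{\alpha_1 = 1 - \sqrt{1-\alpha}}.  If stage 1 does not reject,
#' stage 2 runs the maximum-over-splits sign-change statistic of
#' \code{\link{estimate_crossing}}, calibrated by seeded group-label
#' permutation at level \eqn{\alpha_2 = \alpha_1}; the split of the
#' levels makes the overall procedure level \eqn{\alpha} under the
#' asymptotic independence of the two stages.  The overall p-value is
#' \eqn{1 - (1-p_1)(1-p_2)} when both stages run, and \eqn{p_1}
#' otherwise.
#'
#' @param sample1,sample2 \code{surv_sample} objects.
#' @param alpha Overall significance level.
#' @param permutations Stage-2 permutation budget.
#' @param seed Stage-2 permutation seed.
#' @return An object of class \code{two_stage_result}: \code{stage1}
#'   and (possibly \code{NULL}) \code{stage2} test results,
#'   \code{crossing_estimate}, \code{p_overall}, \code{reject} and the
#'   stage levels.
#' @export
ts_test <- function(sample1, sample2, alpha = 0.05,
                    permutations = 2000L, seed = 1L) {
  rt <- build_risk_table(sample1, sample2)
  stage1 <- weighted_logrank(rt)
  a1 <- 1 - sqrt(1 - alpha)
  out <- list(stage1 = stage1, stage2 = NULL, crossing_estimate = NULL,
              alpha1 = a1, alpha2 = a1)
  if (stage1$p_value <= a1 || rt$tau_index < 3L) {
    out$p_overall <- stage1$p_value
    out$reject <- stage1$p_value <= a1
  } else {
    cross <- estimate_crossing(rt)
    res <- perm_pvalue(sample1, sample2, split_scan_stat, permutations, seed)
    out$stage2 <- new_test_result("TS-stage2", res$observed, res$p_value,
                                  sided = "one",
                                  extras = list(permutations = permutations))
    out$crossing_estimate <- cross$time
    out$p_overall <- min(max(1 - (1 - stage1$p_value) * (1 - res$p_value), 0), 1)
    out$reject <- res$p_value <= a1
  }
  structure(out, class = "two_stage_result")
}

#' @export
print.two_stage_result <- function(x, digits = 4L, ...) {
  cat("Two-stage test (log-rank, then sign-change scan)\n")
  cat(sprintf("  stage 1 (log-rank): z = %.*f, p = %.*f (level %.*f)\n",
              digits, x$stage1$statistic, digits, x$stage1$p_value,
              digits, x$alpha1))
  if (is.null(x$stage2)) {
    cat("  stage 2: not run (stage 1 decisive)\n")
  } else {
    cat(sprintf("  stage 2 (max split scan): statistic = %.*f, perm p = %.*f\n",
                digits, x$stage2$statistic, digits, x$stage2$p_value))
    cat(sprintf("  estimated crossing time: %g\n", x$crossing_estimate))
  }
  cat(sprintf("  overall p = %.*f; reject: %s\n", digits, x$p_overall,
              if (x$reject) "yes" else "no"))
  invisible(x)
}
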