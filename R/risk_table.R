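#' Pooled risk table for two right-censored samples
#'
#' Builds the shared substrate of all rank-based two-sample statistics:
#' one row per distinct pooled event time \eqn{t_j}, carrying the pooled
#' and per-group at-risk counts and death counts.  Subjects censored at
#' \eqn{t} are still at risk at \eqn{t} (events precede censorings at
#' tied times).  \code{tau_index} marks the last row at which both
#' groups retain at least one subject at risk; test statistics
#' accumulate only rows up to \code{tau_index}, while the table itself
#' keeps every pooled event time so estimators can show full follow-up.
#'
#' @param sample1,sample2 \code{surv_sample} objects (group 1 and 2).
#' @return An object of class \code{risk_table}: a list with
#'   \code{event_times}, \code{d} (pooled deaths), \code{d1}, \code{n}
#'   (pooled at risk), \code{n1}, \code{n2} and \code{tau_index}.
#' @examples
#' s1 <- surv_sample(c(1, 3), 1, 1)
#' s2 <- surv_sample(c(2, 4), 1, 2)
#' build_risk_table(s1, s2)
#' @export
build_risk_table <- function(sample1, sample2) {
  s1 <- as_surv_sample(sample1, 1L)
  s2 <- as_surv_sample(sample2, 2L)
  times <- c(s1$times, s2$times)
  status <- c(s1$status, s2$status)
  grp1 <- rep(c(TRUE, FALSE), c(s1$size, s2$size))
  if (sum(status) == 0L)
    stop("no-events: neither group contains an observed event")

  et <- sort(unique(times[status == 1L]))
  k <- length(et)
  # at-risk index: subject i contributes to rows 1..r[i]
  r <- findInterval(times, et)
  n  <- rev(cumsum(rev(tabulate(r, nbins = k))))
  n1 <- rev(cumsum(rev(tabulate(r[grp1], nbins = k))))
  n2 <- n - n1
  ev <- status == 1L
  e <- match(times[ev], et)
  d  <- tabulate(e, nbins = k)
  d1 <- tabulate(e[grp1[ev]], nbins = k)

  both <- which(n1 >= 1L & n2 >= 1L)
  tau_index <- if (length(both)) max(both) else 0L
  if (tau_index == 0L)
    stop("no-events: no event time with both groups at risk")

  structure(list(event_times = et, d = d, d1 = d1,
                 n = n, n1 = n1, n2 = n2, tau_index = tau_index,
                 size1 = s1$size, size2 = s2$size),
            class = "risk_table")
}

#' @export
print.risk_table <- function(x, ...) {
  df <- as.data.frame(x)
  cat(sprintf("Pooled risk table: %d event times, tau at t = %g (row %d)\n",
              length(x$event_times), x$event_times[x$tau_index], x$tau_index))
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.risk_table <- function(x, ...) {
  data.frame(time = x$event_times, n = x$n, n1 = x$n1, n2 = x$n2,
             d = x$d, d1 = x$d1)
}

# Per-row hypergeometric variance of d1 given margins; rows with n <= 1
# contribute zero (they lie beyond any two-group comparison).
rt_hyper_var <- function(rt) {
  n <- rt$n; d <- rt$d; n1 <- rt$n1
  v <- ifelse(n > 1, d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1), 0)
  v
}

# Observed-minus-expected group-1 deaths per row.
rt_oe <- function(rt) rt$d1 - rt$n1 * rt$d / rt$n

# Pooled Kaplan-Meier left limit S(t_j-) at each risk-table row.
rt_km_left <- function(rt) {
  s <- cumprod(1 - rt$d / rt$n)
  c(1, s[-length(s)])
}
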