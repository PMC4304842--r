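#' Step-function estimators: Kaplan-Meier, Nelson-Aalen, censoring KM
#'
#' Right-continuous step estimates with pointwise variances.  The
#' Kaplan-Meier estimator is the product-limit estimate of the survival
#' function with Greenwood variance; the Nelson-Aalen estimator is the
#' cumulative-sum estimate of the cumulative hazard with variance
#' \eqn{\sum d_j/n_j^2}; the censoring Kaplan-Meier flips the role of
#' the event indicator (censorings precede events at tied times,
#' mirroring the event-side convention) and estimates the censoring
#' survival function needed by Kaplan-Meier-difference weights.
#'
#' @param sample A \code{surv_sample}.
#' @return An object of class \code{step_estimate}: list with
#'   \code{knots}, \code{values}, \code{variances}, \code{kind} and the
#'   pre-knot baseline value \code{start} (1 for survival kinds, 0 for
#'   cumulative hazard).
#' @examples
#' s <- surv_sample(c(1, 2, 3), c(1, 0, 1))
#' kaplan_meier(s)
#' @export
kaplan_meier <- function(sample) {
  km_core(sample$times, sample$status, kind = "survival")
}

#' @rdname kaplan_meier
#' @export
nelson_aalen <- function(sample) {
  tms <- sample$times; st <- sample$status
  et <- sort(unique(tms[st == 1L]))
  if (!length(et))
    return(new_step(numeric(0), numeric(0), numeric(0), "cumulative_hazard"))
  r <- findInterval(tms, et)
  n <- rev(cumsum(rev(tabulate(r, nbins = length(et)))))
  d <- tabulate(match(tms[st == 1L], et), nbins = length(et))
  new_step(et, cumsum(d / n), cumsum(d / n^2), "cumulative_hazard")
}

#' @rdname kaplan_meier
#' @export
censoring_km <- function(sample) {
  km_core(sample$times, 1L - sample$status, kind = "censoring_survival")
}

km_core <- function(tms, st, kind) {
  et <- sort(unique(tms[st == 1L]))
  if (!length(et)) return(new_step(numeric(0), numeric(0), numeric(0), kind))
  r <- findInterval(tms, et)
  n <- rev(cumsum(rev(tabulate(r, nbins = length(et)))))
  d <- tabulate(match(tms[st == 1L], et), nbins = length(et))
  s <- cumprod(1 - d / n)
  gw <- cumsum(ifelse(n > d, d / (n * (n - d)), 0))
  new_step(et, s, s^2 * gw, kind)
}

new_step <- function(knots, values, variances, kind) {
  structure(list(knots = knots, values = values, variances = variances,
                 kind = kind,
                 start = if (kind == "cumulative_hazard") 0 else 1),
            class = "step_estimate")
}

#' Evaluate a step estimate
#'
#' \code{step_value} returns the right-continuous value at \code{t};
#' \code{step_value_left} the left limit (the value strictly before
#' \code{t}, equal to the baseline before the first knot).
#'
#' @param est A \code{step_estimate}.
#' @param t Numeric vector of evaluation times.
#' @return Numeric vector of estimate values.
#' @export
step_value <- function(est, t) {
  idx <- findInterval(t, est$knots)
  c(est$start, est$values)[idx + 1L]
}

#' @rdname step_value
#' @export
step_value_left <- function(est, t) {
  idx <- findInterval(t, est$knots)
  hit <- idx >= 1L & est$knots[pmax(idx, 1L)] == t
  idx[hit] <- idx[hit] - 1L
  c(est$start, est$values)[idx + 1L]
}

#' @export
print.step_estimate <- function(x, ...) {
  cat(sprintf("Step estimate (%s) with %d knots\n", x$kind, length(x$knots)))
  if (length(x$knots))
    print(utils::head(data.frame(time = x$knots, estimate = x$values,
                                 variance = x$variances), 10L),
          row.names = FALSE)
  invisible(x)
}

#' @export
plot.step_estimate <- function(x, ...,
                               xlab = "time",
                               ylab = if (x$kind == "cumulative_hazard")
                                 "cumulative hazard" else "survival") {
  k <- c(0, x$knots)
  v <- c(x$start, x$values)
  graphics::plot(k, v, type = "s", xlab = xlab, ylab = ylab, ...)
  invisible(x)
}
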