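#' Weight specification for weighted log-rank statistics
#'
#' Named per-row weights on the pooled risk table: \code{"LR"} (log-rank,
#' weight 1), \code{"GW"} (Gehan-Wilcoxon, weight \eqn{n_j}), \code{"TW"}
#' (Tarone-Ware, weight \eqn{\sqrt{n_j}}) and \code{"FH"}
#' (Fleming-Harrington \eqn{G^{\rho\gamma}}, weight
#' \eqn{[\hat S(t_j-)]^\rho [1-\hat S(t_j-)]^\gamma} with \eqn{\hat S}
#' the pooled Kaplan-Meier evaluated as a left limit).
#'
#' @param name One of \code{"LR"}, \code{"GW"}, \code{"TW"}, \code{"FH"}.
#' @param rho,gamma Non-negative Fleming-Harrington exponents (FH only).
#' @return An object of class \code{weight_spec}.
#' @export
weight_spec <- function(name = c("LR", "GW", "TW", "FH"), rho = 0, gamma = 0) {
  name <- match.arg(name)
  if (name == "FH" && (rho < 0 || gamma < 0))
    stop("Fleming-Harrington exponents must be non-negative")
  structure(list(name = name, rho = rho, gamma = gamma),
            class = "weight_spec")
}

# Evaluate a weight spec on every row of a risk table.
wlr_weights <- function(rt, weight) {
  switch(weight$name,
         LR = rep(1, length(rt$n)),
         GW = as.numeric(rt$n),
         TW = sqrt(rt$n),
         FH = {
           sm <- rt_km_left(rt)
           sm^weight$rho * (1 - sm)^weight$gamma
         })
}

#' Weighted log-rank test
#'
#' Computes \eqn{U = \sum_{j \le \tau} W_j (d_{1j} - n_{1j} d_j / n_j)}
#' with hypergeometric variance
#' \eqn{V = \sum_{j \le \tau} W_j^2 d_j \frac{n_{1j}}{n_j}
#' (1-\frac{n_{1j}}{n_j}) \frac{n_j-d_j}{n_j-1}} and reports the signed
#' standardized statistic \eqn{Z = U/\sqrt{V}} with a two-sided normal
#' p-value.  Rows with a single subject at risk contribute zero
#' variance.  Sums stop at the last event time with both groups at risk.
#'
#' @param table A \code{risk_table} (or pass two \code{surv_sample}s to
#'   \code{\link{build_risk_table}} first).
#' @param weight A \code{weight_spec}; default log-rank.
#' @return A \code{crossurv_test} result with the signed z statistic.
#' @examples
#' rt <- build_risk_table(surv_sample(c(1, 3), 1, 1),
#'                        surv_sample(c(2, 4), 1, 2))
#' weighted_logrank(rt)
#' @export
weighted_logrank <- function(table, weight = weight_spec("LR")) {
  w <- wlr_weights(table, weight)
  j <- seq_len(table$tau_index)
  U <- sum(w[j] * rt_oe(table)[j])
  V <- sum(w[j]^2 * rt_hyper_var(table)[j])
  label <- wlr_label(weight)
  if (V <= 0)
    return(degenerate_result(label, extras = list(U = U)))
  z <- U / sqrt(V)
  new_test_result(label, z, 2 * stats::pnorm(-abs(z)), variance = V,
                  extras = list(U = U))
}

wlr_label <- function(weight) {
  if (weight$name == "FH")
    sprintf("FH(%g,%g)", weight$rho, weight$gamma)
  else weight$name
}

#' Covariance between two weighted log-rank numerators
#'
#' \eqn{\mathrm{Cov}(U_a, U_b) = \sum_{j\le\tau} W_{aj} W_{bj} v_j}
#' with \eqn{v_j} the per-row hypergeometric variance term; with
#' \code{weight_a == weight_b} this equals the variance used by
#' \code{\link{weighted_logrank}}.
#'
#' @inheritParams weighted_logrank
#' @param weight_a,weight_b \code{weight_spec} objects.
#' @return The covariance (a scalar).
#' @export
wlr_covariance <- function(table, weight_a, weight_b) {
  j <- seq_len(table$tau_index)
  v <- rt_hyper_var(table)
  sum(wlr_weights(table, weight_a)[j] * wlr_weights(table, weight_b)[j] * v[j])
}

#' Lee's combined versatile tests SHL1-SHL3
#'
#' Combines the standardized Fleming-Harrington statistics
#' \eqn{Z_1 = G^{1,0}} and \eqn{Z_2 = G^{0,1}}: SHL1 is the average
#' \eqn{(Z_1+Z_2)/2} (null variance \eqn{(1+\hat\rho)/2}); SHL2 the
#' average of absolute values; SHL3 the maximum of absolute values.
#' SHL2 and SHL3 p-values come from the bivariate normal with the
#' estimated correlation, evaluated by adaptive quadrature over the
#' conditional-normal decomposition.
#'
#' @inheritParams weighted_logrank
#' @return An object of class \code{shl_result} with components
#'   \code{z1}, \code{z2}, \code{correlation} and the three
#'   \code{crossurv_test} results \code{shl1}, \code{shl2}, \code{shl3}.
#' @export
shl_combined <- function(table) {
  w10 <- weight_spec("FH", 1, 0)
  w01 <- weight_spec("FH", 0, 1)
  t10 <- weighted_logrank(table, w10)
  t01 <- weighted_logrank(table, w01)
  if (is_degenerate(t10) || is_degenerate(t01)) {
    deg <- degenerate_result("SHL")
    return(structure(list(z1 = 0, z2 = 0, correlation = 1,
                          shl1 = deg, shl2 = deg, shl3 = deg),
                     class = "shl_result"))
  }
  z1 <- t10$statistic
  z2 <- t01$statistic
  rho <- wlr_covariance(table, w10, w01) / sqrt(t10$variance * t01$variance)
  rho <- min(max(rho, -1), 1)

  s1 <- (z1 + z2) / 2
  p1 <- 2 * stats::pnorm(-abs(s1) / sqrt((1 + rho) / 2))
  s2 <- (abs(z1) + abs(z2)) / 2
  p2 <- bvn_absmean_sf(s2, rho)
  s3 <- max(abs(z1), abs(z2))
  p3 <- bvn_absmax_sf(s3, rho)

  structure(list(z1 = z1, z2 = z2, correlation = rho,
                 shl1 = new_test_result("SHL1", s1, p1,
                                        extras = list(correlation = rho)),
                 shl2 = new_test_result("SHL2", s2, p2,
                                        extras = list(correlation = rho)),
                 shl3 = new_test_result("SHL3", s3, p3,
                                        extras = list(correlation = rho))),
            class = "shl_result")
}

#' @export
print.shl_result <- function(x, digits = 4L, ...) {
  cat(sprintf("Combined Fleming-Harrington tests (corr = %.*f)\n",
              digits, x$correlation))
  cat(sprintf("  Z1 = G^{1,0} = %.*f, Z2 = G^{0,1} = %.*f\n",
              digits, x$z1, digits, x$z2))
  for (nm in c("shl1", "shl2", "shl3"))
    cat(sprintf("  %s: statistic = %.*f, p = %.*f\n", x[[nm]]$method,
                digits, x[[nm]]$statistic, digits, x[[nm]]$p_value))
  invisible(x)
}

# P((|Z1| + |Z2|)/2 >= c) for standard bivariate normal, corr rho.
bvn_absmean_sf <- function(c0, rho) {
  if (c0 <= 0) return(1)
  if (rho >= 1 - 1e-10) return(2 * stats::pnorm(-c0))
  s <- sqrt(1 - rho^2)
  cdf <- stats::integrate(function(z) {
    hi <- 2 * c0 - abs(z)
    stats::dnorm(z) *
      (stats::pnorm((hi - rho * z) / s) - stats::pnorm((-hi - rho * z) / s))
  }, -2 * c0, 2 * c0, rel.tol = 1e-9, abs.tol = 1e-12)$value
  min(max(1 - cdf, 0), 1)
}

# P(max(|Z1|, |Z2|) >= c) for standard bivariate normal, corr rho.
bvn_absmax_sf <- function(c0, rho) {
  if (c0 <= 0) return(1)
  if (abs(rho) >= 1 - 1e-10) return(2 * stats::pnorm(-c0))
  s <- sqrt(1 - rho^2)
  cdf <- stats::integrate(function(z) {
    stats::dnorm(z) *
      (stats::pnorm((c0 - rho * z) / s) - stats::pnorm((-c0 - rho * z) / s))
  }, -c0, c0, rel.tol = 1e-9, abs.tol = 1e-12)$value
  min(max(1 - cdf, 0), 1)
}
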