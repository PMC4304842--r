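#' Pepe-Fleming weighted Kaplan-Meier test
#'
#' Tests the integrated weighted difference of the two Kaplan-Meier
#' curves, \eqn{\sqrt{n_1 n_2/n}\int_0^\tau \hat w(t)[\hat S_1(t) -
#' \hat S_2(t)]\,dt}, with the censoring-stabilising weight
#' \eqn{\hat w(t) = n\,\hat C_1(t-)\hat C_2(t-) / [n_1\hat C_1(t-) +
#' n_2 \hat C_2(t-)]} built from the per-group censoring Kaplan-Meier
#' estimates.  The null variance is the plug-in estimator
#' \eqn{\sum_{j\le\tau} A_j^2\, d_j/(n_{1j} n_{2j}) \cdot
#' (n_j-d_j)/(n_j-1)} with \eqn{A_j = \int_{t_j}^{\tau} \hat w \hat S_p\,du}
#' the forward integral of the weighted pooled survival curve.
#'
#' @param sample1,sample2 \code{surv_sample} objects.
#' @return A \code{crossurv_test} with the signed standardized statistic
#'   (group 1 minus group 2) and two-sided normal p-value.
#' @export
wkm_test <- function(sample1, sample2) {
  g <- wkm_geometry(sample1, sample2)
  A <- sum(g$widths * g$w * (g$S1 - g$S2))
  Aj <- wkm_forward_integrals(g, g$w)
  V <- sum(Aj^2 * g$var_core)
  if (V <= 0) return(degenerate_result("WKM"))
  z <- A / sqrt(V)
  new_test_result("WKM", z, 2 * stats::pnorm(-abs(z)), variance = V,
                  extras = list(integral = A, tau = g$tau_time))
}

# Shared step-function geometry on [0, tau] for the KM-difference tests:
# a grid at which every step function involved is constant on each
# segment, with values taken at the left endpoints (right-continuous,
# i.e. the left limit on the open segment).
wkm_geometry <- function(sample1, sample2) {
  rt <- build_risk_table(sample1, sample2)
  tau_time <- rt$event_times[rt$tau_index]
  tt <- sort(unique(c(sample1$times, sample2$times)))
  starts <- unique(c(0, tt[tt < tau_time]))
  ends <- c(starts[-1], tau_time)
  km1 <- km_core(sample1$times, sample1$status, "survival")
  km2 <- km_core(sample2$times, sample2$status, "survival")
  kmp <- km_core(c(sample1$times, sample2$times),
                 c(sample1$status, sample2$status), "survival")
  c1 <- censoring_km(sample1)
  c2 <- censoring_km(sample2)
  n1 <- sample1$size; n2 <- sample2$size; n <- n1 + n2
  C1 <- step_value(c1, starts)
  C2 <- step_value(c2, starts)
  den <- n1 * C1 + n2 * C2
  w <- ifelse(den > 0, n * C1 * C2 / den, 0)
  j <- seq_len(rt$tau_index)
  var_core <- (rt$d[j] / (rt$n1[j] * rt$n2[j])) *
    ifelse(rt$n[j] > 1, (rt$n[j] - rt$d[j]) / (rt$n[j] - 1), 0)
  list(rt = rt, tau_time = tau_time, starts = starts, widths = ends - starts,
       S1 = step_value(km1, starts), S2 = step_value(km2, starts),
       Sp = step_value(kmp, starts), Sp_left = step_value_left(kmp, starts),
       w = w, var_core = var_core, event_rows = j,
       event_grid_index = match(rt$event_times[j], c(starts, tau_time)))
}

# A_j = integral from t_j to tau of weight * pooled KM, for each
# risk-table row j <= tau.
wkm_forward_integrals <- function(g, weight_values) {
  seg <- g$widths * weight_values * g$Sp
  rc <- rev(cumsum(rev(c(seg, 0))))
  rc[g$event_grid_index]
}

#' Configuration for the maximum weighted Kaplan-Meier test
#'
#' @param rho_grid,gamma_grid Integer exponent grids for the
#'   Fleming-Harrington-type survival weights; the default 0:2 crossed
#'   grid yields the standard nine component statistics.
#' @param mc_draws Monte Carlo draws for the multivariate-normal maximum
#'   p-value (at least 10000).
#' @param seed Seed for those draws.
#' @return A list of class \code{mkm_config}.
#' @export
mkm_config <- function(rho_grid = 0:2, gamma_grid = 0:2,
                       mc_draws = 100000L, seed = 1L) {
  if (!length(rho_grid) || !length(gamma_grid))
    stop("exponent grids must be non-empty")
  if (mc_draws < 10000L) stop("mc_draws must be at least 10000")
  structure(list(rho_grid = rho_grid, gamma_grid = gamma_grid,
                 mc_draws = as.integer(mc_draws), seed = seed),
            class = "mkm_config")
}

#' Shen-Cai maximum weighted Kaplan-Meier test
#'
#' Forms one weighted Kaplan-Meier statistic per
#' \eqn{(\rho, \gamma)} pair, with weights
#' \eqn{\hat w(t) [\hat S_p(t-)]^\rho [1 - \hat S_p(t-)]^\gamma}, takes
#' the maximum of the absolute standardized components, and computes the
#' p-value as \eqn{P(\max_k |Z_k| \ge} observed\eqn{)} under the
#' multivariate normal with the plug-in correlation matrix, by seeded
#' Monte Carlo.
#'
#' @inheritParams wkm_test
#' @param config An \code{\link{mkm_config}}.
#' @return A \code{crossurv_test}; \code{extras$components} holds the
#'   standardized component statistics.
#' @export
mkm_test <- function(sample1, sample2, config = mkm_config()) {
  g <- wkm_geometry(sample1, sample2)
  grid <- expand.grid(rho = config$rho_grid, gamma = config$gamma_grid)
  m <- nrow(grid)
  V <- numeric(m)
  Amat <- matrix(0, length(g$event_rows), m)
  for (k in seq_len(m)) {
    wk <- g$w * g$Sp_left^grid$rho[k] * (1 - g$Sp_left)^grid$gamma[k]
    V[k] <- sum(g$widths * wk * (g$S1 - g$S2))
    Amat[, k] <- wkm_forward_integrals(g, wk)
  }
  C <- crossprod(Amat * sqrt(g$var_core))
  sds <- sqrt(diag(C))
  ok <- sds > 0
  if (!any(ok)) return(degenerate_result("MKM"))
  z <- V[ok] / sds[ok]
  R <- stats::cov2cor(C[ok, ok, drop = FALSE])
  R <- nearest_correlation(R)
  obs <- max(abs(z))
  p <- with_seed(config$seed, {
    L <- chol(R)
    draws <- matrix(stats::rnorm(config$mc_draws * nrow(R)),
                    config$mc_draws) %*% L
    mean(apply(abs(draws), 1L, max) >= obs)
  })
  new_test_result("MKM", obs, p,
                  extras = list(components = z, correlation = R,
                                grid = grid[ok, , drop = FALSE]))
}

# Clip negative eigenvalues and rescale back to a correlation matrix.
nearest_correlation <- function(R, tol = 1e-8) {
  ch <- tryCatch(chol(R), error = function(e) NULL)
  if (!is.null(ch)) return(R)
  eg <- eigen(R, symmetric = TRUE)
  vals <- pmax(eg$values, tol)
  R2 <- eg$vectors %*% (vals * t(eg$vectors))
  stats::cov2cor(R2)
}

#' Configuration for the Lin-Xu area test
#'
#' @param rho_cross Constant correlation assumed between the per-interval
#'   area contributions when accumulating the variance of each area
#'   under the Kaplan-Meier curve; in \eqn{[0,1]}, default 0.5.
#' @param sided \code{"one"} (LX1) or \code{"two"} (LX2).
#' @param upper_limit Integration endpoint; \code{NULL} uses the shared
#'   truncation time \eqn{t_\tau}.
#' @return A list of class \code{lx_config}.
#' @export
lx_config <- function(rho_cross = 0.5, sided = c("one", "two"),
                      upper_limit = NULL) {
  if (rho_cross < 0 || rho_cross > 1) stop("rho_cross must lie in [0, 1]")
  structure(list(rho_cross = rho_cross, sided = match.arg(sided),
                 upper_limit = upper_limit),
            class = "lx_config")
}

#' Lin-Xu area-between-survival-curves test
#'
#' Compares the areas under the two Kaplan-Meier curves up to the
#' truncation time: \eqn{D = |A_1 - A_2|} with
#' \eqn{A_i = \int_0^\tau \hat S_i(t)\,dt}.  The variance of each area
#' accumulates Greenwood-based per-interval terms with a constant
#' pairwise correlation \code{rho_cross} between interval
#' contributions; \eqn{Z = D/\sqrt{\widehat{Var} A_1 + \widehat{Var} A_2}}
#' is referred to the standard normal, one-sided (LX1) or two-sided
#' (LX2).
#'
#' @inheritParams wkm_test
#' @param config An \code{\link{lx_config}}.
#' @return A \code{crossurv_test}.
#' @export
lx_test <- function(sample1, sample2, config = lx_config()) {
  rt <- build_risk_table(sample1, sample2)
  tau_time <- if (is.null(config$upper_limit))
    rt$event_times[rt$tau_index] else config$upper_limit
  a1 <- lx_area(sample1, tau_time, config$rho_cross)
  a2 <- lx_area(sample2, tau_time, config$rho_cross)
  D <- abs(a1$area - a2$area)
  V <- a1$variance + a2$variance
  label <- if (config$sided == "one") "LX1" else "LX2"
  if (V <= 0)
    return(degenerate_result(label, sided = config$sided))
  z <- D / sqrt(V)
  p <- if (config$sided == "one") stats::pnorm(-z) else 2 * stats::pnorm(-z)
  new_test_result(label, z, p, variance = V, sided = config$sided,
                  extras = list(area1 = a1$area, area2 = a2$area,
                                tau = tau_time))
}

lx_area <- function(sample, tau_time, rho_cross) {
  km <- km_core(sample$times, sample$status, "survival")
  ev <- km$knots[km$knots < tau_time]
  starts <- c(0, ev)
  widths <- c(ev, tau_time) - starts
  svals <- step_value(km, starts)
  svar <- c(0, km$variances[seq_along(ev)])
  sds <- widths * sqrt(svar)
  variance <- rho_cross * sum(sds)^2 + (1 - rho_cross) * sum(sds^2)
  list(area = sum(widths * svals), variance = variance)
}

#' Lin-Wang squared observed-minus-expected test
#'
#' Statistic \eqn{T = \sum_{j\le\tau} (d_{1j} - n_{1j} d_j/n_j)^2},
#' calibrated by seeded group-label permutation (the risk table is
#' re-derived for every permutation).
#'
#' @inheritParams wkm_test
#' @param permutations Number of label permutations.
#' @param seed Permutation seed.
#' @return A \code{crossurv_test}.
#' @export
lw_test <- function(sample1, sample2, permutations = 2000L, seed = 1L) {
  res <- perm_pvalue(sample1, sample2, lw_stat, permutations, seed)
  new_test_result("LW", res$observed, res$p_value, sided = "one",
                  extras = list(permutations = permutations))
}

lw_stat <- function(pf, cnt) {
  j <- seq_len(cnt$tau)
  sum((cnt$d1[j] - cnt$n1[j] * pf$d[j] / pf$n[j])^2)
}
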