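#' Configuration for the adaptive Neyman smooth tests
#'
#' @param d Fixed dimension of the smooth alternative (the fixed-d test
#'   uses the score statistic \eqn{T_d}); default 4.
#' @param d_max Maximum dimension of the nested data-driven test;
#'   default 8 (at most 12).
#' @param d0 Number of forced high-priority basis directions in the
#'   Schwarz selection (the selected dimension is always > \code{d0});
#'   default 0.
#' @param permutations Permutation budget for the p-value; default 2000.
#' @param seed Permutation seed.
#' @param basis Basis family; shifted Legendre polynomials of the
#'   pooled cumulative-hazard time transform.
#' @return A list of class \code{ny_config}.
#' @export
ny_config <- function(d = 4L, d_max = 8L, d0 = 0L,
                      permutations = 2000L, seed = 1L,
                      basis = "legendre") {
  d <- as.integer(d); d_max <- as.integer(d_max); d0 <- as.integer(d0)
  if (d < 1L || d > d_max || d_max > 12L)
    stop("need 1 <= d <= d_max <= 12")
  if (d0 >= d_max) stop("d0 must be smaller than d_max")
  if (permutations < 100L) stop("at least 100 permutations are required")
  structure(list(d = d, d_max = d_max, d0 = d0,
                 permutations = as.integer(permutations), seed = seed,
                 basis = match.arg(basis)),
            class = "ny_config")
}

# Orthonormal shifted Legendre polynomials phi_1..phi_d on [0,1]
# (degree 0 excluded: that direction is the plain log-rank).
legendre_shifted <- function(x, d) {
  y <- 2 * x - 1
  P <- matrix(0, length(x), d + 1L)
  P[, 1L] <- 1
  if (d >= 1L) P[, 2L] <- y
  if (d >= 2L) for (k in 1:(d - 1L))
    P[, k + 2L] <- ((2 * k + 1) * y * P[, k + 1L] - k * P[, k]) / (k + 1)
  Phi <- P[, -1L, drop = FALSE]
  sweep(Phi, 2L, sqrt(2 * seq_len(d) + 1), `*`)
}

#' Smooth-basis matrix on the risk-table time transform
#'
#' Maps each risk-table row to the midpoint of its increment of the
#' normalized pooled Nelson-Aalen estimator,
#' \eqn{x_j = [\hat\Lambda_p(t_{j-1}) + \hat\Lambda_p(t_j)] /
#' [2\hat\Lambda_p(t_\tau)]} (pooled, so the design is invariant under
#' group relabelling), and evaluates the first \code{d} orthonormal
#' shifted Legendre polynomials there.  If fewer rows than
#' \code{d} are available the dimension is truncated with a warning.
#'
#' @param table A \code{risk_table}.
#' @param d Number of basis functions.
#' @return A matrix with one row per risk-table row up to \eqn{\tau} and
#'   one column per basis function.
#' @export
basis_matrix <- function(table, d) {
  tau <- table$tau_index
  if (d > tau) {
    warning("dimension truncated from ", d, " to ", tau,
            " (not enough event times)")
    d <- tau
  }
  j <- seq_len(tau)
  lam <- cumsum(table$d[j] / table$n[j])
  legendre_shifted(transform_midpoints(lam), d)
}

# Design points of the smooth basis: each risk-table row is placed at
# the midpoint of its increment of the normalized pooled cumulative
# hazard.  The symmetric placement keeps the null quadratic form close
# to its chi-square reference; evaluating at the right (or left) limit
# instead inflates (deflates) the score statistic noticeably when late
# rows carry large hazard increments.
transform_midpoints <- function(lam) {
  (c(0, lam[-length(lam)]) + lam) / (2 * lam[length(lam)])
}

#' Partial-likelihood smooth score statistic
#'
#' Score vector \eqn{U_k = \sum_{j\le\tau} \phi_k(x_j)(d_{1j} -
#' n_{1j} d_j/n_j)} and covariance \eqn{\Sigma_{kl} = \sum_j \phi_k
#' \phi_l v_j} with \eqn{v_j} the hypergeometric row variance;
#' \eqn{T_d = U'\Sigma^{-1}U} (Moore-Penrose inverse when
#' \eqn{\Sigma} is rank-deficient, with the rank as effective
#' dimension).
#'
#' @inheritParams basis_matrix
#' @param basis \code{"legendre"} or \code{"constant"} (a single
#'   constant direction; then \eqn{T_1} is the squared standardized
#'   log-rank statistic, used as an internal consistency check).
#' @return A list of class \code{smooth_score} with \code{U},
#'   \code{Sigma}, \code{T_d}, \code{d} and \code{rank}.
#' @export
smooth_score <- function(table, d, basis = c("legendre", "constant")) {
  basis <- match.arg(basis)
  j <- seq_len(table$tau_index)
  Phi <- if (basis == "constant")
    matrix(1, length(j), 1L)
  else basis_matrix(table, d)
  oe <- rt_oe(table)[j]
  v <- rt_hyper_var(table)[j]
  U <- drop(crossprod(Phi, oe))
  Sigma <- crossprod(Phi, Phi * v)
  qf <- quad_form_inv(U, Sigma)
  structure(list(U = U, Sigma = Sigma, T_d = qf$value, d = ncol(Phi),
                 rank = qf$rank),
            class = "smooth_score")
}

quad_form_inv <- function(U, Sigma) {
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (!is.null(ch)) {
    z <- backsolve(ch, U, transpose = TRUE)
    return(list(value = sum(z^2), rank = length(U)))
  }
  eg <- eigen(Sigma, symmetric = TRUE)
  tol <- max(eg$values, 0) * 1e-10
  keep <- eg$values > tol
  if (!any(keep)) return(list(value = 0, rank = 0L))
  w <- drop(crossprod(eg$vectors[, keep, drop = FALSE], U))
  list(value = sum(w^2 / eg$values[keep]), rank = sum(keep))
}

#' Schwarz (BIC-type) dimension selection for the nested smooth test
#'
#' Selects \eqn{S = \arg\max_{d_0 < d \le d_{max}} [T_d - (d - d_0)
#' \log n_{events}]}, ties broken toward the smaller dimension.
#'
#' @param scores Numeric vector of nested score statistics \eqn{T_d},
#'   \eqn{d = 1, \ldots, d_{max}}.
#' @param n_events Pooled event count used as the penalty sample size.
#' @param d0 Number of forced high-priority directions.
#' @return The selected dimension (an integer).
#' @export
select_dimension <- function(scores, n_events, d0 = 0L) {
  d_max <- length(scores)
  if (d0 >= d_max) stop("d0 must be smaller than the number of scores")
  ds <- (d0 + 1L):d_max
  crit <- scores[ds] - (ds - d0) * log(max(n_events, 1))
  ds[which.max(crit)]
}

#' Adaptive Neyman smooth tests with permutation calibration
#'
#' \code{type = "fixed"} is the fixed-dimension score test (statistic
#' \eqn{T_d}, default \eqn{d = 4}); \code{type = "data_driven"} is the
#' nested data-driven test (statistic \eqn{T_S} with the Schwarz-selected
#' dimension \eqn{S \le d_{max}}, default 8, re-selected inside every
#' permutation).  P-values are seeded permutation p-values
#' \eqn{(1 + \#\{T^{perm} \ge T^{obs}\})/(B+1)}.
#'
#' @param sample1,sample2 \code{surv_sample} objects.
#' @param config An \code{\link{ny_config}}.
#' @param type \code{"fixed"} or \code{"data_driven"}.
#' @return A \code{crossurv_test}; for the data-driven test
#'   \code{extras$selected_d} holds the selected dimension.
#' @export
ny_test <- function(sample1, sample2, config = ny_config(),
                    type = c("fixed", "data_driven")) {
  type <- match.arg(type)
  eng <- ny_perm_engine(sample1, sample2, config)
  if (type == "fixed")
    new_test_result("NY1", eng$T_fixed, eng$p_fixed, sided = "one",
                    extras = list(d = config$d,
                                  permutations = config$permutations))
  else
    new_test_result("NY2", eng$T_sel, eng$p_sel, sided = "one",
                    extras = list(selected_d = eng$selected_d,
                                  d_max = config$d_max, d0 = config$d0,
                                  permutations = config$permutations))
}

# Shared permutation engine: one pass over the permutations yields both
# the fixed-d and the data-driven statistics (the nested T_d sequence
# falls out of one Cholesky factorization via cumulative squared
# forward-solved scores).
ny_perm_engine <- function(sample1, sample2, config) {
  pf <- perm_frame(sample1, sample2)
  eval_one <- function(cnt) ny_stats(pf, cnt, config)
  obs <- eval_one(frame_counts(pf, seq_len(pf$n1_size)))
  B <- config$permutations
  perm_fixed <- numeric(B)
  perm_sel <- numeric(B)
  with_seed(config$seed, {
    for (b in seq_len(B)) {
      st <- eval_one(frame_counts(pf, sample.int(pf$n_total, pf$n1_size)))
      perm_fixed[b] <- st$T_fixed
      perm_sel[b] <- st$T_sel
    }
  })
  list(T_fixed = obs$T_fixed, T_sel = obs$T_sel,
       selected_d = obs$selected_d,
       p_fixed = (1 + sum(perm_fixed >= obs$T_fixed - 1e-12)) / (B + 1),
       p_sel = (1 + sum(perm_sel >= obs$T_sel - 1e-12)) / (B + 1))
}

ny_stats <- function(pf, cnt, config) {
  tau <- cnt$tau
  if (tau < 1L) return(list(T_fixed = 0, T_sel = 0, selected_d = config$d0 + 1L))
  j <- seq_len(tau)
  dm <- min(config$d_max, tau)
  lam <- cumsum(pf$d[j] / pf$n[j])
  Phi <- legendre_shifted(transform_midpoints(lam), dm)
  oe <- cnt$d1[j] - cnt$n1[j] * pf$d[j] / pf$n[j]
  v <- frame_hyper_var(pf, cnt$n1)[j]
  U <- drop(crossprod(Phi, oe))
  Sigma <- crossprod(Phi, Phi * v)
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  Tnest <- if (!is.null(ch)) {
    cumsum(backsolve(ch, U, transpose = TRUE)^2)
  } else {
    vapply(seq_len(dm), function(dd)
      quad_form_inv(U[seq_len(dd)],
                    Sigma[seq_len(dd), seq_len(dd), drop = FALSE])$value,
      numeric(1))
  }
  nev <- sum(pf$d[j])
  sel <- select_dimension(Tnest, nev, min(config$d0, dm - 1L))
  list(T_fixed = Tnest[min(config$d, dm)], T_sel = Tnest[sel],
       selected_d = sel)
}
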