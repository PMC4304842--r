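#' Survival-time generating laws
#'
#' Constructors for the three generating laws used by the benchmark
#' scenarios: exponential (hazard \code{rate}), Weibull with
#' \eqn{S(t) = \exp\{-(t/\theta)^\eta\}} (shape \eqn{\eta}, scale
#' \eqn{\theta}), and piecewise exponential with constant hazard
#' \code{rates[i]} between consecutive \code{breakpoints}.
#'
#' @param rate,shape,scale,breakpoints,rates Law parameters; all rates
#'   and scales strictly positive, breakpoints strictly increasing,
#'   with one more rate than breakpoints.
#' @return A classed list describing the law.
#' @export
law_exponential <- function(rate) {
  if (rate <= 0) stop("rate must be positive")
  structure(list(kind = "exponential", rate = rate), class = "surv_law")
}

#' @rdname law_exponential
#' @export
law_weibull <- function(shape, scale) {
  if (shape <= 0 || scale <= 0) stop("shape and scale must be positive")
  structure(list(kind = "weibull", shape = shape, scale = scale),
            class = "surv_law")
}

#' @rdname law_exponential
#' @export
law_piecewise_exponential <- function(breakpoints, rates) {
  breakpoints <- as.numeric(breakpoints)
  if (length(rates) != length(breakpoints) + 1L)
    stop("need exactly one more rate than breakpoints")
  if (any(rates <= 0)) stop("all rates must be positive")
  if (is.unsorted(breakpoints, strictly = TRUE) ||
      (length(breakpoints) && breakpoints[1] <= 0))
    stop("breakpoints must be positive and strictly increasing")
  structure(list(kind = "pwexp", breakpoints = breakpoints, rates = rates),
            class = "surv_law")
}

#' Survival function of a generating law
#'
#' @param law A \code{surv_law}.
#' @param t Evaluation times.
#' @return \eqn{S(t)} as a numeric vector.
#' @export
law_survival <- function(law, t) {
  switch(law$kind,
         exponential = exp(-law$rate * t),
         weibull = exp(-(t / law$scale)^law$shape),
         pwexp = exp(-pwexp_cumhaz(law, t)))
}

pwexp_cumhaz <- function(law, t) {
  bp <- c(0, law$breakpoints)
  H <- c(0, cumsum(law$rates[-length(law$rates)] * diff(bp)))
  idx <- findInterval(t, bp)
  H[idx] + law$rates[idx] * (t - bp[idx])
}

pwexp_quantile_from_cumhaz <- function(law, h) {
  bp <- c(0, law$breakpoints)
  H <- c(0, cumsum(law$rates[-length(law$rates)] * diff(bp)))
  idx <- findInterval(h, H)
  bp[idx] + (h - H[idx]) / law$rates[idx]
}

#' Sample failure times from a generating law
#'
#' Inverse-CDF sampling; reproducible under \code{seed}.
#'
#' @inheritParams law_survival
#' @param n Number of draws.
#' @param seed Optional seed (\code{NULL} uses the current RNG stream).
#' @return Numeric vector of failure times.
#' @export
sample_survival_times <- function(law, n, seed = NULL) {
  if (n < 1L) stop("n must be at least 1")
  with_seed(seed, {
    u <- stats::runif(n)
    switch(law$kind,
           exponential = -log(u) / law$rate,
           weibull = law$scale * (-log(u))^(1 / law$shape),
           pwexp = pwexp_quantile_from_cumhaz(law, -log(u)))
  })
}

#' Uniform censoring specification
#'
#' Censoring times are drawn from \eqn{U(0, a)} in group 1 and
#' \eqn{U(0, b)} in group 2 (\code{kind = "uniform"}), or absent
#' (\code{kind = "none"}).
#'
#' @param kind \code{"none"} or \code{"uniform"}.
#' @param a,b Upper limits of the per-group uniform censoring laws.
#' @param target_rate The censoring rate the limits were calibrated to
#'   (bookkeeping only).
#' @return A list of class \code{censoring_spec}.
#' @export
censoring_spec <- function(kind = c("none", "uniform"), a = NULL, b = NULL,
                           target_rate = 0) {
  kind <- match.arg(kind)
  if (kind == "uniform" && (is.null(a) || is.null(b) || a <= 0 || b <= 0))
    stop("uniform censoring needs positive limits a and b")
  structure(list(kind = kind, a = a, b = b, target_rate = target_rate),
            class = "censoring_spec")
}

#' Calibrate a uniform censoring limit to a target censoring rate
#'
#' Solves \eqn{P(C < X) = } \code{target_rate} for \eqn{C \sim U(0,a)}
#' and \eqn{X} following \code{law}, i.e.
#' \eqn{\frac{1}{a}\int_0^a S_X(t)\,dt = } \code{target_rate}, by
#' bisection to absolute tolerance 1e-6.  For exponential \eqn{X} with
#' rate \eqn{\lambda} the equation is
#' \eqn{(1 - e^{-\lambda a})/(\lambda a)} = \code{target_rate}.
#'
#' @inheritParams law_survival
#' @param target_rate Desired censoring proportion, strictly in (0, 1).
#' @return The calibrated upper limit \eqn{a}.
#' @export
calibrate_censoring <- function(law, target_rate) {
  if (target_rate <= 0 || target_rate >= 1)
    stop("target_rate must be strictly between 0 and 1")
  cens_rate <- function(a)
    stats::integrate(function(t) law_survival(law, t), 0, a,
                     rel.tol = 1e-10)$value / a
  lo <- 1e-8; hi <- 1
  while (cens_rate(hi) > target_rate) {
    hi <- hi * 2
    if (hi > 1e12) stop("target censoring rate unattainable for this law")
  }
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (cens_rate(mid) > target_rate) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Apply random censoring to failure times
#'
#' Each subject gets \eqn{T = \min(X, Cr)} and \eqn{\delta = I[X \le Cr]}
#' with \eqn{Cr \sim U(0, \mathrm{limit})}; with \code{kind = "none"}
#' all subjects are events.
#'
#' @param times Failure times \eqn{X}.
#' @param censoring A \code{censoring_spec}.
#' @param group Group label for the resulting sample (selects limit
#'   \code{a} for group 1, \code{b} for group 2).
#' @param seed Optional seed.
#' @return A \code{surv_sample}.
#' @export
apply_censoring <- function(times, censoring, group = 1L, seed = NULL) {
  if (censoring$kind == "none")
    return(surv_sample(times, 1L, group))
  lim <- if (group == 1L) censoring$a else censoring$b
  with_seed(seed, {
    cr <- stats::runif(length(times), 0, lim)
    surv_sample(pmin(times, cr), as.integer(times <= cr), group)
  })
}

#' Crossing point of two survival curves
#'
#' For two Weibull laws with different shapes the crossing time has the
#' closed form \eqn{t^* = \exp[(\eta_1\log\theta_1 - \eta_2\log\theta_2)
#' /(\eta_1-\eta_2)]}; otherwise the root of \eqn{S_1 - S_2} is found by
#' bisection after a sign-change scan.  Returns \code{NULL} when the
#' curves do not cross (e.g. proportional-type ordering).
#'
#' @param law1,law2 \code{surv_law} objects.
#' @return \code{NULL}, or a list with \code{time} and \code{level}
#'   (the common survival value \eqn{S(t^*)}).
#' @export
crossing_point <- function(law1, law2) {
  as_weib <- function(l) {
    if (l$kind == "weibull") c(l$shape, l$scale)
    else if (l$kind == "exponential") c(1, 1 / l$rate)
    else NULL
  }
  w1 <- as_weib(law1); w2 <- as_weib(law2)
  if (!is.null(w1) && !is.null(w2)) {
    if (isTRUE(all.equal(w1, w2))) stop("curves-identical: the two laws coincide")
    if (abs(w1[1] - w2[1]) < 1e-12) return(NULL)   # equal shapes: no crossing
    t_star <- exp((w1[1] * log(w1[2]) - w2[1] * log(w2[2])) / (w1[1] - w2[1]))
    return(list(time = t_star, level = law_survival(law1, t_star)))
  }
  f <- function(t) law_survival(law1, t) - law_survival(law2, t)
  hi <- 1
  while (law_survival(law1, hi) > 1e-6 || law_survival(law2, hi) > 1e-6) {
    hi <- hi * 2
    if (hi > 1e12) break
  }
  grid <- seq(hi / 512, hi, length.out = 512)
  fx <- f(grid)
  if (max(abs(fx)) < 1e-12) stop("curves-identical: the two laws coincide")
  sc <- which(fx[-1] * fx[-length(fx)] < 0)
  if (!length(sc)) return(NULL)
  root <- stats::uniroot(f, c(grid[sc[1]], grid[sc[1] + 1]), tol = 1e-10)$root
  list(time = root, level = law_survival(law1, root))
}

#' Benchmark scenario presets
#'
#' Returns the generating configuration for one benchmark scenario.
#' Group 1 always follows the exponential law with hazard 0.25;
#' \code{"null"} uses the same law in group 2, \code{"A"} a
#' proportional-hazards alternative (hazard 0.5), and \code{"B"},
#' \code{"C"}, \code{"D"} Weibull alternatives constructed so the two
#' survival curves cross exactly at survival level 0.7 (early crossing,
#' band \eqn{S(t^*) > 0.6}), 0.5 (middle, band 0.4--0.6) and 0.3
#' (late, band 0.2--0.4).  Uniform censoring limits are calibrated
#' separately against each group's law so both arms reach the same
#' target censoring rate.
#'
#' @param label One of \code{"null"}, \code{"A"}, \code{"B"},
#'   \code{"C"}, \code{"D"}.
#' @param n1,n2 Per-group sample sizes.
#' @param censoring_rate Target censoring rate, one of 0, 0.2, 0.4, 0.6
#'   (any rate in [0, 1) is accepted).
#' @return A list of class \code{scenario_config} with \code{law1},
#'   \code{law2}, \code{censoring}, sizes and label.
#' @export
scenario_config <- function(label = c("null", "A", "B", "C", "D"),
                            n1 = 50L, n2 = 50L, censoring_rate = 0) {
  label <- match.arg(label)
  law1 <- law_exponential(0.25)
  law2 <- switch(label,
                 null = law_exponential(0.25),
                 A = law_exponential(0.5),
                 B = weibull_crossing_at(law1, level = 0.7, shape = 0.5),
                 C = weibull_crossing_at(law1, level = 0.5, shape = 2.5),
                 D = weibull_crossing_at(law1, level = 0.3, shape = 2.5))
  cens <- if (censoring_rate <= 0) censoring_spec("none")
  else censoring_spec("uniform",
                      a = calibrate_censoring(law1, censoring_rate),
                      b = calibrate_censoring(law2, censoring_rate),
                      target_rate = censoring_rate)
  structure(list(label = label, law1 = law1, law2 = law2,
                 censoring = cens, n1 = as.integer(n1), n2 = as.integer(n2)),
            class = "scenario_config")
}

# Weibull law with the given shape whose survival curve crosses that of
# the exponential reference exactly at survival level `level`.
weibull_crossing_at <- function(ref, level, shape) {
  t_star <- -log(level) / ref$rate
  law_weibull(shape, t_star / (-log(level))^(1 / shape))
}

#' Draw one two-sample replicate from a scenario
#'
#' @param config A \code{\link{scenario_config}}.
#' @param seed Optional seed for the replicate.
#' @return A list with \code{sample1} and \code{sample2}.
#' @export
simulate_scenario <- function(config, seed = NULL) {
  with_seed(seed, {
    x1 <- sample_survival_times(config$law1, config$n1)
    x2 <- sample_survival_times(config$law2, config$n2)
    list(sample1 = apply_censoring(x1, config$censoring, 1L),
         sample2 = apply_censoring(x2, config$censoring, 2L))
  })
}

#' @export
print.scenario_config <- function(x, ...) {
  fmt_law <- function(l) switch(l$kind,
    exponential = sprintf("Exp(rate %g)", l$rate),
    weibull = sprintf("Weibull(shape %.4g, scale %.4g)", l$shape, l$scale),
    pwexp = sprintf("piecewise Exp(%d pieces)", length(l$rates)))
  cat(sprintf("Scenario %s: n = (%d, %d)\n", x$label, x$n1, x$n2))
  cat("  group 1:", fmt_law(x$law1), "\n  group 2:", fmt_law(x$law2), "\n")
  if (x$censoring$kind == "none") cat("  censoring: none\n")
  else cat(sprintf("  censoring: U(0, %.4g) / U(0, %.4g), target rate %g\n",
                   x$censoring$a, x$censoring$b, x$censoring$target_rate))
  invisible(x)
}
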