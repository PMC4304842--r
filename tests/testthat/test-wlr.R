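test_that("weighted log-rank reproduces the four-subject hand computation", {
  h <- hand_samples()
  rt <- build_risk_table(h$s1, h$s2)
  r <- weighted_logrank(rt)
  expect_equal(r$extras$U, 2 / 3, tolerance = 1e-12)
  expect_equal(r$variance, 13 / 18, tolerance = 1e-12)
  expect_equal(r$statistic, (2 / 3) / sqrt(13 / 18), tolerance = 1e-10)
  expect_equal(r$statistic, 0.7845, tolerance = 1e-4)

  m <- mirrored_samples()
  rm_ <- build_risk_table(m$s1, m$s2)
  r0 <- weighted_logrank(rm_)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
})

test_that("log-rank agrees with survival::survdiff", {
  skip_if_not_installed("survival")
  set.seed(3)
  t1 <- rexp(40); t2 <- rexp(40, 1.7)
  st1 <- rbinom(40, 1, 0.8); st2 <- rbinom(40, 1, 0.8)
  rt <- build_risk_table(surv_sample(t1, st1, 1), surv_sample(t2, st2, 2))
  z <- weighted_logrank(rt)$statistic
  sd2 <- survival::survdiff(
    survival::Surv(c(t1, t2), c(st1, st2)) ~ rep(1:2, each = 40))
  expect_equal(z^2, sd2$chisq, tolerance = 1e-10)
})

test_that("covariance of weighted numerators matches hand sum and variance", {
  h <- hand_samples()
  rt <- build_risk_table(h$s1, h$s2)
  expect_equal(wlr_covariance(rt, weight_spec("LR"), weight_spec("GW")),
               13 / 6, tolerance = 1e-12)
  for (w in list(weight_spec("LR"), weight_spec("GW"), weight_spec("TW"),
                 weight_spec("FH", 1, 1)))
    expect_equal(wlr_covariance(rt, w, w), weighted_logrank(rt, w)$variance)
  # gamma > 0 kills the first row (pooled KM left limit is 1 there)
  w01 <- crossurv:::wlr_weights(rt, weight_spec("FH", 0, 1))
  expect_equal(w01[1], 0)
})

test_that("FH(0,0) is the log-rank test and labels are exchangeable", {
  set.seed(11)
  s1 <- surv_sample(rexp(15), rbinom(15, 1, 0.7), 1)
  s2 <- surv_sample(rexp(15, 2), rbinom(15, 1, 0.7), 2)
  if (sum(s1$status) == 0) s1$status[1] <- 1L
  rt12 <- build_risk_table(s1, s2)
  expect_equal(weighted_logrank(rt12, weight_spec("FH", 0, 0))$statistic,
               weighted_logrank(rt12, weight_spec("LR"))$statistic)
  rt21 <- build_risk_table(surv_sample(s2$times, s2$status, 1),
                           surv_sample(s1$times, s1$status, 2))
  a <- weighted_logrank(rt12); b <- weighted_logrank(rt21)
  expect_equal(a$statistic, -b$statistic, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
})

test_that("normal p-values track the exhaustive permutation law at pooled n <= 8", {
  z_stat <- function(a, b)
    weighted_logrank(build_risk_table(a, b))$statistic
  cases <- list(
    list(s1 = surv_sample(c(0.3, 1.1, 2.5, 4.0), 1, 1),
         s2 = surv_sample(c(0.8, 1.9, 3.2, 5.5), 1, 2)),
    list(s1 = surv_sample(c(0.5, 1.4, 2.2, 6.0), c(1, 1, 0, 1), 1),
         s2 = surv_sample(c(0.9, 2.8, 3.6, 4.4), c(1, 1, 1, 0), 2)),
    list(s1 = surv_sample(c(0.2, 0.6, 1.0), 1, 1),
         s2 = surv_sample(c(1.5, 2.5, 3.5, 4.5, 5.5), 1, 2)))
  for (cs in cases) {
    pn <- weighted_logrank(build_risk_table(cs$s1, cs$s2))$p_value
    pe <- exact_perm_p(cs$s1, cs$s2, z_stat)
    expect_lt(abs(pn - pe), 0.15)
  }
})

test_that("combined versatile tests behave at the degenerate corners", {
  m <- mirrored_samples()
  sh <- shl_combined(build_risk_table(m$s1, m$s2))
  expect_equal(sh$z1, 0)
  expect_equal(sh$z2, 0)
  expect_equal(sh$shl1$p_value, 1)
  expect_equal(sh$shl2$p_value, 1)
  expect_equal(sh$shl3$p_value, 1)

  # perfect-dependence limit: all three p-values collapse to the
  # single-statistic two-sided p
  for (z in c(0.7, 1.5, 2.3)) {
    p0 <- 2 * pnorm(-z)
    expect_equal(2 * pnorm(-z / sqrt((1 + 1) / 2)), p0)
    expect_equal(crossurv:::bvn_absmean_sf(z, 1 - 1e-12), p0, tolerance = 1e-6)
    expect_equal(crossurv:::bvn_absmax_sf(z, 1 - 1e-12), p0, tolerance = 1e-6)
  }
  sh3 <- shl_combined(build_risk_table(surv_sample(c(1, 2, 4, 7), 1, 1),
                                       surv_sample(c(3, 5, 6, 9), 1, 2)))
  expect_equal(sh3$shl3$statistic, max(abs(sh3$z1), abs(sh3$z2)))
  expect_lte(abs(sh3$correlation), 1)
})

test_that("bivariate-normal quadrature matches a Monte Carlo oracle", {
  set.seed(5)
  rho <- 0.6
  z <- matrix(rnorm(2e5), ncol = 2)
  z[, 2] <- rho * z[, 1] + sqrt(1 - rho^2) * z[, 2]
  for (c0 in c(0.8, 1.6)) {
    mc_mean <- mean((abs(z[, 1]) + abs(z[, 2])) / 2 >= c0)
    mc_max <- mean(pmax(abs(z[, 1]), abs(z[, 2])) >= c0)
    se <- sqrt(0.25 / 2e5)
    expect_lt(abs(crossurv:::bvn_absmean_sf(c0, rho) - mc_mean), 4 * se + 1e-3)
    expect_lt(abs(crossurv:::bvn_absmax_sf(c0, rho) - mc_max), 4 * se + 1e-3)
  }
})
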