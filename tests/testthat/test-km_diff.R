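test_that("weighted Kaplan-Meier test vanishes on identical groups and
           reduces to the area between curves without censoring", {
  m <- mirrored_samples()
  r <- wkm_test(m$s1, m$s2)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  set.seed(15)
  s1 <- surv_sample(rexp(20), 1, 1)
  s2 <- surv_sample(rexp(20, 2), 1, 2)
  g <- crossurv:::wkm_geometry(s1, s2)
  expect_true(all(abs(g$w - 1) < 1e-12))     # no censoring: weight is 1
  # the unscaled integral equals the area between the KM curves up to tau
  km1 <- kaplan_meier(s1); km2 <- kaplan_meier(s2)
  grid <- g$starts
  area <- sum((step_value(km1, grid) - step_value(km2, grid)) * g$widths)
  expect_equal(sum(g$widths * g$w * (g$S1 - g$S2)), area, tolerance = 1e-12)
})

test_that("weighted Kaplan-Meier normal p agrees with a permutation oracle", {
  cfg <- scenario_config("D", 50, 50, 0.2)
  d <- simulate_scenario(cfg, seed = 31)
  p_norm <- wkm_test(d$sample1, d$sample2)$p_value
  p_perm <- mc_perm_p(d$sample1, d$sample2,
                      function(a, b) abs(wkm_test(a, b)$statistic),
                      B = 2000, seed = 99)
  expect_lt(abs(p_norm - p_perm), 0.03)
})

test_that("maximum weighted Kaplan-Meier test reduces and calibrates", {
  m <- mirrored_samples()
  r <- mkm_test(m$s1, m$s2, mkm_config(mc_draws = 10000, seed = 1))
  expect_equal(r$statistic, 0)
  expect_gt(r$p_value, 0.95)

  set.seed(16)
  s1 <- surv_sample(rexp(30), rbinom(30, 1, 0.8), 1)
  s2 <- surv_sample(rexp(30, 1.8), rbinom(30, 1, 0.8), 2)
  single <- mkm_test(s1, s2, mkm_config(rho_grid = 0, gamma_grid = 0,
                                        mc_draws = 200000, seed = 2))
  ref <- wkm_test(s1, s2)
  expect_equal(single$statistic, abs(ref$statistic), tolerance = 1e-10)
  expect_equal(single$p_value, ref$p_value, tolerance = 0.01)

  full <- mkm_test(s1, s2, mkm_config(mc_draws = 20000, seed = 3))
  expect_length(full$extras$components, 9L)
  expect_true(all(eigen(full$extras$correlation,
                        symmetric = TRUE)$values > -1e-8))
})

test_that("Lin-Xu area test: identities, monotonicity in the correlation", {
  m <- mirrored_samples()
  r <- lx_test(m$s1, m$s2, lx_config(sided = "two"))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  # restricted-mean identity without censoring: area = mean(min(X, tau))
  set.seed(17)
  s1 <- surv_sample(rexp(25), 1, 1)
  s2 <- surv_sample(rexp(25, 1.4), 1, 2)
  rt <- build_risk_table(s1, s2)
  tau <- rt$event_times[rt$tau_index]
  a1 <- crossurv:::lx_area(s1, tau, 0.5)
  expect_equal(a1$area, mean(pmin(s1$times, tau)), tolerance = 1e-12)

  # z grows monotonically as the assumed cross-interval correlation drops
  zs <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(r)
    lx_test(s1, s2, lx_config(r, "two"))$statistic, numeric(1))
  expect_true(all(diff(zs) <= 1e-12))
  # one-sided p is half the two-sided p at the same statistic
  p1 <- lx_test(s1, s2, lx_config(0.5, "one"))$p_value
  p2 <- lx_test(s1, s2, lx_config(0.5, "two"))$p_value
  expect_equal(2 * p1, p2, tolerance = 1e-12)
})

test_that("Lin-Wang squared observed-expected statistic and permutation null", {
  h <- hand_samples()
  r <- lw_test(h$s1, h$s2, permutations = 300, seed = 4)
  expect_equal(r$statistic, 0.25 + 1 / 9 + 0.25, tolerance = 1e-12)

  m <- mirrored_samples()
  r0 <- lw_test(m$s1, m$s2, permutations = 300, seed = 4)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  # permutation p-value is deterministic under the seed
  set.seed(18)
  s1 <- surv_sample(rexp(20), rbinom(20, 1, 0.8), 1)
  s2 <- surv_sample(rexp(20, 1.5), rbinom(20, 1, 0.8), 2)
  p_a <- lw_test(s1, s2, 500, seed = 7)$p_value
  p_b <- lw_test(s1, s2, 500, seed = 7)$p_value
  expect_identical(p_a, p_b)
})
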