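test_that("Brownian supremum series calibrates the Renyi test", {
  # root of the series at the 0.05 level
  root <- uniroot(function(q) crossurv:::brownian_sup_sf(q) - 0.05,
                  c(1, 4), tol = 1e-8)$root
  expect_equal(root, 2.2414, tolerance = 1e-4)
  expect_equal(crossurv:::brownian_sup_sf(0), 1)

  m <- mirrored_samples()
  r <- renyi_test(build_risk_table(m$s1, m$s2))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  # supremum dominates the endpoint statistic on any input
  set.seed(8)
  for (i in 1:20) {
    s1 <- surv_sample(rexp(20), rbinom(20, 1, 0.8), 1)
    s2 <- surv_sample(rexp(20, 1.6), rbinom(20, 1, 0.8), 2)
    if (sum(s1$status) + sum(s2$status) == 0) next
    rt <- build_risk_table(s1, s2)
    lr <- weighted_logrank(rt)
    expect_gte(renyi_test(rt)$statistic + 1e-12, abs(lr$statistic))
  }
})

test_that("supremum and integral statistics are invariant to group exchange", {
  set.seed(9)
  s1 <- surv_sample(rexp(25), rbinom(25, 1, 0.75), 1)
  s2 <- surv_sample(rweibull(25, 2, 3), rbinom(25, 1, 0.75), 2)
  rt12 <- build_risk_table(s1, s2)
  rt21 <- build_risk_table(surv_sample(s2$times, s2$status, 1),
                           surv_sample(s1$times, s1$status, 2))
  expect_equal(renyi_test(rt12)$statistic, renyi_test(rt21)$statistic)
  expect_equal(mks_test(rt12)$statistic, mks_test(rt21)$statistic)
  c12 <- cvm_tests(rt12); c21 <- cvm_tests(rt21)
  expect_equal(c12$cvm1$statistic, c21$cvm1$statistic)
  expect_equal(c12$cvm2$statistic, c21$cvm2$statistic)
})

test_that("modified Kolmogorov-Smirnov agrees with its permutation oracle", {
  cfg <- scenario_config("A", 20, 20, 0)
  d <- simulate_scenario(cfg, seed = 17)
  p_asym <- mks_test(build_risk_table(d$sample1, d$sample2))$p_value
  p_perm <- mc_perm_p(d$sample1, d$sample2,
                      function(a, b) mks_test(build_risk_table(a, b))$statistic,
                      B = 1500, seed = 99)
  # the bridge calibration may be conservative but must stay valid
  expect_gte(p_asym, p_perm - 2 * sqrt(p_perm * (1 - p_perm) / 1500))
  expect_lt(abs(p_asym - p_perm), 0.10)

  m <- mirrored_samples()
  r <- mks_test(build_risk_table(m$s1, m$s2))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
})

test_that("Cramer-von Mises limit laws are reproduced by the eigen expansion", {
  # classical omega^2 critical value at the 0.05 level
  lam_b <- crossurv:::cvm_eigenvalues("bridge")
  crit <- uniroot(function(x) crossurv:::wchisq_sf(x, lam_b) - 0.05,
                  c(0.2, 0.9), tol = 1e-8)$root
  expect_equal(crit, 0.4614, tolerance = 2e-4)

  # Monte Carlo oracle for both weighted chi-square laws
  lam_m <- crossurv:::cvm_eigenvalues("motion")
  set.seed(10)
  zm <- matrix(rnorm(5e4 * 50)^2, ncol = 50)
  draws_m <- zm %*% as.numeric(lam_m)[1:50] + (0.5 - sum(lam_m[1:50]))
  draws_b <- zm %*% as.numeric(lam_b)[1:50] + (1 / 6 - sum(lam_b[1:50]))
  for (q in c(0.3, 0.8)) {
    expect_lt(abs(crossurv:::wchisq_sf(q, lam_m) - mean(draws_m >= q)), 0.01)
    expect_lt(abs(crossurv:::wchisq_sf(q, lam_b) - mean(draws_b >= q)), 0.01)
  }

  m <- mirrored_samples()
  cv <- cvm_tests(build_risk_table(m$s1, m$s2))
  expect_equal(cv$cvm1$statistic, 0)
  expect_equal(cv$cvm2$statistic, 0)
  expect_equal(cv$cvm1$p_value, 1)
  expect_equal(cv$cvm2$p_value, 1)
})

test_that("null p-values of the hazard-scale tests are not anti-conservative", {
  reps <- 400
  cfg <- scenario_config("null", 50, 50, 0.2)
  set.seed(14)
  ps <- replicate(reps, {
    d <- simulate_scenario(cfg)
    rt <- build_risk_table(d$sample1, d$sample2)
    cv <- cvm_tests(rt)
    c(renyi_test(rt)$p_value, mks_test(rt)$p_value,
      cv$cvm1$p_value, cv$cvm2$p_value)
  })
  rej <- rowMeans(ps <= 0.05)
  se3 <- 3 * sqrt(0.05 * 0.95 / reps)
  for (r in rej) expect_lte(r, 0.05 + se3)
})
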