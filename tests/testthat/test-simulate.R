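test_that("samplers match their laws", {
  # Weibull with shape 1 is exponential: mean 1/rate
  x <- sample_survival_times(law_weibull(1, 4), 1e5, seed = 1)
  expect_lt(abs(mean(x) - 4), 0.05)
  # closed-form Weibull median
  med <- 1 * log(2)^(1 / 2)
  expect_equal(med, 0.8326, tolerance = 1e-4)
  expect_equal(law_survival(law_weibull(2, 1), med), 0.5, tolerance = 1e-12)

  # single-rate piecewise exponential is the exponential law
  y <- sample_survival_times(law_piecewise_exponential(numeric(0), 0.25),
                             1e4, seed = 2)
  expect_gt(suppressWarnings(
    ks.test(y, function(t) 1 - law_survival(law_exponential(0.25), t))$p.value),
    0.01)

  # inverse-CDF samplers pass a goodness-of-fit check against their law
  laws <- list(law_exponential(0.25), law_weibull(2.5, 3.2),
               law_piecewise_exponential(c(1, 3), c(0.1, 0.5, 0.25)))
  for (i in seq_along(laws)) {
    z <- sample_survival_times(laws[[i]], 1e4, seed = 30 + i)
    p <- suppressWarnings(
      ks.test(z, function(t) 1 - law_survival(laws[[i]], t))$p.value)
    expect_gt(p, 0.001)
  }
  expect_error(law_weibull(-1, 2), "positive")
  expect_error(law_piecewise_exponential(c(2, 1), c(1, 1, 1)), "increasing")
})

test_that("censoring calibration solves the uniform-censoring equation", {
  law <- law_exponential(0.25)
  # independent oracle: closed-form equation (1 - exp(-u))/u = rate, a = u/0.25
  closed_form_a <- function(rate)
    uniroot(function(u) (1 - exp(-u)) / u - rate, c(1e-6, 50),
            tol = 1e-10)$root / 0.25
  expect_equal(closed_form_a(0.20), 19.86, tolerance = 1e-3)
  expect_equal(closed_form_a(0.40), 8.922, tolerance = 1e-3)
  for (rate in c(0.2, 0.4, 0.6))
    expect_equal(calibrate_censoring(law, rate), closed_form_a(rate),
                 tolerance = 1e-5)
  expect_error(calibrate_censoring(law, 1.2), "between 0 and 1")

  # round trip: empirical censoring fraction hits the target within 0.01
  for (law_i in list(law, law_weibull(2.5, 3.2))) {
    for (rate in c(0.2, 0.4, 0.6)) {
      a <- calibrate_censoring(law_i, rate)
      x <- sample_survival_times(law_i, 1e5, seed = 40)
      smp <- apply_censoring(x, censoring_spec("uniform", a = a, b = a,
                                               target_rate = rate),
                             group = 1L, seed = 41)
      expect_lt(abs(mean(smp$status == 0) - rate), 0.01)
    }
  }

  # kind = none keeps every subject an event
  s <- apply_censoring(c(1, 2, 3), censoring_spec("none"))
  expect_true(all(s$status == 1L))
})

test_that("crossing solver: closed form, no-crossing, identical laws", {
  cp <- crossing_point(law_weibull(1.5, 2), law_weibull(0.8, 3))
  expect_equal(cp$time, 1.258, tolerance = 1e-3)
  expect_null(crossing_point(law_weibull(1, 2), law_weibull(1, 3)))
  expect_error(crossing_point(law_exponential(0.5), law_weibull(1, 2)),
               "curves-identical")
  # bisection path for piecewise laws
  cp2 <- crossing_point(law_piecewise_exponential(2, c(0.1, 0.6)),
                        law_exponential(0.25))
  expect_equal(law_survival(law_exponential(0.25), cp2$time), cp2$level,
               tolerance = 1e-6)
})

test_that("scenario presets put the crossing in the stated survival bands", {
  bands <- list(B = c(0.6, 1), C = c(0.4, 0.6), D = c(0.2, 0.4))
  for (lab in names(bands)) {
    cfg <- scenario_config(lab, 50, 50, 0)
    cp <- crossing_point(cfg$law1, cfg$law2)
    expect_gte(cp$level, bands[[lab]][1])
    expect_lte(cp$level, bands[[lab]][2])
  }
  expect_null(crossing_point(scenario_config("A")$law1,
                             scenario_config("A")$law2))

  cfg <- scenario_config("C", 30, 40, 0.4)
  d <- simulate_scenario(cfg, seed = 3)
  expect_identical(d$sample1$size, 30L)
  expect_identical(d$sample2$size, 40L)
  d2 <- simulate_scenario(cfg, seed = 3)
  expect_identical(d$sample1$times, d2$sample1$times)
})
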