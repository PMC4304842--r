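#' Names of the registered two-sample tests
#'
#' The registry order matches the column order used by the benchmark
#' tables: LR, GW, TW, G01, G10, G11, RY, MKS, CVM1, CVM2, WKM, MKM,
#' SHL1, SHL2, SHL3, LW, LX1, LX2, TS, NY1, NY2.
#'
#' @return Character vector of method names.
#' @export
crossurv_methods <- function() {
  c("LR", "GW", "TW", "G01", "G10", "G11", "RY", "MKS", "CVM1", "CVM2",
    "WKM", "MKM", "SHL1", "SHL2", "SHL3", "LW", "LX1", "LX2", "TS",
    "NY1", "NY2")
}

# One method's (statistic, p-value) on a dataset.  `permutations` caps
# the budget of permutation-calibrated tests; `seed` drives every
# stochastic calibration.
method_result <- function(method, sample1, sample2, permutations = 2000L,
                          seed = 1L, rho_cross = 0.5, alpha = 0.05,
                          mc_draws = 100000L) {
  rt_needed <- !method %in% c("WKM", "MKM", "LW", "LX1", "LX2", "TS",
                              "NY1", "NY2")
  rt <- if (rt_needed) build_risk_table(sample1, sample2) else NULL
  wl <- function(nm, r = 0, g = 0) weighted_logrank(rt, weight_spec(nm, r, g))
  res <- switch(method,
    LR = wl("LR"), GW = wl("GW"), TW = wl("TW"),
    G01 = wl("FH", 0, 1), G10 = wl("FH", 1, 0), G11 = wl("FH", 1, 1),
    RY = renyi_test(rt),
    MKS = mks_test(rt),
    CVM1 = cvm_tests(rt)$cvm1,
    CVM2 = cvm_tests(rt)$cvm2,
    WKM = wkm_test(sample1, sample2),
    MKM = mkm_test(sample1, sample2,
                   mkm_config(mc_draws = mc_draws, seed = seed)),
    SHL1 = shl_combined(rt)$shl1,
    SHL2 = shl_combined(rt)$shl2,
    SHL3 = shl_combined(rt)$shl3,
    LW = lw_test(sample1, sample2, permutations, seed),
    LX1 = lx_test(sample1, sample2, lx_config(rho_cross, "one")),
    LX2 = lx_test(sample1, sample2, lx_config(rho_cross, "two")),
    TS = {
      ts <- ts_test(sample1, sample2, alpha, permutations, seed)
      new_test_result("TS", NA_real_, ts$p_overall,
                      extras = list(two_stage = ts))
    },
    NY1 = ny_test(sample1, sample2,
                  ny_config(permutations = permutations, seed = seed),
                  type = "fixed"),
    NY2 = ny_test(sample1, sample2,
                  ny_config(permutations = permutations, seed = seed),
                  type = "data_driven"),
    stop("unknown method: ", method))
  res
}

#' Monte Carlo size/power estimation for one test under one scenario
#'
#' Draws \code{reps} independent replicate datasets from the scenario,
#' runs the test on each, and reports the proportion of replicates with
#' p-value at or below \code{alpha}, with its Monte Carlo standard
#' error.  Replicates receive pre-assigned seeds spawned from the
#' master seed, so results are reproducible and independent of
#' evaluation order.  A replicate on which the test raises an error or
#' a degenerate-variance flag is counted as a non-rejection (an
#' uninformative sample cannot reject) and tallied in
#' \code{degenerate}.
#'
#' @param test A method name from \code{\link{crossurv_methods}}, or a
#'   function \code{(sample1, sample2, seed)} returning a p-value or a
#'   \code{crossurv_test}.
#' @param scenario A \code{\link{scenario_config}}.
#' @param reps Number of Monte Carlo replicates (at least 100).
#' @param alpha Nominal level.
#' @param seed Master seed.
#' @param permutations Permutation budget per replicate for
#'   permutation-calibrated tests (reduced inside benchmarks; the
#'   single-dataset default elsewhere is 2000).
#' @param mc_draws Monte Carlo draws for the MKM p-value.
#' @return An object of class \code{mc_result}.
#' @export
run_monte_carlo <- function(test, scenario, reps = 5000L, alpha = 0.05,
                            seed = 1L, permutations = 500L,
                            mc_draws = 20000L) {
  if (reps < 100L) stop("reps must be at least 100")
  test_name <- if (is.character(test)) test else "custom"
  rep_seeds <- with_seed(seed, sample.int(2147483646L, reps, replace = TRUE))
  fn <- if (is.character(test)) {
    function(s1, s2, sd) method_result(test, s1, s2,
                                       permutations = permutations,
                                       seed = sd, alpha = alpha,
                                       mc_draws = mc_draws)
  } else test
  rejections <- 0L
  degenerate <- 0L
  for (i in seq_len(reps)) {
    dat <- simulate_scenario(scenario, seed = rep_seeds[i])
    res <- tryCatch(fn(dat$sample1, dat$sample2, rep_seeds[i] %% 1000003L + 1L),
                    error = function(e) NULL)
    if (is.null(res) || (inherits(res, "crossurv_test") && is_degenerate(res))) {
      degenerate <- degenerate + 1L
      next
    }
    p <- if (inherits(res, "crossurv_test")) res$p_value else as.numeric(res)
    if (!is.na(p) && p <= alpha) rejections <- rejections + 1L
  }
  prop <- rejections / reps
  structure(list(test = test_name, scenario = scenario$label,
                 n1 = scenario$n1, n2 = scenario$n2,
                 censoring_rate = scenario$censoring$target_rate,
                 reps = reps, alpha = alpha,
                 rejections = rejections, proportion = prop,
                 mc_se = sqrt(prop * (1 - prop) / reps),
                 degenerate = degenerate, seed = seed),
            class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf(
    "%s | scenario %s, n = (%d, %d), censoring %.0f%%: rejection %.4f (MC SE %.4f, %d reps)\n",
    x$test, x$scenario, x$n1, x$n2, 100 * x$censoring_rate,
    x$proportion, x$mc_se, x$reps))
  if (x$degenerate > 0)
    cat(sprintf("  %d degenerate replicates counted as non-rejections\n",
                x$degenerate))
  invisible(x)
}

#' Arrange Monte Carlo results as a benchmark table
#'
#' Rows are (n1, n2) by censoring rate; columns are tests in registry
#' order; missing cells stay \code{NA}.
#'
#' @param results A list of \code{mc_result} objects.
#' @return A data frame.
#' @export
summarize_table <- function(results) {
  if (inherits(results, "mc_result")) results <- list(results)
  key <- vapply(results, function(r)
    sprintf("%s|%d|%d|%g", r$scenario, r$n1, r$n2, r$censoring_rate),
    character(1))
  tests <- unique(vapply(results, `[[`, character(1), "test"))
  tests <- c(intersect(crossurv_methods(), tests),
             setdiff(tests, crossurv_methods()))
  rows <- unique(key)
  out <- do.call(rbind, lapply(rows, function(k) {
    first <- results[[match(k, key)]]
    df <- data.frame(scenario = first$scenario, n1 = first$n1, n2 = first$n2,
                     censoring = first$censoring_rate)
    for (tn in tests) {
      hit <- which(key == k &
                     vapply(results, `[[`, character(1), "test") == tn)
      df[[tn]] <- if (length(hit)) results[[hit[1]]]$proportion else NA_real_
    }
    df
  }))
  out
}

#' Write a benchmark table as delimited text
#'
#' @param table A data frame from \code{\link{summarize_table}}.
#' @param path Output path.
#' @param sep Delimiter.
#' @return \code{path}, invisibly.
#' @export
write_benchmark_table <- function(table, path, sep = "\t") {
  utils::write.table(table, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
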