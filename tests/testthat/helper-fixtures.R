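# Shared fixtures and independent oracles, built in code.

# Four-subject hand example: group 1 events at 1 and 3, group 2 at 2 and 4.
hand_samples <- function() {
  list(s1 = surv_sample(c(1, 3), 1, 1),
       s2 = surv_sample(c(2, 4), 1, 2))
}

# Two identical (mirrored) arms: every statistic must vanish.
mirrored_samples <- function(times = c(1, 2, 3, 5, 8), status = 1) {
  list(s1 = surv_sample(times, status, 1),
       s2 = surv_sample(times, status, 2))
}

# Exhaustive group-label permutation p-value for any statistic
# (absolute value compared); feasible for pooled n <= 10.
exact_perm_p <- function(s1, s2, statfun) {
  tm <- c(s1$times, s2$times)
  st <- c(s1$status, s2$status)
  n <- length(tm)
  obs <- abs(statfun(s1, s2))
  sets <- utils::combn(n, s1$size)
  stats <- apply(sets, 2, function(idx) {
    a <- surv_sample(tm[idx], st[idx], 1)
    b <- surv_sample(tm[-idx], st[-idx], 2)
    tryCatch(abs(statfun(a, b)), error = function(e) 0)
  })
  mean(stats >= obs - 1e-12)
}

# Monte Carlo group-label permutation p-value (one-sided on statfun).
mc_perm_p <- function(s1, s2, statfun, B = 1500, seed = 99) {
  tm <- c(s1$times, s2$times)
  st <- c(s1$status, s2$status)
  n <- length(tm)
  obs <- statfun(s1, s2)
  set.seed(seed)
  cnt <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, s1$size)
    a <- surv_sample(tm[idx], st[idx], 1)
    bb <- surv_sample(tm[-idx], st[-idx], 2)
    val <- tryCatch(statfun(a, bb), error = function(e) 0)
    if (val >= obs - 1e-12) cnt <- cnt + 1L
  }
  (1 + cnt) / (B + 1)
}

# Null rejection rate of a p-value-returning function under the
# exponential(0.25) null.
null_rejection_rate <- function(pfun, n1, n2, censoring_rate, reps,
                                seed = 2024, alpha = 0.05) {
  cfg <- scenario_config("null", n1, n2, censoring_rate)
  set.seed(seed)
  rej <- 0L
  for (i in seq_len(reps)) {
    d <- simulate_scenario(cfg)
    p <- pfun(d$sample1, d$sample2, sample.int(1e6, 1))
    if (!is.na(p) && p <= alpha) rej <- rej + 1L
  }
  rej / reps
}
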