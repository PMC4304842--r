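# Pooled-data machinery for group-label permutation nulls.
#
# The pooled event times, pooled death counts and pooled at-risk counts
# are invariant under relabelling, so they are computed once; each
# permutation only recomputes the group-1 at-risk and death counts
# (O(n + #event times) per draw).

perm_frame <- function(sample1, sample2) {
  times <- c(sample1$times, sample2$times)
  status <- c(sample1$status, sample2$status)
  if (sum(status) == 0L)
    stop("no-events: neither group contains an observed event")
  et <- sort(unique(times[status == 1L]))
  k <- length(et)
  r <- findInterval(times, et)
  e <- ifelse(status == 1L, match(times, et), NA_integer_)
  n <- rev(cumsum(rev(tabulate(r, nbins = k))))
  d <- tabulate(e[status == 1L], nbins = k)
  list(times = times, status = status, et = et, k = k, r = r, e = e,
       n = n, d = d, n_total = length(times), n1_size = sample1$size)
}

# Group-1 counts and tau for one label assignment (idx1 = group-1 rows).
frame_counts <- function(pf, idx1) {
  n1 <- rev(cumsum(rev(tabulate(pf$r[idx1], nbins = pf$k))))
  ev1 <- idx1[pf$status[idx1] == 1L]
  d1 <- tabulate(pf$e[ev1], nbins = pf$k)
  both <- n1 >= 1L & (pf$n - n1) >= 1L
  tau <- if (any(both)) max(which(both)) else 0L
  list(n1 = n1, d1 = d1, tau = tau)
}

frame_hyper_var <- function(pf, n1) {
  ifelse(pf$n > 1,
         pf$d * (n1 / pf$n) * (1 - n1 / pf$n) * (pf$n - pf$d) / (pf$n - 1),
         0)
}

# Evaluate `stat_fn(pf, counts)` on the observed labels and `permutations`
# random relabellings; returns the one-sided permutation p-value
# (1 + #{perm >= obs}) / (B + 1) together with the observed statistic.
perm_pvalue <- function(sample1, sample2, stat_fn, permutations, seed) {
  pf <- perm_frame(sample1, sample2)
  obs <- stat_fn(pf, frame_counts(pf, seq_len(pf$n1_size)))
  perm <- with_seed(seed, {
    vapply(seq_len(permutations), function(b) {
      idx1 <- sample.int(pf$n_total, pf$n1_size)
      stat_fn(pf, frame_counts(pf, idx1))
    }, numeric(1))
  })
  list(observed = obs,
       p_value = (1 + sum(perm >= obs - 1e-12)) / (permutations + 1),
       permutations = permutations)
}

# Run `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards.  seed = NULL uses the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
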