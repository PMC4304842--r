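# Common result container for all two-sample tests.

new_test_result <- function(method, statistic, p_value, variance = NA_real_,
                            sided = "two", extras = list()) {
  structure(list(method = method,
                 statistic = as.numeric(statistic),
                 variance = as.numeric(variance),
                 p_value = min(max(as.numeric(p_value), 0), 1),
                 sided = sided,
                 extras = extras),
            class = "crossurv_test")
}

degenerate_result <- function(method, sided = "two", extras = list()) {
  extras$degenerate <- TRUE
  new_test_result(method, 0, 1, 0, sided, extras)
}

is_degenerate <- function(x) isTRUE(x$extras$degenerate)

#' @export
print.crossurv_test <- function(x, digits = 4L, ...) {
  cat(sprintf("%s test (%s-sided)\n", x$method, x$sided))
  cat(sprintf("  statistic = %.*f, p-value = %.*f\n",
              digits, x$statistic, digits, x$p_value))
  if (is_degenerate(x))
    cat("  note: degenerate variance; the sample carries no two-group information\n")
  invisible(x)
}
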