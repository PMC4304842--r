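#' Construct a one-group right-censored survival sample
#'
#' Bundles observed times, event indicators and a group label into a
#' validated container used by every test in the package.
#'
#' @param times Numeric vector of observed times, all strictly positive.
#' @param status Event indicator per subject: 1 = event observed,
#'   0 = right-censored.  Recycled if of length 1.
#' @param group Group label, 1 or 2.
#'
#' @return An object of class \code{surv_sample}: a list with elements
#'   \code{times}, \code{status}, \code{group} and \code{size}.
#' @examples
#' surv_sample(c(1.2, 3.4, 5.6), c(1, 0, 1), group = 1)
#' @export
surv_sample <- function(times, status = 1, group = 1L) {
  times <- as.numeric(times)
  if (length(times) < 1L) stop("a survival sample needs at least one subject")
  if (anyNA(times) || any(times <= 0))
    stop("all observation times must be positive and non-missing")
  status <- as.integer(rep_len(status, length(times)))
  if (anyNA(status) || !all(status %in% c(0L, 1L)))
    stop("status must contain only 0 (censored) and 1 (event)")
  group <- as.integer(group)
  if (length(group) != 1L || !group %in% c(1L, 2L))
    stop("group must be a single label, 1 or 2")
  structure(list(times = times, status = status, group = group,
                 size = length(times)),
            class = "surv_sample")
}

#' @export
print.surv_sample <- function(x, ...) {
  cat(sprintf("Survival sample (group %d): %d subjects, %d events (%.1f%% censored)\n",
              x$group, x$size, sum(x$status),
              100 * mean(x$status == 0L)))
  invisible(x)
}

as_surv_sample <- function(x, group) {
  if (inherits(x, "surv_sample")) return(x)
  surv_sample(x$times, x$status, group)
}

#' Read a two-group survival dataset from delimited text
#'
#' Expects a header line with columns \code{time}, \code{status} and
#' \code{group}; the delimiter (comma or tab) is detected from the header.
#' Group labels are coerced to 1/2 by the sorted order of the distinct
#' labels found in the file.
#'
#' @param path Path to the file.
#' @return A list with components \code{sample1} and \code{sample2}
#'   (class \code{surv_sample}) and \code{group_labels}, the original
#'   labels in the order they were mapped to 1 and 2.
#' @export
read_survival_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("time", "status", "group")
  if (!all(need %in% names(df)))
    stop("header must contain columns time, status, group (found: ",
         paste(names(df), collapse = ", "), ")")
  tm <- suppressWarnings(as.numeric(df$time))
  bad <- which(is.na(tm) | tm <= 0)
  if (length(bad))
    stop(sprintf("row %d: invalid time value '%s' (must be a positive number)",
                 bad[1L], as.character(df$time[bad[1L]])))
  st <- suppressWarnings(as.numeric(df$status))
  bad <- which(is.na(st) | !st %in% c(0, 1))
  if (length(bad))
    stop(sprintf("row %d: invalid status value '%s' (must be 0 or 1)",
                 bad[1L], as.character(df$status[bad[1L]])))
  labs <- sort(unique(df$group))
  if (length(labs) != 2L)
    stop("expected exactly 2 distinct group labels, found ", length(labs))
  g <- match(df$group, labs)
  list(sample1 = surv_sample(tm[g == 1L], st[g == 1L], 1L),
       sample2 = surv_sample(tm[g == 2L], st[g == 2L], 2L),
       group_labels = labs)
}

#' Write a two-group survival dataset as delimited text
#'
#' @param sample1,sample2 \code{surv_sample} objects.
#' @param path Output path.
#' @param sep Field delimiter, \code{","} (default) or \code{"\t"}.
#' @return \code{path}, invisibly.
#' @export
write_survival_csv <- function(sample1, sample2, path, sep = ",") {
  df <- data.frame(
    time = c(sample1$times, sample2$times),
    status = c(sample1$status, sample2$status),
    group = rep(c(1L, 2L), c(sample1$size, sample2$size)))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
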