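#' Spearman rank correlation of a series against time
#'
#' The trend statistic used throughout: `rho` is the Pearson correlation of
#' the average ranks of the series and of time; the two-sided p-value uses
#' the exact null distribution for n <= 8 and the t-approximation otherwise.
#' Significance is declared at p <= 0.05 with no multiple-testing
#' correction.
#'
#' @param series numeric vector of annual values (no missing values).
#' @param time time axis; defaults to `seq_along(series)`.
#' @return An object of class `trend_result`: list with `rho`, `p_value`,
#'   `significant`, `n`. A constant series returns `NA` rho and p.
#' @export
spearman_trend <- function(series, time = seq_along(series)) {
  if (anyNA(series)) stop("series contains missing values")
  n <- length(series)
  if (n < 4L) stop("trend test needs at least 4 points")
  if (length(time) != n) stop("series and time differ in length")
  if (stats::sd(series) == 0) {
    res <- list(rho = NA_real_, p_value = NA_real_, significant = NA, n = n)
    return(structure(res, class = "trend_result"))
  }
  rho <- stats::cor(rank(series), rank(time))
  ct <- suppressWarnings(
    stats::cor.test(time, series, method = "spearman", exact = n <= 8,
                    alternative = "two.sided"))
  p <- unname(ct$p.value)
  structure(list(rho = rho, p_value = p, significant = p <= 0.05, n = n),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("Spearman trend: rho = %s, p = %s (n = %d)%s\n",
              format(x$rho, digits = 3), format(x$p_value, digits = 3), x$n,
              if (isTRUE(x$significant)) " *" else ""))
  invisible(x)
}

#' Trend tests over a collection of series
#'
#' @param series named list of equal-length numeric series, or a data.frame
#'   whose columns (except an optional `year` column, used as the time axis)
#'   are the series.
#' @return tidy data.frame with one row per series: `series`, `rho`,
#'   `p_value`, `significant`, `n`.
#' @export
trend_matrix <- function(series) {
  if (is.data.frame(series)) {
    time <- if ("year" %in% names(series)) series$year else seq_len(nrow(series))
    series <- as.list(series[setdiff(names(series), "year")])
  } else {
    time <- seq_along(series[[1]])
  }
  lens <- vapply(series, length, integer(1))
  if (length(unique(lens)) > 1L) stop("series must have equal length")
  rows <- lapply(names(series), function(nm) {
    tr <- spearman_trend(series[[nm]], time)
    data.frame(series = nm, rho = tr$rho, p_value = tr$p_value,
               significant = tr$significant, n = tr$n)
  })
  do.call(rbind, rows)
}
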