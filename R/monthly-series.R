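#' Monthly sea-surface temperature series
#'
#' A `monthly_series` is a data frame with columns `year`, `month` (1-12)
#' and `sst_c` (degrees Celsius), sampled contiguously month by month. It is
#' the common currency passed between the climatology, downscaling and
#' cover-projection stages.
#'
#' @param year Integer calendar years, one per monthly record.
#' @param month Integer months 1-12.
#' @param sst_c Sea-surface temperature, degrees C.
#' @return A `monthly_series` data frame sorted by `(year, month)`.
#' @examples
#' ms <- monthly_series(rep(2000:2001, each = 12), rep(1:12, 2), rnorm(24, 25))
#' nrow(ms)
#' @export
monthly_series <- function(year, month, sst_c) {
  df <- data.frame(year = as.integer(year), month = as.integer(month),
                   sst_c = as.numeric(sst_c))
  df <- df[order(df$year, df$month), , drop = FALSE]
  rownames(df) <- NULL
  validate_monthly_series(df)
  class(df) <- c("monthly_series", "data.frame")
  df
}

validate_monthly_series <- function(df) {
  if (!all(c("year", "month", "sst_c") %in% names(df)))
    stopf("monthly series needs columns year, month, sst_c",
          class = "coralproj_format_error")
  if (nrow(df) == 0)
    stopf("monthly series is empty", class = "coralproj_format_error")
  if (anyNA(df))
    stopf("monthly series contains missing values",
          class = "coralproj_format_error")
  if (any(df$month < 1 | df$month > 12))
    stopf("month outside 1..12", class = "coralproj_format_error")
  idx <- df$year * 12L + (df$month - 1L)
  step <- diff(idx)
  if (any(step != 1L)) {
    bad <- which(step != 1L)[1]
    # report the first month that is missing (gap) or repeated (duplicate)
    nxt <- idx[bad] + 1L
    stopf("monthly series gap or duplicate at %d-%02d",
          nxt %/% 12L, nxt %% 12L + 1L, class = "coralproj_format_error")
  }
  invisible(df)
}

#' @export
print.monthly_series <- function(x, ...) {
  cat(sprintf("<monthly_series> %d months, %d-%02d to %d-%02d, mean %.2f degC\n",
              nrow(x), x$year[1], x$month[1], x$year[nrow(x)],
              x$month[nrow(x)], mean(x$sst_c)))
  invisible(x)
}

#' Read a monthly SST series from CSV
#'
#' Expects the dialect `year,month,sst_c` (UTF-8, '.' decimal). Records are
#' sorted on read, then validated: any calendar gap, duplicate month or
#' missing value is an error naming the first offending `(year, month)`.
#'
#' @param path Path to a CSV file.
#' @param format Only `"csv"` is supported.
#' @return A [monthly_series()].
#' @seealso [write_sst()]
#' @export
read_sst <- function(path, format = c("csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path)
  monthly_series(df$year, df$month, df$sst_c)
}

#' Write a monthly SST series to CSV
#'
#' @param x A [monthly_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sst <- function(x, path) {
  validate_monthly_series(x)
  utils::write.csv(as.data.frame(x)[, c("year", "month", "sst_c")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Restrict a monthly series to a year window
#'
#' @param x A [monthly_series()].
#' @param start_year,end_year Inclusive calendar-year bounds.
#' @return A [monthly_series()] covering only the requested years.
#' @export
series_window <- function(x, start_year, end_year) {
  keep <- x$year >= start_year & x$year <= end_year
  if (!any(keep)) stopf("window %d-%d not covered by series", start_year, end_year)
  monthly_series(x$year[keep], x$month[keep], x$sst_c[keep])
}

# years present with all 12 months
full_years <- function(x) {
  tab <- table(x$year)
  as.integer(names(tab)[tab == 12L])
}

# annual means over full calendar years
annual_means <- function(x) {
  yrs <- full_years(x)
  sub <- x[x$year %in% yrs, ]
  data.frame(year = yrs,
             sst_c = as.numeric(tapply(sub$sst_c, sub$year, mean)))
}
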