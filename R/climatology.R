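#' Monthly SST climatology
#'
#' Computes per-calendar-month means and interannual standard deviations
#' over a reference period, plus the summary statistics the growth and
#' bleaching modules anchor on: `clim_max` / `clim_min` (warmest / coolest
#' climatological monthly mean) and `clim_sd`.
#'
#' `clim_sd` defaults to the standard deviation of the 12 climatological
#' monthly means -- i.e. the spread of the seasonal cycle itself, the
#' quantity the growth-curve anchor "maximum climatological monthly mean
#' minus two standard deviations" refers to. The alternative reading
#' (interannual SD of the warmest calendar month) is available via
#' `sd_mode = "interannual_warmest"`.
#'
#' @param series A [monthly_series()].
#' @param ref_period Length-2 integer vector `(start_year, end_year)`. The
#'   default uses every complete year in the record from 1945 onward (or
#'   the whole record when it starts later), mirroring the practice of
#'   discarding early reconstruction years with large standard errors.
#' @param sd_mode `"seasonal"` (default) or `"interannual_warmest"`; see
#'   Details.
#' @return An `sst_climatology` object: list with `monthly_mean`,
#'   `monthly_sd` (both length 12), `clim_max`, `clim_min`, `clim_sd`,
#'   `ref_period`, `n_years`.
#' @examples
#' p <- synth_sst_params(1950, 30, 25 + 3 * cospi((1:12 - 8) / 6),
#'                       rep(0, 12), seed = 1)
#' cl <- monthly_climatology(gen_historic_sst(p))
#' cl$clim_max   # 28
#' @export
monthly_climatology <- function(series, ref_period = NULL,
                                sd_mode = c("seasonal", "interannual_warmest")) {
  validate_monthly_series(series)
  sd_mode <- match.arg(sd_mode)
  fy <- full_years(series)
  if (is.null(ref_period)) {
    lo <- if (min(fy) < 1945 && max(fy) >= 1945) 1945L else min(fy)
    ref_period <- c(lo, max(fy))
  }
  yrs <- fy[fy >= ref_period[1] & fy <= ref_period[2]]
  if (length(yrs) < 2)
    stopf("reference period %d-%d contains fewer than 2 full years",
          ref_period[1], ref_period[2], class = "coralproj_data_error")
  sub <- series[series$year %in% yrs, ]
  mm <- as.numeric(tapply(sub$sst_c, sub$month, mean))
  ms <- as.numeric(tapply(sub$sst_c, sub$month, stats::sd))
  clim_sd <- switch(sd_mode,
                    seasonal = stats::sd(mm),
                    interannual_warmest = ms[which.max(mm)])
  structure(list(monthly_mean = mm, monthly_sd = ms,
                 clim_max = max(mm), clim_min = min(mm), clim_sd = clim_sd,
                 ref_period = as.integer(ref_period), n_years = length(yrs),
                 sd_mode = sd_mode),
            class = "sst_climatology")
}

#' @export
print.sst_climatology <- function(x, ...) {
  cat(sprintf(paste0("<sst_climatology> ref %d-%d (%d yr): ",
                     "min %.2f, max %.2f, clim_sd %.2f degC\n"),
              x$ref_period[1], x$ref_period[2], x$n_years,
              x$clim_min, x$clim_max, x$clim_sd))
  invisible(x)
}

#' Bleaching threshold from a climatology
#'
#' The heat-stress ("bleaching") threshold is the maximum climatological
#' monthly mean temperature plus a fixed offset, 1 degC by convention.
#' Degree heating months accumulate above this temperature.
#'
#' @param clim An [monthly_climatology()] result.
#' @param offset Offset above the warmest climatological month, degrees C.
#' @return Threshold temperature, degrees C.
#' @export
bleaching_threshold <- function(clim, offset = 1) {
  stopifnot(inherits(clim, "sst_climatology"))
  clim$clim_max + offset
}
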