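#' Parameters for synthetic monthly SST generation
#'
#' Defines the statistical structure of a synthetic site: a 12-month
#' climatological cycle, per-calendar-month Gaussian variability, a secular
#' warming trend, and (for climate-model-style series) an additive bias and
#' a multiplicative distortion of the seasonal cycle. These are the knobs a
#' reconstruction-vs-model comparison needs: 20th-century climate-model
#' output can carry substantial mean biases and unrealistic seasonal
#' amplitudes relative to observations, and the downscaling stage exists to
#' remove exactly those artefacts.
#'
#' @param start_year First calendar year of the series.
#' @param n_years Number of years (>= 2).
#' @param monthly_clim 12 climatological monthly means, degrees C.
#' @param monthly_sigma 12 per-calendar-month standard deviations, degrees C
#'   (all > 0; may be 0 only for noise-free test series).
#' @param trend_per_century Linear warming trend, degrees C per 100 years,
#'   applied to the annual position `(year - start_year)/100`.
#' @param quad_per_century2 Optional quadratic acceleration term (degrees C
#'   per century squared); default 0.
#' @param bias Additive offset in degrees C (model-style series only).
#' @param seasonal_amp_factor Multiplier on the seasonal anomaly
#'   (model-style series only; > 0).
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return A `synth_sst_params` list.
#' @export
synth_sst_params <- function(start_year, n_years, monthly_clim, monthly_sigma,
                             trend_per_century = 0, quad_per_century2 = 0,
                             bias = 0, seasonal_amp_factor = 1, seed = NULL) {
  if (length(monthly_clim) != 12 || length(monthly_sigma) != 12)
    stopf("monthly_clim and monthly_sigma must have length 12",
          class = "coralproj_param_error")
  if (any(monthly_sigma < 0))
    stopf("monthly_sigma must be >= 0", class = "coralproj_param_error")
  if (seasonal_amp_factor <= 0)
    stopf("seasonal_amp_factor must be > 0", class = "coralproj_param_error")
  if (n_years < 2)
    stopf("n_years must be >= 2", class = "coralproj_param_error")
  structure(list(start_year = as.integer(start_year),
                 n_years = as.integer(n_years),
                 monthly_clim = as.numeric(monthly_clim),
                 monthly_sigma = as.numeric(monthly_sigma),
                 trend_per_century = trend_per_century,
                 quad_per_century2 = quad_per_century2,
                 bias = bias, seasonal_amp_factor = seasonal_amp_factor,
                 seed = seed),
            class = "synth_sst_params")
}

# shared core: climatology (possibly distorted) + trend + bias + noise.
# Noise is drawn in the same order regardless of bias/amp so that a
# model-style series with bias 0 and amp 1 is identical to its historic twin.
gen_sst_core <- function(p, bias, amp) {
  yrs <- rep(p$start_year + seq_len(p$n_years) - 1L, each = 12L)
  mos <- rep(1:12, p$n_years)
  t <- (yrs - p$start_year) / 100
  clim_mean <- mean(p$monthly_clim)
  cyc <- clim_mean + amp * (p$monthly_clim[mos] - clim_mean)
  if (!is.null(p$seed)) set.seed(p$seed)
  eps <- stats::rnorm(length(yrs), 0, p$monthly_sigma[mos])
  sst <- cyc + p$trend_per_century * t + p$quad_per_century2 * t^2 + bias + eps
  monthly_series(yrs, mos, sst)
}

#' Generate a synthetic observation-style monthly SST series
#'
#' Emulates a gridded historical reconstruction at a single site: the
#' stated monthly climatology plus a secular trend plus independent
#' per-calendar-month Gaussian noise. Monthly values are independent draws
#' (no interannual autocorrelation is emulated).
#'
#' @param params A [synth_sst_params()]; `bias` and `seasonal_amp_factor`
#'   are ignored for observation-style series.
#' @return A [monthly_series()] of length `12 * n_years`.
#' @examples
#' p <- synth_sst_params(1950, 50, 25 + 2 * cospi((1:12 - 8.5) / 6),
#'                       rep(0.5, 12), trend_per_century = 1, seed = 1)
#' gen_historic_sst(p)
#' @export
gen_historic_sst <- function(params) {
  stopifnot(inherits(params, "synth_sst_params"))
  gen_sst_core(params, bias = 0, amp = 1)
}

#' Generate a synthetic climate-model-style monthly SST series
#'
#' As [gen_historic_sst()], then adds the configured mean bias and
#' multiplies the seasonal anomaly by `seasonal_amp_factor`. With `bias = 0`
#' and `seasonal_amp_factor = 1` the output is identical to the historic
#' twin generated from the same seed.
#'
#' @inheritParams gen_historic_sst
#' @return A [monthly_series()].
#' @export
gen_model_sst <- function(params) {
  stopifnot(inherits(params, "synth_sst_params"))
  gen_sst_core(params, bias = params$bias, amp = params$seasonal_amp_factor)
}

#' Synthetic site presets
#'
#' Illustrative monthly climatologies and variabilities for four synthetic
#' sites named after the study locations of the Hawaiian Archipelago
#' analysis this package supports (JOH, OAH, FFS, MID, south to north).
#' The ordering is qualitative only -- MID is coldest with the largest
#' seasonal range and the largest monthly variability, JOH warmest with the
#' smallest -- these are fixtures for testing and examples, not extracted
#' reconstruction data.
#'
#' @param site One of `"JOH"`, `"OAH"`, `"FFS"`, `"MID"`.
#' @return A list with `monthly_clim` and `monthly_sigma` (each length 12).
#' @export
site_preset <- function(site = c("JOH", "OAH", "FFS", "MID")) {
  site <- match.arg(site)
  cfg <- switch(site,
    JOH = list(mean = 26.8, amp = 1.4, sig0 = 0.40, sig_amp = 0.10),
    OAH = list(mean = 25.8, amp = 1.9, sig0 = 0.45, sig_amp = 0.10),
    FFS = list(mean = 25.0, amp = 2.4, sig0 = 0.55, sig_amp = 0.15),
    MID = list(mean = 23.0, amp = 3.6, sig0 = 0.80, sig_amp = 0.25))
  m <- 1:12
  # warmest in late summer (month ~8.5), coolest in late winter
  list(monthly_clim = cfg$mean + cfg$amp * cospi((m - 8.5) / 6),
       monthly_sigma = cfg$sig0 + cfg$sig_amp * (1 + cospi((m - 2.5) / 6)) / 2)
}

#' Generate an annual atmospheric CO2 pathway
#'
#' Stand-in for a carbon-cycle model's atmospheric CO2 output. Produces one
#' mixing ratio per year, monotone between exact endpoints, with a linear,
#' exponential (constant growth rate) or logistic (S-shaped, symmetric
#' about the window midpoint) shape.
#'
#' @param start_year,end_year Calendar years (`end_year > start_year`).
#' @param start_ppm,end_ppm Endpoint mixing ratios, ppm (> 0); reproduced
#'   exactly.
#' @param shape `"linear"`, `"exponential"` or `"logistic"`.
#' @param logistic_rate Steepness of the logistic transition per year;
#'   default scales with the window so the transition spans it.
#' @return A `co2_pathway` data frame with columns `year`, `co2_ppm`.
#' @examples
#' gen_co2_pathway(2000, 2099, 370, 700, "logistic")
#' @export
gen_co2_pathway <- function(start_year, end_year, start_ppm, end_ppm,
                            shape = c("linear", "exponential", "logistic"),
                            logistic_rate = NULL) {
  shape <- match.arg(shape)
  if (end_year <= start_year)
    stopf("end_year must exceed start_year", class = "coralproj_param_error")
  if (start_ppm <= 0 || end_ppm <= 0)
    stopf("ppm values must be > 0", class = "coralproj_param_error")
  yrs <- start_year:end_year
  f <- (yrs - start_year) / (end_year - start_year)
  ppm <- switch(shape,
    linear = start_ppm + f * (end_ppm - start_ppm),
    exponential = start_ppm * (end_ppm / start_ppm)^f,
    logistic = {
      k <- logistic_rate %||% (10 / (end_year - start_year))
      mid <- (start_year + end_year) / 2
      raw <- stats::plogis(k * (yrs - mid))
      # rescale so endpoints are exact; symmetry keeps the midpoint at the
      # arithmetic mean of the endpoints
      u <- (raw - raw[1]) / (raw[length(raw)] - raw[1])
      start_ppm + u * (end_ppm - start_ppm)
    })
  structure(data.frame(year = as.integer(yrs), co2_ppm = ppm),
            class = c("co2_pathway", "data.frame"))
}

#' Default century-scale CO2 pathway preset
#'
#' A logistic rise from 370 to 700 ppm over 2000-2099, emulating a
#' mid-range (A1B-like) emissions trajectory. With the packaged aragonite
#' table this takes surface-ocean aragonite saturation from about 3.8 at
#' the start of the century to about 2.5 at its end.
#'
#' @return A `co2_pathway` data frame.
#' @export
co2_preset_a1b <- function() gen_co2_pathway(2000, 2099, 370, 700, "logistic")

#' Read / write an annual CO2 pathway CSV
#'
#' Dialect: header `year,co2_ppm`.
#' @param path CSV path.
#' @return `read_co2`: a `co2_pathway`; `write_co2`: `path` invisibly.
#' @export
read_co2 <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("year", "co2_ppm") %in% names(df)))
    stopf("CO2 CSV needs columns year, co2_ppm", class = "coralproj_format_error")
  if (any(df$co2_ppm <= 0))
    stopf("CO2 mixing ratios must be > 0", class = "coralproj_format_error")
  df <- df[order(df$year), ]
  rownames(df) <- NULL
  structure(df, class = c("co2_pathway", "data.frame"))
}

#' @rdname read_co2
#' @param x A `co2_pathway`.
#' @export
write_co2 <- function(x, path) {
  utils::write.csv(as.data.frame(x)[, c("year", "co2_ppm")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Generate synthetic heat-stress mortality observations
#'
#' Draws degree-heating-month exposures uniformly on `[0, dhm_max]` and
#' maps them through a known zero-intercept quadratic plus Gaussian noise,
#' clipped to `[0, 1]`. Used as ground-truthed fixtures for the
#' mortality-curve fit.
#'
#' @param a,b Quadratic and linear coefficients of the true curve
#'   (mortality fraction = `a * DHM^2 + b * DHM`).
#' @param noise_sd Gaussian noise SD on the mortality fraction.
#' @param n Number of observations (>= 3).
#' @param dhm_max Upper bound of the DHM design range, degC-months.
#' @param seed Integer seed.
#' @return Data frame with columns `dhm`, `mortality_fraction`.
#' @export
gen_mortality_observations <- function(a, b, noise_sd = 0, n = 20,
                                       dhm_max = 10, seed = NULL) {
  if (n < 3) stopf("need n >= 3 observations", class = "coralproj_param_error")
  if (!is.null(seed)) set.seed(seed)
  dhm <- stats::runif(n, 0, dhm_max)
  mort <- clip01(a * dhm^2 + b * dhm + stats::rnorm(n, 0, noise_sd))
  data.frame(dhm = dhm, mortality_fraction = mort)
}
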