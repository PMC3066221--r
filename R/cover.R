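#' Parameter bundle for the annual cover model
#'
#' Collects everything the annual cover update needs: the site growth
#' curve, the DHM-mortality curve, the bleaching-threshold policy, the
#' baseline turnover scale, the aragonite sensitivity, and flags enabling
#' the acidification and episodic-mortality modules.
#'
#' @param growth_curve A [fit_growth_curve()] result.
#' @param mortality_curve A [fit_mortality_curve()] result.
#' @param threshold_policy A [threshold_policy()].
#' @param baseline_turnover Gross growth-rate scale at equilibrium, per
#'   year (> 0); default 0.05, i.e. decadal-scale recovery potential.
#' @param omega_sensitivity Per-Omega-unit calcification sensitivity in
#'   [0, 0.45]; see [calcification_factor()].
#' @param use_co2 Enable the acidification module.
#' @param use_episodic Enable episodic heat-stress mortality.
#' @param mortality_order `"growth_first"` (default) applies the year's
#'   growth increment before the episodic cull; `"mortality_first"`
#'   reverses the order.
#' @param growth_floor Lower clamp on relative growth; default -1.
#' @return A `cover_params` object.
#' @export
cover_params <- function(growth_curve, mortality_curve, threshold_policy,
                         baseline_turnover = 0.05, omega_sensitivity = 0.3,
                         use_co2 = TRUE, use_episodic = TRUE,
                         mortality_order = c("growth_first", "mortality_first"),
                         growth_floor = -1) {
  stopifnot(inherits(growth_curve, "growth_curve"),
            inherits(mortality_curve, "mortality_curve"),
            inherits(threshold_policy, "threshold_policy"))
  if (baseline_turnover <= 0)
    stopf("baseline_turnover must be > 0", class = "coralproj_param_error")
  structure(list(growth_curve = growth_curve,
                 mortality_curve = mortality_curve,
                 threshold_policy = threshold_policy,
                 baseline_turnover = baseline_turnover,
                 omega_sensitivity = omega_sensitivity,
                 use_co2 = use_co2, use_episodic = use_episodic,
                 mortality_order = match.arg(mortality_order),
                 growth_floor = growth_floor),
            class = "cover_params")
}

#' Calibrate the background mortality rate at start-year equilibrium
#'
#' Long-term growth and mortality are assumed balanced at the start of the
#' run: the background mortality rate is set to exactly offset gross
#' growth under start-year climate, so a stationary climate holds cover
#' flat at 1.
#'
#' @param params A [cover_params()].
#' @param t_ref Start-year annual mean temperature, degC.
#' @param omega_ref Start-year aragonite saturation (only used when the
#'   acidification module is enabled; the start-year calcification factor
#'   relative to itself is 1).
#' @return Background mortality rate `m0`, per year.
#' @export
equilibrium_calibrate <- function(params, t_ref, omega_ref = NULL) {
  stopifnot(inherits(params, "cover_params"))
  g0 <- relative_growth(params$growth_curve, t_ref, params$growth_floor)
  if (g0 <= 0)
    stopf("infeasible equilibrium: relative growth %.3f <= 0 at start-year mean %.2f degC",
          g0, t_ref, class = "coralproj_infeasible_equilibrium")
  a0 <- if (params$use_co2 && !is.null(omega_ref))
    calcification_factor(params$omega_sensitivity, omega_ref, omega_ref)
  else 1
  params$baseline_turnover * g0 * a0
}

#' One annual cover update
#'
#' Multiplicative annual balance: cover grows by the temperature- and
#' saturation-scaled gross rate less the calibrated background mortality,
#' then (by default) the episodic cull removes a fraction of what remains:
#' `cover' = cover * (1 + tau * G(T) * A(Omega) - m0) * (1 - M(DHM))`,
#' floored at 0. There is no ceiling: relative cover may exceed 1 where
#' warming moves a site toward its growth optimum.
#'
#' @param cover Current relative cover (>= 0).
#' @param t_annual_mean Annual mean temperature, degC.
#' @param dhm Annual degree heating months.
#' @param omega_t Current aragonite saturation (or `NULL` when the
#'   acidification module is off).
#' @param params A [cover_params()].
#' @param m0 Calibrated background mortality rate.
#' @param omega_ref Start-year aragonite saturation.
#' @return Updated relative cover.
#' @export
step_cover <- function(cover, t_annual_mean, dhm, omega_t, params, m0,
                       omega_ref = NULL) {
  g <- relative_growth(params$growth_curve, t_annual_mean, params$growth_floor)
  a <- if (params$use_co2 && !is.null(omega_t))
    calcification_factor(params$omega_sensitivity, omega_ref, omega_t)
  else 1
  m_epi <- if (params$use_episodic)
    episodic_mortality(params$mortality_curve, dhm)
  else 0
  grow <- function(x) x * (1 + params$baseline_turnover * g * a - m0)
  cull <- function(x) x * (1 - m_epi)
  out <- if (params$mortality_order == "growth_first")
    cull(grow(cover))
  else grow(cull(cover))
  max(0, out)
}

#' Run an annual cover trajectory
#'
#' Integrates relative coral cover over the years of a monthly SST series:
#' for each year the adapted bleaching threshold, the annual DHM, the
#' annual mean temperature and (when enabled) the aragonite saturation are
#' computed, and the cover update applied. Cover is 1 at the start year by
#' definition; the first year's climate defines the equilibrium reference.
#'
#' @param sst A [monthly_series()] of complete years.
#' @param co2 A `co2_pathway` covering the same years (required when the
#'   acidification module is enabled).
#' @param params A [cover_params()].
#' @param arag An [build_aragonite_table()] result (required when the
#'   acidification module is enabled).
#' @return A `cover_trajectory` data frame: `year`, `cover_rel`, `dhm`,
#'   `episodic_mortality`; attributes `m0`, `t_ref`, `omega_ref`, `events`
#'   (the rows with positive DHM) and `params`.
#' @export
run_trajectory <- function(sst, co2 = NULL, params, arag = NULL) {
  validate_monthly_series(sst)
  stopifnot(inherits(params, "cover_params"))
  yrs <- full_years(sst)
  if (length(yrs) < 2)
    stopf("need at least 2 full years of SST", class = "coralproj_data_error")
  if (params$use_co2) {
    if (is.null(co2) || is.null(arag))
      stopf("acidification module enabled: co2 pathway and aragonite table required",
            class = "coralproj_param_error")
    if (!all(yrs %in% co2$year))
      stopf("CO2 pathway does not cover years %d-%d", min(yrs), max(yrs),
            class = "coralproj_data_error")
  }
  mat <- matrix(sst$sst_c[sst$year %in% yrs], nrow = 12)  # month x year
  tbar <- colMeans(mat)
  t_ref <- tbar[1]
  omega_ref <- if (params$use_co2)
    omega_a(arag, t_ref, co2$co2_ppm[match(yrs[1], co2$year)])
  else NULL
  m0 <- equilibrium_calibrate(params, t_ref, omega_ref)

  n <- length(yrs)
  cover <- numeric(n)
  dhm <- numeric(n)
  mepi <- numeric(n)
  cover[1] <- 1
  thr <- adapted_threshold(params$threshold_policy, yrs)
  for (i in seq_len(n)) {
    dhm[i] <- annual_dhm(mat[, i], thr[i])
    mepi[i] <- if (params$use_episodic)
      episodic_mortality(params$mortality_curve, dhm[i])
    else 0
    if (i == 1) next
    omega_t <- if (params$use_co2)
      omega_a(arag, tbar[i], co2$co2_ppm[match(yrs[i], co2$year)])
    else NULL
    cover[i] <- step_cover(cover[i - 1], tbar[i], dhm[i], omega_t, params,
                           m0, omega_ref)
  }
  out <- data.frame(year = yrs, cover_rel = cover, dhm = dhm,
                    episodic_mortality = mepi)
  structure(out, class = c("cover_trajectory", "data.frame"),
            m0 = m0, t_ref = t_ref, omega_ref = omega_ref,
            events = out[out$dhm > 0, , drop = FALSE], params = params)
}

#' @export
print.cover_trajectory <- function(x, ...) {
  cat(sprintf(paste0("<cover_trajectory> %d-%d: end cover %.3f, ",
                     "%d years with DHM > 0\n"),
              x$year[1], x$year[nrow(x)], x$cover_rel[nrow(x)],
              sum(x$dhm > 0)))
  invisible(x)
}

#' @export
plot.cover_trajectory <- function(x, ...) {
  graphics::plot(x$year, x$cover_rel, type = "l", xlab = "year",
                 ylab = "relative cover", ...)
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}

#' Write a cover trajectory to CSV
#'
#' Columns: `year,cover_rel,dhm,episodic_mortality`.
#' @param x A `cover_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
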