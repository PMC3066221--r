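#' Normalized variance of a set of summary values
#'
#' The sensitivity metric: population variance of the values divided by
#' their mean. Undefined for zero mean.
#'
#' @param values Numeric vector.
#' @return Dimensionless normalized variance.
#' @examples
#' normalized_variance(c(1, 3))  # population variance 1 / mean 2 = 0.5
#' @export
normalized_variance <- function(values) {
  if (length(values) < 1 || anyNA(values))
    stopf("values must be non-empty and complete", class = "coralproj_param_error")
  m <- mean(values)
  if (m == 0)
    stopf("normalized variance undefined for zero mean",
          class = "coralproj_undefined_statistic")
  v <- mean((values - m)^2)  # population variance
  v / m
}

#' Scenario bundle for sensitivity runs
#'
#' Everything a sensitivity sweep holds fixed: site climatology, the
#' multi-model trend and historic anomaly distributions driving the Monte
#' Carlo SST generator, the CO2 pathway, the aragonite table, and the three
#' candidate DHM-mortality curves.
#'
#' @param clim Site [monthly_climatology()].
#' @param trend A [multi_model_trend()] result.
#' @param distributions A [monthly_anomaly_distributions()] result.
#' @param co2 A `co2_pathway`.
#' @param arag An [build_aragonite_table()] result.
#' @param mortality_curves Named list of [fit_mortality_curve()] results;
#'   must include `"all_data"`, `"mhi_nwhi"`, `"carib"`. Defaults to fits
#'   of the packaged observation tables.
#' @param start_year Projection start year; default 2000.
#' @param baseline_turnover Passed to [cover_params()]; default 0.05.
#' @return A `sensitivity_config` list.
#' @export
sensitivity_config <- function(clim, trend, distributions, co2, arag,
                               mortality_curves = NULL, start_year = 2000,
                               baseline_turnover = 0.05) {
  if (is.null(mortality_curves))
    mortality_curves <- lapply(
      stats::setNames(nm = c("all_data", "mhi_nwhi", "carib")),
      function(nm) fit_mortality_curve(mortality_fixture(nm)))
  stopifnot(inherits(clim, "sst_climatology"),
            all(c("all_data", "mhi_nwhi", "carib") %in%
                  names(mortality_curves)))
  structure(list(clim = clim, trend = trend, distributions = distributions,
                 co2 = co2, arag = arag,
                 mortality_curves = mortality_curves,
                 start_year = start_year,
                 baseline_turnover = baseline_turnover),
            class = "sensitivity_config")
}

default_levels <- function(parameter) {
  switch(parameter,
         adaptation = seq(0, 2, by = 0.5),
         omega_coeff = c(0, 0.15, 0.3, 0.45),
         dhm_curve = c("all_data", "mhi_nwhi", "carib"),
         growth_curve = 1:5)  # five perturbation draws
}

# cover_params for one level of one swept parameter, all else at the
# less-resilient baseline (adaptation 0, s = 0.3, all-data curve)
level_params <- function(parameter, level, config, seed) {
  base_thr <- bleaching_threshold(config$clim)
  gc <- fit_growth_curve(config$clim)
  mc <- config$mortality_curves[["all_data"]]
  adapt <- 0
  s <- 0.3
  switch(parameter,
         adaptation = adapt <- level,
         omega_coeff = s <- level,
         dhm_curve = mc <- config$mortality_curves[[level]],
         growth_curve = gc <- perturb_growth_curve(
           config$clim, seed = derive_seed(seed, 900000 + level)))
  cover_params(gc, mc,
               threshold_policy(base_thr, adapt, config$start_year),
               baseline_turnover = config$baseline_turnover,
               omega_sensitivity = s, use_co2 = TRUE, use_episodic = TRUE)
}

#' Parameter sensitivity sweep with normalized-variance summary
#'
#' Sweeps one of the four salient model parameters across its levels while
#' holding everything else at the less-resilient baseline, runs a Monte
#' Carlo cover ensemble per level with common random numbers (the same SST
#' member substreams at every level), and summarizes sensitivity as the
#' normalized variance of the per-level ensemble means -- and, separately,
#' of the per-level member standard deviations -- at the evaluation years.
#'
#' Default level grids: threshold adaptation 0 to 2 degC/century in 0.5
#' steps; aragonite sensitivity 0 to 0.45; the three packaged DHM-mortality
#' curves; five random growth-curve perturbations. Members whose absolute
#' cover change exceeds 500\% anywhere are flagged unstable; summaries are
#' reported both with and without them.
#'
#' @param parameter One of `"adaptation"`, `"omega_coeff"`, `"dhm_curve"`,
#'   `"growth_curve"`.
#' @param config A [sensitivity_config()].
#' @param levels Optional level grid; defaults per parameter as above. A
#'   single level yields zero normalized variance by construction.
#' @param n_runs Approximate total ensemble members across the sweep;
#'   split evenly over levels. Default 200.
#' @param seed Integer seed; the sweep is fully reproducible from
#'   `(seed, config)`.
#' @param eval_years Evaluation years; default 2050 and 2099.
#' @return A `sensitivity_report`: per evaluation year the normalized
#'   variance of level means and of level SDs (with and without unstable
#'   members), plus per-level summaries, the unstable-member rate and run
#'   counts.
#' @export
run_sensitivity <- function(parameter = c("adaptation", "omega_coeff",
                                          "dhm_curve", "growth_curve"),
                            config, levels = NULL, n_runs = 200, seed = 1,
                            eval_years = c(2050, 2099)) {
  parameter <- match.arg(parameter)
  stopifnot(inherits(config, "sensitivity_config"))
  levels <- levels %||% default_levels(parameter)
  if (length(levels) < 1)
    stopf("need >= 1 level", class = "coralproj_param_error")
  runs_per_level <- max(2L, as.integer(round(n_runs / length(levels))))

  per_level <- vector("list", length(levels))
  for (li in seq_along(levels)) {
    params <- level_params(parameter, levels[[li]], config, seed)
    ens <- run_mc_ensemble(config$trend, config$distributions, config$co2,
                           params, config$arag, n = runs_per_level,
                           seed = seed, eval_years = eval_years)
    unstable <- apply(abs(ens$member_matrix - 1) > 5, 2, any)
    per_level[[li]] <- list(
      level = levels[[li]],
      n = ens$n_members,
      n_unstable = sum(unstable),
      stats = lapply(eval_years, function(y) {
        v <- ens$member_matrix[match(y, ens$years), ]
        vs <- v[!unstable]
        list(year = y, mean = mean(v), sd = stats::sd(v),
             mean_stable = if (length(vs) >= 2) mean(vs) else NA_real_,
             sd_stable = if (length(vs) >= 2) stats::sd(vs) else NA_real_)
      }))
  }

  pull <- function(field, j) vapply(per_level, function(l) l$stats[[j]][[field]],
                                    numeric(1))
  summary_tab <- do.call(rbind, lapply(seq_along(eval_years), function(j) {
    means <- pull("mean", j); sds <- pull("sd", j)
    means_s <- pull("mean_stable", j); sds_s <- pull("sd_stable", j)
    data.frame(
      year = eval_years[j],
      nv_mean = normalized_variance(means),
      nv_sd = normalized_variance(sds),
      nv_mean_stable = if (anyNA(means_s)) NA_real_
                       else normalized_variance(means_s),
      nv_sd_stable = if (anyNA(sds_s)) NA_real_ else normalized_variance(sds_s))
  }))

  n_total <- sum(vapply(per_level, `[[`, numeric(1), "n"))
  structure(list(parameter = parameter, levels = levels,
                 runs_per_level = runs_per_level, n_total = n_total,
                 unstable_rate = sum(vapply(per_level, `[[`, numeric(1),
                                            "n_unstable")) / n_total,
                 summary = summary_tab, per_level = per_level,
                 eval_years = eval_years, seed = seed),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("<sensitivity_report> parameter %s: %d levels x %d runs (unstable rate %.1f%%)\n",
              x$parameter, length(x$levels), x$runs_per_level,
              100 * x$unstable_rate))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
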