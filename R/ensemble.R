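#' Build an ensemble result from member trajectories
#'
#' Internal constructor shared by both ensemble methods: aligns member
#' trajectories on their common years, computes the pointwise ensemble
#' mean, and fits a normal distribution (sample mean / SD) to the member
#' cover values at each evaluation year.
#'
#' @noRd
make_ensemble <- function(trajectories, method, eval_years, excluded = NULL,
                          seed = NULL) {
  if (length(trajectories) < 2)
    stopf("need >= 2 ensemble members", class = "coralproj_param_error")
  yrs <- trajectories[[1]]$year
  for (tr in trajectories)
    if (!identical(tr$year, yrs))
      stopf("member trajectories do not share a common calendar",
            class = "coralproj_data_error")
  mat <- vapply(trajectories, function(tr) tr$cover_rel, numeric(length(yrs)))
  eval_years <- eval_years[eval_years %in% yrs]
  fits <- lapply(eval_years, function(y) {
    v <- mat[match(y, yrs), ]
    list(year = y, mean = mean(v), sd = stats::sd(v), n = length(v))
  })
  structure(list(members = trajectories,
                 years = yrs,
                 member_matrix = mat,
                 mean_trajectory = data.frame(year = yrs,
                                              cover_rel = rowMeans(mat)),
                 normal_fits = fits,
                 eval_years = eval_years,
                 method = method,
                 n_members = length(trajectories),
                 excluded = excluded %||% list(),
                 seed = seed),
            class = "coral_ensemble")
}

#' Individual-model ensemble projection
#'
#' Method 1: each downscaled climate-model series that passed selection is
#' run through the cover model once; the member trajectories are averaged
#' into a multi-model mean expressing the most likely net outcome. Members
#' whose run fails with an infeasible-curve or infeasible-equilibrium
#' error are excluded and logged, not fatal.
#'
#' @param members Named list of downscaled [monthly_series()] objects
#'   (>= 2).
#' @param co2 A `co2_pathway` (when the acidification module is enabled).
#' @param params A [cover_params()].
#' @param arag An aragonite table (when the acidification module is
#'   enabled).
#' @param eval_years Years at which normal fits of member outcomes are
#'   computed; default 2050 and 2099.
#' @return A `coral_ensemble` object.
#' @export
run_individual_ensemble <- function(members, co2 = NULL, params, arag = NULL,
                                    eval_years = c(2050, 2099)) {
  if (length(members) < 2)
    stopf("need >= 2 members", class = "coralproj_param_error")
  ids <- names(members) %||% as.character(seq_along(members))
  excluded <- list()
  trajectories <- list()
  for (i in seq_along(members)) {
    tr <- tryCatch(run_trajectory(members[[i]], co2, params, arag),
                   coralproj_infeasible_curve = function(e) e,
                   coralproj_infeasible_equilibrium = function(e) e)
    if (inherits(tr, "condition"))
      excluded[[ids[i]]] <- conditionMessage(tr)
    else trajectories[[ids[i]]] <- tr
  }
  if (length(trajectories) < 2)
    stopf("fewer than 2 members survived (excluded: %d)", length(excluded),
          class = "coralproj_data_error")
  make_ensemble(trajectories, "individual", eval_years, excluded)
}

#' Monte Carlo ensemble projection
#'
#' Method 2: simulates `n` SST realizations about the low-pass multi-model
#' trend using the historic per-month anomaly distributions, runs each
#' through the cover model, and aggregates as in
#' [run_individual_ensemble()]. Default 500 members; the spread of
#' outcomes is essentially converged there.
#'
#' @param trend A [multi_model_trend()] result.
#' @param distributions A [monthly_anomaly_distributions()] result.
#' @inheritParams run_individual_ensemble
#' @param n Number of Monte Carlo members (>= 2); default 500.
#' @param seed Integer seed; member `k` derives the substream `(seed, k)`,
#'   so the full result is reproducible.
#' @return A `coral_ensemble` object.
#' @export
run_mc_ensemble <- function(trend, distributions, co2 = NULL, params,
                            arag = NULL, n = 500, seed = NULL,
                            eval_years = c(2050, 2099)) {
  if (n < 2) stopf("need n >= 2", class = "coralproj_param_error")
  sims <- simulate_sst(trend, distributions, n_sims = n, seed = seed)
  names(sims) <- sprintf("mc%03d", seq_len(n))
  excluded <- list()
  trajectories <- list()
  for (id in names(sims)) {
    tr <- tryCatch(run_trajectory(sims[[id]], co2, params, arag),
                   coralproj_infeasible_curve = function(e) e,
                   coralproj_infeasible_equilibrium = function(e) e)
    if (inherits(tr, "condition")) excluded[[id]] <- conditionMessage(tr)
    else trajectories[[id]] <- tr
  }
  if (length(trajectories) < 2)
    stopf("fewer than 2 members survived", class = "coralproj_data_error")
  make_ensemble(trajectories, "monte_carlo", eval_years, excluded, seed)
}

#' Probability of a cover decline by a given year
#'
#' Fits a normal distribution to the member cover values at the requested
#' year and returns the fitted probability that cover lies below
#' `1 - decline_frac`. With zero member variance the probability
#' degenerates to 0 or 1 by the position of the mean.
#'
#' @param result A `coral_ensemble`.
#' @param year Evaluation year (must be in the ensemble calendar).
#' @param decline_frac Decline relative to start cover, e.g. 0.5 for a
#'   >50\% decrease, 0.99 for loss of viable cover.
#' @return Probability in [0, 1].
#' @examples
#' # members with mean 0.4 and SD 0.2 at the evaluation year give
#' # P(>50% decline) = pnorm((0.5 - 0.4) / 0.2) = 0.6915
#' @export
decline_probability <- function(result, year = 2099, decline_frac = 0.99) {
  stopifnot(inherits(result, "coral_ensemble"))
  if (!(year %in% result$years))
    stopf("year %d not in ensemble calendar", year,
          class = "coralproj_param_error")
  v <- result$member_matrix[match(year, result$years), ]
  if (length(v) < 2)
    stopf("need >= 2 members", class = "coralproj_param_error")
  thr <- 1 - decline_frac
  s <- stats::sd(v)
  if (s == 0) return(as.numeric(mean(v) < thr))
  stats::pnorm(thr, mean(v), s)
}

#' @export
print.coral_ensemble <- function(x, ...) {
  cat(sprintf("<coral_ensemble> method %s, %d members, %d-%d",
              x$method, x$n_members, x$years[1], x$years[length(x$years)]))
  if (length(x$excluded)) cat(sprintf(" (%d excluded)", length(x$excluded)))
  cat("\n")
  for (f in x$normal_fits)
    cat(sprintf("  %d: mean cover %.3f, SD %.3f (n=%d)\n",
                f$year, f$mean, f$sd, f$n))
  invisible(x)
}

#' @export
summary.coral_ensemble <- function(object, decline_fracs = c(0.5, 0.99), ...) {
  rows <- do.call(rbind, lapply(object$eval_years, function(y) {
    data.frame(year = y,
               mean_cover = object$normal_fits[[
                 match(y, object$eval_years)]]$mean,
               sd_cover = object$normal_fits[[match(y, object$eval_years)]]$sd,
               t(vapply(decline_fracs, function(f)
                 decline_probability(object, y, f), numeric(1))))
  }))
  names(rows)[-(1:3)] <- sprintf("p_decline_%g", decline_fracs * 100)
  rows
}

#' @export
plot.coral_ensemble <- function(x, max_members = 50, ...) {
  graphics::matplot(x$years, x$member_matrix[, seq_len(min(max_members,
                                                           x$n_members))],
                    type = "l", lty = 1, col = "grey70", xlab = "year",
                    ylab = "relative cover", ...)
  graphics::lines(x$mean_trajectory$year, x$mean_trajectory$cover_rel,
                  lwd = 2)
  invisible(x)
}

#' Named model-resilience parameter presets
#'
#' The run configurations used to bound future outcomes:
#' \describe{
#'   \item{less_resilient}{no threshold adaptation, aragonite sensitivity
#'     0.3 -- corals neither acclimatize nor escape the calcification
#'     penalty.}
#'   \item{more_resilient}{threshold adaptation 1 degC per century,
#'     acidification module off.}
#'   \item{no_bleaching}{episodic-mortality module off (otherwise as
#'     less_resilient); isolates the growth response to warming.}
#'   \item{validation_20c}{the less_resilient parameterization, intended
#'     for 20th-century hindcast windows.}
#' }
#'
#' @param name Preset name.
#' @param clim Site [monthly_climatology()] (defines growth curve anchors
#'   and base threshold).
#' @param mortality_curve A [fit_mortality_curve()] result.
#' @param start_year Projection start year; default 2000 (1900 for
#'   `validation_20c`).
#' @param baseline_turnover Passed through to [cover_params()].
#' @return A [cover_params()] object.
#' @export
case_preset <- function(name = c("less_resilient", "more_resilient",
                                 "no_bleaching", "validation_20c"),
                        clim, mortality_curve, start_year = NULL,
                        baseline_turnover = 0.05) {
  name <- match.arg(name)
  start_year <- start_year %||% if (name == "validation_20c") 1900 else 2000
  gc <- fit_growth_curve(clim)
  base_thr <- bleaching_threshold(clim)
  switch(name,
    less_resilient = ,
    validation_20c = cover_params(
      gc, mortality_curve, threshold_policy(base_thr, 0, start_year),
      baseline_turnover = baseline_turnover, omega_sensitivity = 0.3,
      use_co2 = TRUE, use_episodic = TRUE),
    more_resilient = cover_params(
      gc, mortality_curve, threshold_policy(base_thr, 1, start_year),
      baseline_turnover = baseline_turnover, omega_sensitivity = 0,
      use_co2 = FALSE, use_episodic = TRUE),
    no_bleaching = cover_params(
      gc, mortality_curve, threshold_policy(base_thr, 0, start_year),
      baseline_turnover = baseline_turnover, omega_sensitivity = 0.3,
      use_co2 = TRUE, use_episodic = FALSE))
}
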