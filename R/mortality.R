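#' Annual degree heating months
#'
#' The annual heat-stress exposure: the sum, over the 12 months of a
#' calendar year, of monthly temperature exceedances above the bleaching
#' threshold (warmest climatological monthly mean + 1 degC by default).
#' Two months each 2 degC above the threshold give 4 DHM.
#'
#' @param sst_months Exactly 12 monthly temperatures, degC.
#' @param threshold Bleaching threshold, degC (see [bleaching_threshold()]).
#' @return DHM in degC-months.
#' @examples
#' annual_dhm(c(rep(26, 10), 30, 30), threshold = 28)  # 4
#' @export
annual_dhm <- function(sst_months, threshold) {
  if (length(sst_months) != 12)
    stopf("annual_dhm needs exactly 12 monthly values, got %d",
          length(sst_months), class = "coralproj_param_error")
  sum(pmax(0, sst_months - threshold))
}

#' Fit the quadratic DHM-mortality curve
#'
#' Least-squares quadratic through the origin relating annual degree
#' heating months to the fraction of colonies lost in the associated
#' bleaching event: `mortality = a * DHM^2 + b * DHM`. The zero intercept
#' encodes no episodic mortality in stress-free years; a free-intercept
#' variant is available for fit comparison only.
#'
#' @param observations Data frame with columns `dhm` and
#'   `mortality_fraction` (>= 2 rows with distinct DHM).
#' @param intercept Fit a free intercept instead (comparison only).
#' @return A `mortality_curve`: list with coefficients `a` (quadratic),
#'   `b` (linear), optional `c0` (intercept), `rss`, `n`.
#' @export
fit_mortality_curve <- function(observations, intercept = FALSE) {
  obs <- as.data.frame(observations)
  if (!all(c("dhm", "mortality_fraction") %in% names(obs)))
    stopf("observations need columns dhm, mortality_fraction",
          class = "coralproj_format_error")
  if (nrow(obs) < 2 || length(unique(obs$dhm)) < 2)
    stopf("need >= 2 observations with distinct DHM",
          class = "coralproj_degenerate_error")
  fit <- if (intercept)
    stats::lm(mortality_fraction ~ I(dhm^2) + dhm, data = obs)
  else
    stats::lm(mortality_fraction ~ 0 + I(dhm^2) + dhm, data = obs)
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stopf("degenerate design: quadratic fit is rank-deficient",
          class = "coralproj_degenerate_error")
  structure(list(a = unname(cf[["I(dhm^2)"]]), b = unname(cf[["dhm"]]),
                 c0 = if (intercept) unname(cf[["(Intercept)"]]) else 0,
                 rss = sum(stats::resid(fit)^2), n = nrow(obs)),
            class = "mortality_curve")
}

#' Evaluate episodic mortality for a DHM exposure
#'
#' @param curve A [fit_mortality_curve()] result.
#' @param dhm Degree heating months (>= 0), vectorized.
#' @return Mortality fraction(s), clipped to [0, 1].
#' @export
episodic_mortality <- function(curve, dhm) {
  stopifnot(inherits(curve, "mortality_curve"))
  if (any(dhm < 0))
    stopf("dhm must be >= 0", class = "coralproj_param_error")
  clip01(curve$a * dhm^2 + curve$b * dhm + curve$c0)
}

#' @export
print.mortality_curve <- function(x, ...) {
  cat(sprintf("<mortality_curve> mortality = %.4g*DHM^2 + %.4g*DHM (n=%d, RSS=%.3g)\n",
              x$a, x$b, x$n, x$rss))
  invisible(x)
}

#' @export
coef.mortality_curve <- function(object, ...) {
  c(a = object$a, b = object$b)
}

#' @export
predict.mortality_curve <- function(object, dhm, ...) {
  episodic_mortality(object, dhm)
}

#' Packaged heat-stress mortality observation tables
#'
#' Three DHM/mortality observation tables mirroring the usual groupings of
#' documented bleaching events (Hawaiian events only, Caribbean 2005 only,
#' and all pooled). The published event observations are not tabulated
#' anywhere in machine-readable form, so these tables are synthesized to
#' match the described curve ordering (the Caribbean curve steepest, the
#' Hawaiian mildest) and are marked synthetic; they are fixtures, not
#' authoritative observations.
#'
#' @param name One of `"all_data"`, `"mhi_nwhi"`, `"carib"`.
#' @return Data frame with columns `dhm`, `mortality_fraction`,
#'   `source_label`.
#' @export
mortality_fixture <- function(name = c("all_data", "mhi_nwhi", "carib")) {
  name <- match.arg(name)
  path <- system.file("extdata",
                      sprintf("dhm_mortality_synthetic_%s.csv", name),
                      package = "coralproj", mustWork = TRUE)
  utils::read.csv(path)
}

#' Bleaching-threshold adaptation policy
#'
#' Encodes a linear drift of the episodic-mortality threshold, standing in
#' for coral acclimatization to heat stress: the threshold rises by
#' `adaptation_rate` degC per century from its base value. The drift
#' applies to the episodic-mortality threshold only, never to the growth
#' curve.
#'
#' @param base_threshold Base bleaching threshold, degC.
#' @param adaptation_rate Linear threshold increase, degC per century, in
#'   [0, 2].
#' @param start_year Year at which the base value applies.
#' @return A `threshold_policy` object.
#' @export
threshold_policy <- function(base_threshold, adaptation_rate = 0,
                             start_year = 2000) {
  if (adaptation_rate < 0 || adaptation_rate > 2)
    stopf("adaptation_rate must lie in [0, 2] degC per century",
          class = "coralproj_param_error")
  structure(list(base_threshold = base_threshold,
                 adaptation_rate = adaptation_rate,
                 start_year = as.integer(start_year)),
            class = "threshold_policy")
}

#' Adapted bleaching threshold at a given year
#'
#' @param policy A [threshold_policy()].
#' @param year Calendar year(s) at or after the policy start year.
#' @return Threshold temperature(s), degC.
#' @examples
#' pol <- threshold_policy(29, adaptation_rate = 1, start_year = 2000)
#' adapted_threshold(pol, 2100)  # 30
#' @export
adapted_threshold <- function(policy, year) {
  stopifnot(inherits(policy, "threshold_policy"))
  if (any(year < policy$start_year))
    stopf("year precedes policy start year %d", policy$start_year,
          class = "coralproj_param_error")
  policy$base_threshold +
    policy$adaptation_rate * (year - policy$start_year) / 100
}
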