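#' Cubic temperature-growth curve from anchor temperatures
#'
#' Solves the cubic relative-growth polynomial from its four defining
#' constraints: zero net growth at `t_zero_low` and `t_zero_high`, a
#' stationary point at `t_gmax`, and unit relative growth at `t_gmax`
#' (the peak is normalised to 1; absolute rate enters the cover model
#' through the baseline turnover). Requires
#' `t_zero_low < t_gmax < t_zero_high`; otherwise an infeasible-curve
#' error (condition class `coralproj_infeasible_curve`) is thrown -- this
#' is the instability that perturbed curves can run into.
#'
#' @param t_zero_low,t_zero_high Temperatures of zero net growth, degC.
#' @param t_gmax Temperature of maximum growth, degC.
#' @return A `growth_curve` object (coefficients in increasing powers of
#'   temperature, plus the anchors).
#' @export
growth_curve_from_anchors <- function(t_zero_low, t_gmax, t_zero_high) {
  if (!(t_zero_low < t_gmax && t_gmax < t_zero_high))
    stop(errorCondition(
      sprintf("infeasible growth curve: need t_zero_low < t_gmax < t_zero_high (got %.3f, %.3f, %.3f)",
              t_zero_low, t_gmax, t_zero_high),
      class = c("coralproj_infeasible_curve", "coralproj_error"),
      anchors = c(t_zero_low = t_zero_low, t_gmax = t_gmax,
                  t_zero_high = t_zero_high)))
  A <- rbind(c(1, t_zero_low, t_zero_low^2, t_zero_low^3),
             c(1, t_zero_high, t_zero_high^2, t_zero_high^3),
             c(1, t_gmax, t_gmax^2, t_gmax^3),
             c(0, 1, 2 * t_gmax, 3 * t_gmax^2))
  coeffs <- solve(A, c(0, 0, 1, 0))
  structure(list(coeffs = as.numeric(coeffs), t_gmax = t_gmax,
                 t_zero_low = t_zero_low, t_zero_high = t_zero_high),
            class = "growth_curve")
}

#' Fit the site growth curve from a climatology
#'
#' Anchors the cubic on the site's climatology: maximum growth at the
#' warmest climatological monthly mean minus `sd_mult` standard deviations
#' (of the 12 monthly means, by default -- see [monthly_climatology()]);
#' zero net growth at the coolest monthly mean minus `delta_low` and the
#' warmest monthly mean plus `delta_high`.
#'
#' @param clim An [monthly_climatology()] result with `clim_sd > 0`.
#' @param delta_low,delta_high Offsets (degC) placing the cool and warm
#'   zero-growth temperatures; default 5.
#' @param sd_mult Multiplier on `clim_sd` placing the growth optimum below
#'   the warmest month; default 2.
#' @return A `growth_curve` object.
#' @examples
#' cl <- structure(list(clim_max = 28, clim_min = 22, clim_sd = 1.5),
#'                 class = "sst_climatology")
#' gc <- fit_growth_curve(cl)
#' c(gc$t_gmax, gc$t_zero_low, gc$t_zero_high)  # 25 17 33
#' @export
fit_growth_curve <- function(clim, delta_low = 5, delta_high = 5, sd_mult = 2) {
  stopifnot(inherits(clim, "sst_climatology"))
  if (clim$clim_sd <= 0)
    stopf("degenerate climatology: clim_sd must be > 0",
          class = "coralproj_degenerate_error")
  growth_curve_from_anchors(clim$clim_min - delta_low,
                            clim$clim_max - sd_mult * clim$clim_sd,
                            clim$clim_max + delta_high)
}

#' Evaluate relative growth at a temperature
#'
#' Evaluates the cubic; values are dimensionless relative growth (1 at the
#' optimum, 0 at the zero-growth anchors). Negative values -- net decline
#' beyond the zero-growth temperatures -- are allowed but clamped at
#' `floor`, keeping runs that stray far outside the calibrated temperature
#' range bounded rather than numerically explosive.
#'
#' @param curve A `growth_curve`.
#' @param temp_c Temperature(s), degC.
#' @param floor Lower clamp on relative growth; default -1.
#' @return Relative growth rate(s), dimensionless.
#' @export
relative_growth <- function(curve, temp_c, floor = -1) {
  stopifnot(inherits(curve, "growth_curve"))
  g <- curve$coeffs[1] + curve$coeffs[2] * temp_c +
    curve$coeffs[3] * temp_c^2 + curve$coeffs[4] * temp_c^3
  pmax(g, floor)
}

#' Randomly perturb a site growth curve
#'
#' The parameter-sensitivity protocol for the growth module: the two
#' zero-growth temperatures are shifted by independent U(-0.5, 0.5) degC
#' draws and the temperature of maximum growth warmward by U(0, 2) degC,
#' then the cubic is refit from the shifted anchors. A draw that breaks
#' the anchor ordering raises an infeasible-curve error carrying the draw
#' metadata; it is reported, not silently retried.
#'
#' @inheritParams fit_growth_curve
#' @param seed Integer seed for the perturbation draws.
#' @param shifts Optional named numeric vector `c(low=, gmax=, high=)`
#'   giving the three anchor shifts explicitly (bypasses the random draws;
#'   useful for the zero-perturbation limit and for replaying a reported
#'   infeasible draw).
#' @return A `growth_curve` with attribute `"perturbation"` (the three
#'   shifts applied).
#' @export
perturb_growth_curve <- function(clim, seed = NULL, delta_low = 5,
                                 delta_high = 5, sd_mult = 2, shifts = NULL) {
  stopifnot(inherits(clim, "sst_climatology"))
  if (is.null(shifts)) {
    if (!is.null(seed)) set.seed(seed)
    d <- c(low = stats::runif(1, -0.5, 0.5),
           gmax = stats::runif(1, 0, 2),
           high = stats::runif(1, -0.5, 0.5))
  } else {
    d <- shifts[c("low", "gmax", "high")]
  }
  base_low <- clim$clim_min - delta_low
  base_g <- clim$clim_max - sd_mult * clim$clim_sd
  base_high <- clim$clim_max + delta_high
  curve <- withCallingHandlers(
    growth_curve_from_anchors(base_low + d[["low"]], base_g + d[["gmax"]],
                              base_high + d[["high"]]),
    coralproj_infeasible_curve = function(e) {
      e$draws <- d
      stop(e)
    })
  attr(curve, "perturbation") <- d
  curve
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf(paste0("<growth_curve> zeros at %.2f / %.2f degC, ",
                     "optimum %.2f degC (peak 1)\n"),
              x$t_zero_low, x$t_zero_high, x$t_gmax))
  invisible(x)
}

#' @export
coef.growth_curve <- function(object, ...) {
  stats::setNames(object$coeffs, c("c0", "c1", "c2", "c3"))
}

#' @export
predict.growth_curve <- function(object, temp_c, floor = -1, ...) {
  relative_growth(object, temp_c, floor = floor)
}

#' @export
plot.growth_curve <- function(x, ...) {
  tt <- seq(x$t_zero_low - 1, x$t_zero_high + 1, length.out = 200)
  graphics::plot(tt, relative_growth(x, tt, floor = -Inf), type = "l",
                 xlab = "temperature (degC)", ylab = "relative growth", ...)
  graphics::abline(h = 0, lty = 3)
  graphics::abline(v = c(x$t_zero_low, x$t_gmax, x$t_zero_high), lty = 3)
  invisible(x)
}

#' Serialize / restore a growth curve as JSON
#'
#' Round-trips coefficients and anchor temperatures, for provenance in run
#' manifests.
#'
#' @param curve A `growth_curve`.
#' @param path Optional file path; if `NULL`, the JSON string is returned.
#' @return `growth_curve_json`: JSON string or `path`;
#'   `growth_curve_from_json`: a `growth_curve`.
#' @export
growth_curve_json <- function(curve, path = NULL) {
  stopifnot(inherits(curve, "growth_curve"))
  js <- jsonlite::toJSON(unclass(curve), digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' @rdname growth_curve_json
#' @param json JSON string or path to a JSON file.
#' @export
growth_curve_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  structure(list(coeffs = as.numeric(obj$coeffs), t_gmax = obj$t_gmax,
                 t_zero_low = obj$t_zero_low, t_zero_high = obj$t_zero_high),
            class = "growth_curve")
}
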