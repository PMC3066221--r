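# Seawater carbonate equilibrium from the (pCO2, total alkalinity) pair.
#
# Constants, all on the total hydrogen-ion scale, mol/kg-SW:
#   K0  CO2 solubility          Weiss (1974)
#   K1, K2 carbonic acid        Lueker, Dickson & Keeling (2000)
#   KB  boric acid              Dickson (1990)
#   KW  water                   Millero (1995)
#   Ksp aragonite               Mucci (1983)
#   total borate from salinity  Uppstrom (1974)
#   calcium from salinity       Riley & Tongudai (1967)
# Alkalinity here is carbonate + borate + water alkalinity; phosphate and
# silicate contributions are neglected (open-ocean oligotrophic surface).
carb_constants <- function(temp_c, salinity) {
  TK <- temp_c + 273.15
  S <- salinity
  list(
    K0 = exp(-60.2409 + 93.4517 * (100 / TK) + 23.3585 * log(TK / 100) +
               S * (0.023517 - 0.023656 * (TK / 100) +
                      0.0047036 * (TK / 100)^2)),
    K1 = 10^-(3633.86 / TK - 61.2172 + 9.6777 * log(TK) -
                0.011555 * S + 0.0001152 * S^2),
    K2 = 10^-(471.78 / TK + 25.929 - 3.16967 * log(TK) -
                0.01781 * S + 0.0001122 * S^2),
    KB = exp((-8966.90 - 2890.53 * sqrt(S) - 77.942 * S + 1.728 * S^1.5 -
                0.0996 * S^2) / TK +
               148.0248 + 137.1942 * sqrt(S) + 1.62142 * S -
               (24.4344 + 25.085 * sqrt(S) + 0.2474 * S) * log(TK) +
               0.053105 * sqrt(S) * TK),
    KW = exp(148.9802 - 13847.26 / TK - 23.6521 * log(TK) +
               (118.67 / TK - 5.977 + 1.0495 * log(TK)) * sqrt(S) -
               0.01615 * S),
    KspAr = 10^(-171.945 - 0.077993 * TK + 2903.293 / TK +
                  71.595 * log10(TK) +
                  (-0.068393 + 0.0017276 * TK + 88.135 / TK) * sqrt(S) -
                  0.10018 * S + 0.0059415 * S^1.5),
    BT = 0.0004157 * S / 35,
    Ca = 0.02128 / 40.087 * S / 1.80655)
}

#' Aragonite saturation state from temperature and pCO2
#'
#' Solves the seawater carbonate system with two known parameters --
#' surface-ocean pCO2 (taken in annual equilibrium with the atmosphere)
#' and total alkalinity -- for the hydrogen-ion concentration, then returns
#' the aragonite saturation state Omega_a = [Ca2+][CO3 2-] / Ksp(aragonite).
#'
#' @param temp_c Temperature, degC.
#' @param pco2_uatm Surface-water pCO2, micro-atm (numerically equal to the
#'   atmospheric mixing ratio in ppm under the annual-equilibration
#'   assumption).
#' @param salinity Practical salinity; default 35.
#' @param alkalinity Total alkalinity, micro-mol/kg; default 2400
#'   (subtropical surface value chosen so the default table reproduces
#'   present-day open-ocean Omega_a of about 3.8 at 370 micro-atm).
#' @return Omega_a (dimensionless), vectorized over `temp_c`/`pco2_uatm`.
#' @examples
#' carb_omega_a(25, 370)  # ~3.8
#' @export
carb_omega_a <- function(temp_c, pco2_uatm, salinity = 35, alkalinity = 2400) {
  n <- max(length(temp_c), length(pco2_uatm))
  temp_c <- rep_len(temp_c, n)
  pco2_uatm <- rep_len(pco2_uatm, n)
  TA <- alkalinity * 1e-6
  vapply(seq_len(n), function(i) {
    k <- carb_constants(temp_c[i], salinity)
    co2s <- k$K0 * pco2_uatm[i] * 1e-6
    f <- function(H) {
      k$K1 * co2s / H + 2 * k$K1 * k$K2 * co2s / H^2 +
        k$BT * k$KB / (k$KB + H) + k$KW / H - H - TA
    }
    root <- tryCatch(
      stats::uniroot(f, c(1e-12, 1e-2), tol = 1e-18)$root,
      error = function(e) stopf(
        "carbonate solver failed at T=%.2f degC, pCO2=%.1f uatm: %s",
        temp_c[i], pco2_uatm[i], conditionMessage(e),
        class = "coralproj_solver_error"))
    co3 <- k$K1 * k$K2 * co2s / root^2
    k$Ca * co3 / k$KspAr
  }, numeric(1))
}

#' Build a temperature x pCO2 aragonite saturation table
#'
#' Precomputes Omega_a on a rectangular grid by direct carbonate-system
#' solves at every node, for fast bilinear lookup during cover projection.
#'
#' @param t_grid Sorted temperature grid, degC (>= 2 points).
#' @param pco2_grid Sorted pCO2 grid, micro-atm (>= 2 points).
#' @inheritParams carb_omega_a
#' @return An `aragonite_table`: list with `t_grid`, `pco2_grid`, `omega`
#'   (matrix, temperature by pCO2), `salinity`, `alkalinity`.
#' @export
build_aragonite_table <- function(t_grid = seq(15, 35, by = 1),
                                  pco2_grid = seq(200, 1100, by = 50),
                                  salinity = 35, alkalinity = 2400) {
  if (length(t_grid) < 2 || length(pco2_grid) < 2)
    stopf("grids need at least 2 points each", class = "coralproj_param_error")
  if (is.unsorted(t_grid, strictly = TRUE) ||
      is.unsorted(pco2_grid, strictly = TRUE))
    stopf("grids must be strictly increasing", class = "coralproj_param_error")
  omega <- outer(t_grid, pco2_grid,
                 function(tt, pp) carb_omega_a(tt, pp, salinity, alkalinity))
  structure(list(t_grid = t_grid, pco2_grid = pco2_grid, omega = omega,
                 salinity = salinity, alkalinity = alkalinity),
            class = "aragonite_table")
}

#' @export
print.aragonite_table <- function(x, ...) {
  cat(sprintf(paste0("<aragonite_table> T %.1f-%.1f degC x pCO2 %.0f-%.0f uatm",
                     " (S=%.1f, TA=%.0f umol/kg), Omega_a %.2f-%.2f\n"),
              min(x$t_grid), max(x$t_grid), min(x$pco2_grid), max(x$pco2_grid),
              x$salinity, x$alkalinity, min(x$omega), max(x$omega)))
  invisible(x)
}

#' Interpolate aragonite saturation from a precomputed table
#'
#' Bilinear interpolation on the table grid; exact at the nodes. Queries
#' outside the grid hull are an error -- no silent extrapolation.
#'
#' @param table An [build_aragonite_table()] result.
#' @param temp_c Temperature, degC.
#' @param pco2_uatm pCO2, micro-atm.
#' @return Interpolated Omega_a, vectorized.
#' @export
omega_a <- function(table, temp_c, pco2_uatm) {
  stopifnot(inherits(table, "aragonite_table"))
  n <- max(length(temp_c), length(pco2_uatm))
  temp_c <- rep_len(temp_c, n)
  pco2_uatm <- rep_len(pco2_uatm, n)
  if (any(temp_c < min(table$t_grid) | temp_c > max(table$t_grid) |
            pco2_uatm < min(table$pco2_grid) | pco2_uatm > max(table$pco2_grid)))
    stopf("query outside table hull (T %.2f-%.2f, pCO2 %.1f-%.1f)",
          min(table$t_grid), max(table$t_grid), min(table$pco2_grid),
          max(table$pco2_grid), class = "coralproj_extrapolation_error")
  # pracma::interp2 expects Z with rows along y; omega is t x pco2
  pracma::interp2(x = table$t_grid, y = table$pco2_grid, Z = t(table$omega),
                  xp = temp_c, yp = pco2_uatm, method = "linear")
}

#' Calcification multiplier from aragonite saturation decline
#'
#' A linear per-unit sensitivity: each unit decrease in Omega_a below the
#' reference state removes a fraction `s` of the calcification rate. The
#' multiplier is clipped to [0, 1]; with `s = 0` the module is inert (the
#' "more resilient" configuration).
#'
#' @param s Per-Omega-unit sensitivity coefficient, in [0, 0.45].
#' @param omega_ref Reference (model start) Omega_a.
#' @param omega_t Current Omega_a.
#' @return Multiplier in [0, 1], vectorized over `omega_t`.
#' @examples
#' calcification_factor(0.3, 3.8, 2.8)  # 0.70
#' @export
calcification_factor <- function(s, omega_ref, omega_t) {
  if (s < 0 || s > 0.45)
    stopf("sensitivity s must lie in [0, 0.45]", class = "coralproj_param_error")
  clip01(1 - s * pmax(0, omega_ref - omega_t))
}
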