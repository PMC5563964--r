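# Dissolved methane from headspace equilibration, and delta-notation
# conversions for 13C isotope ratios.

# Coefficients of the published 1979 least-squares fit of methane solubility
# in water and seawater (equilibrium concentration form, nmol/l):
#   ln C = ln f + A1 + A2 (100/T) + A3 ln(T/100) + A4 (T/100)
#             + S [B1 + B2 (T/100) + B3 (T/100)^2]
# with T in kelvin, S salinity in per mil and f the methane mole fraction
# (partial pressure in atm at 1 atm total pressure). Stated validity roughly
# -2..30 degC and S 0..40.
CH4_SOL <- list(A1 = -415.2807, A2 = 596.8104, A3 = 379.2599, A4 = -62.0757,
                B1 = -0.059160, B2 = 0.032174, B3 = -0.0048198,
                t_min_K = 271.15, t_max_K = 303.15)

#' Methane solubility at a given partial pressure
#'
#' Equilibrium aqueous methane concentration from the published
#' temperature/salinity fit (see source comments), scaled linearly by the
#' methane partial pressure.
#'
#' @param temperature_K water temperature in kelvin (validity ca. 271--303 K).
#' @param salinity salinity in per mil (default 0, fresh water).
#' @param ch4_atm methane partial pressure in atm (default 1).
#' @return dissolved methane in \eqn{\mu mol\,l^{-1}}.
#' @examples
#' ch4_solubility(279.15)           # ~2100 umol/l at 6 degC, 1 atm
#' @export
ch4_solubility <- function(temperature_K, salinity = 0, ch4_atm = 1) {
  stop_if_not_scalar_number(temperature_K, "temperature_K", positive = TRUE)
  stop_if_not_scalar_number(salinity, "salinity", nonnegative = TRUE)
  stop_if_not_scalar_number(ch4_atm, "ch4_atm", nonnegative = TRUE)
  if (temperature_K < CH4_SOL$t_min_K || temperature_K > CH4_SOL$t_max_K) {
    stop(sprintf("temperature %.2f K outside the solubility fit's validity (%.2f-%.2f K)",
                 temperature_K, CH4_SOL$t_min_K, CH4_SOL$t_max_K),
         call. = FALSE)
  }
  if (ch4_atm == 0) return(0)
  t100 <- temperature_K / 100
  lnC <- log(ch4_atm) + CH4_SOL$A1 + CH4_SOL$A2 * (100 / temperature_K) +
    CH4_SOL$A3 * log(t100) + CH4_SOL$A4 * t100 +
    salinity * (CH4_SOL$B1 + CH4_SOL$B2 * t100 + CH4_SOL$B3 * t100^2)
  exp(lnC) * 1e-3  # nmol/l -> umol/l
}

R_GAS_L_ATM <- 0.0820574  # l atm mol^-1 K^-1

#' Dissolved and headspace methane in an equilibrated closed bottle
#'
#' For a serum bottle with a gas headspace equilibrated at the given methane
#' partial pressure: the aqueous concentration follows the solubility
#' function; the headspace amount is ideal gas.
#'
#' @param headspace_ml headspace volume (ml, > 0).
#' @param liquid_ml liquid volume (ml, > 0).
#' @param temperature_K temperature (K).
#' @param salinity salinity (per mil).
#' @param ch4_atm methane partial pressure in the headspace (atm).
#' @return list with `aqueous_umol_l`, `aqueous_umol`, `headspace_umol`,
#'   `total_umol`.
#' @export
dissolved_ch4 <- function(headspace_ml, liquid_ml, temperature_K,
                          salinity = 0, ch4_atm = 1) {
  stop_if_not_scalar_number(headspace_ml, "headspace_ml", positive = TRUE)
  stop_if_not_scalar_number(liquid_ml, "liquid_ml", positive = TRUE)
  aq_l <- ch4_solubility(temperature_K, salinity, ch4_atm)
  aq <- aq_l * liquid_ml / 1000
  head <- ch4_atm * (headspace_ml / 1000) / (R_GAS_L_ATM * temperature_K) * 1e6
  list(aqueous_umol_l = aq_l, aqueous_umol = aq, headspace_umol = head,
       total_umol = aq + head)
}

#' Partition a known methane amount over headspace and water
#'
#' Solves for the equilibrium partial pressure at which a closed bottle
#' holding `total_umol` methane balances: aqueous + headspace = total. Used
#' to back-calculate dissolved methane from a measured headspace, and as the
#' mass-balance check for [dissolved_ch4()].
#'
#' @inheritParams dissolved_ch4
#' @param total_umol total methane in the bottle (\eqn{\mu}mol, >= 0).
#' @return list as [dissolved_ch4()], plus `ch4_atm`, the equilibrium
#'   partial pressure.
#' @export
equilibrate_headspace <- function(total_umol, headspace_ml, liquid_ml,
                                  temperature_K, salinity = 0) {
  stop_if_not_scalar_number(total_umol, "total_umol", nonnegative = TRUE)
  if (total_umol == 0) {
    out <- dissolved_ch4(headspace_ml, liquid_ml, temperature_K, salinity, 0)
    return(c(out, list(ch4_atm = 0)))
  }
  f <- function(p) {
    dissolved_ch4(headspace_ml, liquid_ml, temperature_K, salinity,
                  p)$total_umol - total_umol
  }
  # total is strictly increasing in p; bracket generously
  upper <- 1
  while (f(upper) < 0) upper <- upper * 2
  p <- uniroot(f, c(0, upper), tol = 1e-12)$root
  out <- dissolved_ch4(headspace_ml, liquid_ml, temperature_K, salinity, p)
  c(out, list(ch4_atm = p))
}

R_VPDB <- 0.0111802

#' Convert between delta 13C (per mil, VPDB) and atom percent
#'
#' \eqn{R = R_{VPDB} (1 + \delta/1000)}, \eqn{at\% = 100 R/(1+R)} with
#' \eqn{R_{VPDB} = 0.0111802}. `atpct_to_delta13c()` is the exact inverse.
#'
#' @param delta delta 13C in per mil (> -1000); vectorised.
#' @param atpct atom percent in (0, 100); vectorised.
#' @param r_vpdb reference isotope ratio (default 0.0111802).
#' @return at%, resp. delta (per mil).
#' @examples
#' delta13c_to_atpct(0)  # 1.1056
#' @export
delta13c_to_atpct <- function(delta, r_vpdb = R_VPDB) {
  if (any(delta <= -1000, na.rm = TRUE)) {
    stop("delta must be > -1000 per mil", call. = FALSE)
  }
  r <- r_vpdb * (1 + delta / 1000)
  100 * r / (1 + r)
}

#' @rdname delta13c_to_atpct
#' @export
atpct_to_delta13c <- function(atpct, r_vpdb = R_VPDB) {
  if (any(atpct <= 0 | atpct >= 100, na.rm = TRUE)) {
    stop("atom percent must lie in (0, 100)", call. = FALSE)
  }
  r <- atpct / (100 - atpct)
  (r / r_vpdb - 1) * 1000
}
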