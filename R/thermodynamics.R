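# universal gas constant, J/(mol K)
GAS_CONSTANT <- 8.314

#' Van't Hoff fit of temperature-dependent binding constants
#'
#' OLS of `log10(Ka)` on `1/T`:
#' \deqn{\log_{10} K_a = -\Delta H / (2.303 R T) + \Delta S / (2.303 R)}
#' so `dH = -2.303 R * slope` (reported in kJ/mol) and
#' `dS = 2.303 R * intercept` (J/(mol K)), with R = 8.314 J/(mol K).
#' `dG = dH - T dS` is evaluated at every input temperature from the single
#' fitted (dH, dS) pair, and the driving forces are classified from the
#' signs of dH and dS.
#'
#' Standard errors require >= 3 temperatures and, with only 3 points, are
#' wide; with exactly 2 temperatures the line interpolates and `r` is
#' reported as 1.
#'
#' @param T_K temperatures in kelvin (>= 2, distinct)
#' @param Ka binding constants (L/mol, > 0), same length as `T_K`
#' @param force_rules forwarded to [classify_forces()]
#' @return object of class `binding_thermo`: `dH` (kJ/mol), `dS`
#'   (J/(mol K)), their SEs, `dG` (kJ/mol, named by temperature), `r_vh`,
#'   `force_verdict`, `spontaneous`
#' @export
vant_hoff_fit <- function(T_K, Ka, force_rules = c("default", "ross")) {
  if (length(T_K) < 2) stop_domain("need >= 2 temperatures")
  if (anyDuplicated(T_K)) stop_domain("duplicate temperatures")
  if (length(Ka) != length(T_K)) stop_domain("T_K and Ka lengths differ")
  if (any(Ka <= 0)) stop_domain("Ka must be positive")
  x <- 1 / T_K
  y <- log10(Ka)
  fit <- stats::lm(y ~ x)
  cf <- lm_summary(fit)$coefficients
  fac <- 2.303 * GAS_CONSTANT
  dH <- -fac * cf[2, 1] / 1000           # kJ/mol
  dS <- fac * cf[1, 1]                   # J/(mol K)
  se_dH <- if (length(T_K) > 2) fac * cf[2, 2] / 1000 else NA_real_
  se_dS <- if (length(T_K) > 2) fac * cf[1, 2] else NA_real_
  r <- if (length(T_K) > 2) stats::cor(x, y) else 1
  dG <- gibbs_free_energy(dH, dS, T_K)
  names(dG) <- as.character(T_K)
  verdict <- classify_forces(dH, dS, rules = force_rules)
  structure(list(T_K = T_K, Ka = Ka, dH = dH, dS = dS,
                 se_dH = se_dH, se_dS = se_dS, dG = dG, r_vh = r,
                 force_verdict = verdict,
                 spontaneous = all(dG < 0)),
            class = "binding_thermo")
}

#' @export
print.binding_thermo <- function(x, ...) {
  cat(sprintf("Van't Hoff fit over %d temperatures (r = %.4f)\n",
              length(x$T_K), x$r_vh))
  cat(sprintf("  dH = %.4g kJ/mol, dS = %.4g J/(mol K)\n", x$dH, x$dS))
  for (i in seq_along(x$dG))
    cat(sprintf("  dG(%s K) = %.4g kJ/mol\n", names(x$dG)[i], x$dG[i]))
  cat("  driving forces:", x$force_verdict,
      if (x$spontaneous) "(spontaneous)" else "(not spontaneous at all T)", "\n")
  invisible(x)
}

#' Gibbs free energy from dH and dS
#'
#' `dG = dH - T * dS`, with `dH` in kJ/mol and `dS` in J/(mol K) (hence the
#' /1000). Vectorised over `T_K`.
#'
#' @param dH enthalpy change (kJ/mol)
#' @param dS entropy change (J/(mol K))
#' @param T_K temperature(s) in kelvin, > 0
#' @return dG in kJ/mol
#' @export
gibbs_free_energy <- function(dH, dS, T_K) {
  if (any(T_K <= 0)) stop_domain("temperature must be positive (kelvin)")
  dH - T_K * dS / 1000
}

#' Classify binding driving forces from the signs of dH and dS
#'
#' Default rule table: (dH < 0, dS > 0) hydrogen bonding plus hydrophobic
#' interaction; (dH < 0, dS < 0) hydrogen bonds plus van der Waals;
#' (dH > 0, dS > 0) hydrophobic; dH within `zero_band` of 0 with dS > 0 is
#' electrostatic. The `"ross"` alternative follows the Ross-Subramanian
#' convention, which assigns (dH < 0, dS > 0) to electrostatic
#' interactions instead.
#'
#' @param dH enthalpy change (kJ/mol)
#' @param dS entropy change (J/(mol K))
#' @param zero_band |dH| below this (kJ/mol) counts as dH ~ 0 (default 1)
#' @param rules `"default"` or `"ross"`
#' @return character verdict
#' @export
classify_forces <- function(dH, dS, zero_band = 1,
                            rules = c("default", "ross")) {
  rules <- match.arg(rules)
  if (!is.finite(dH) || !is.finite(dS)) stop_domain("dH and dS must be finite")
  if (abs(dH) < zero_band && dS > 0) return("electrostatic")
  if (dH < 0 && dS > 0)
    return(if (rules == "ross") "electrostatic" else "hydrogen bonds + hydrophobic")
  if (dH < 0 && dS <= 0) return("hydrogen bonds + van der Waals")
  if (dH >= 0 && dS > 0) return("hydrophobic")
  "indeterminate"
}
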