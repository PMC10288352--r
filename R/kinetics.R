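#' Double-reciprocal (Lineweaver-Burk) transform of a rate table
#'
#' Adds `inv_S = 1/[S]` and `inv_v = 1/v` columns, preserving all rows.
#' Velocities must be strictly positive; a zero or negative velocity aborts
#' with the offending row identified.
#'
#' @param rate_table data.frame with columns `substrate_uM`,
#'   `inhibitor_uM`, `velocity`
#' @return the input with `inv_S` and `inv_v` appended
#' @export
lineweaver_burk_transform <- function(rate_table) {
  bad <- which(!is.finite(rate_table$velocity) | rate_table$velocity <= 0)
  if (length(bad))
    stop_domain("non-positive velocity in row(s) ", paste(bad, collapse = ", "),
                "; Lineweaver-Burk transform requires v > 0")
  rate_table$inv_S <- 1 / rate_table$substrate_uM
  rate_table$inv_v <- 1 / rate_table$velocity
  rate_table
}

#' Fit per-inhibitor-level Lineweaver-Burk primary lines
#'
#' Unweighted OLS of `1/v` on `1/[S]` within each inhibitor level. The slope
#' estimates the apparent `Km/Vmax`, the intercept the apparent `1/Vmax`;
#' for mixed-type data both increase with `[I]`.
#'
#' @param transformed output of [lineweaver_burk_transform()]
#' @return data.frame with one row per inhibitor level: `inhibitor_uM`,
#'   `slope`, `y_intercept`, their SEs, and `r2`
#' @export
fit_primary_lines <- function(transformed) {
  I_levels <- sort(unique(transformed$inhibitor_uM))
  out <- lapply(I_levels, function(Ilev) {
    d <- transformed[transformed$inhibitor_uM == Ilev, ]
    if (length(unique(d$substrate_uM)) < 3)
      stop_domain("need >= 3 substrate levels per inhibitor level (I = ",
                  Ilev, ")")
    fit <- stats::lm(inv_v ~ inv_S, data = d)
    cf <- lm_summary(fit)$coefficients
    data.frame(inhibitor_uM = Ilev,
               slope = cf[2, 1], slope_se = cf[2, 2],
               y_intercept = cf[1, 1], y_intercept_se = cf[1, 2],
               r2 = lm_summary(fit)$r.squared)
  })
  do.call(rbind, out)
}

#' Secondary-plot estimation of Ki, Kis, Km and Vmax
#'
#' Regresses the primary-line slopes and intercepts on inhibitor
#' concentration. With slope-vs-`[I]` intercept `a = Km/Vmax` and slope
#' `b = Km/(Vmax Ki)`, `Ki = a/b`; with intercept-vs-`[I]` intercept
#' `c = 1/Vmax` and slope `d = 1/(Kis Vmax)`, `Kis = c/d`; `Vmax = 1/c` and
#' `Km = a/c`. A non-positive secondary slope means no detectable effect on
#' that branch and the corresponding constant is reported as `Inf` (the
#' pure-competitive / pure-uncompetitive sentinel).
#'
#' @param lines output of [fit_primary_lines()]; >= 3 inhibitor levels
#'   including 0
#' @param rel_tol tolerance forwarded to [classify_inhibition()]
#' @return object of class `kinetic_fit`: `Km`, `Vmax`, `Ki`, `Kis`,
#'   secondary-plot SEs and R-squared values, `primary_lines`,
#'   `inhibition_type`, `prefers_free_enzyme`
#' @export
fit_secondary <- function(lines, rel_tol = 0.10) {
  if (nrow(lines) < 3)
    stop_domain("need >= 3 inhibitor levels for secondary plots")
  if (min(lines$inhibitor_uM) != 0)
    stop_domain("secondary plots require an uninhibited (I = 0) level")
  fs <- stats::lm(slope ~ inhibitor_uM, data = lines)
  fi <- stats::lm(y_intercept ~ inhibitor_uM, data = lines)
  a <- unname(stats::coef(fs)[1]); b <- unname(stats::coef(fs)[2])
  cc <- unname(stats::coef(fi)[1]); d <- unname(stats::coef(fi)[2])
  se_b <- lm_summary(fs)$coefficients[2, 2]
  se_d <- lm_summary(fi)$coefficients[2, 2]

  # a secondary slope whose contribution over the observed [I] range is at
  # numerical-noise level means no detectable effect on that branch: the
  # constant gets the infinite sentinel instead of a floating overflow
  max_I <- max(lines$inhibitor_uM)
  Ki <- if (b > 0 && b * max_I > 1e-9 * abs(a)) a / b else Inf
  Kis <- if (d > 0 && d * max_I > 1e-9 * abs(cc)) cc / d else Inf
  Vmax <- 1 / cc
  Km <- a / cc
  # delta-method SEs, conditioning on the intercepts
  se_Ki <- if (is.finite(Ki)) abs(Ki) * se_b / b else NA_real_
  se_Kis <- if (is.finite(Kis)) abs(Kis) * se_d / d else NA_real_

  type <- classify_inhibition(Ki, Kis, rel_tol = rel_tol)
  structure(list(Km = Km, Vmax = Vmax, Ki = Ki, Kis = Kis,
                 se_Ki = se_Ki, se_Kis = se_Kis,
                 secondary_r2_slope = lm_summary(fs)$r.squared,
                 secondary_r2_intercept = lm_summary(fi)$r.squared,
                 primary_lines = lines,
                 inhibition_type = type,
                 prefers_free_enzyme = is.finite(Ki) && Ki < Kis,
                 rel_tol = rel_tol),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("Kinetic fit (%s inhibition)\n", x$inhibition_type))
  cat(sprintf("  Km = %.4g umol/L, Vmax = %.4g\n", x$Km, x$Vmax))
  cat(sprintf("  Ki = %.4g umol/L (SE %.3g), Kis = %.4g umol/L (SE %.3g)\n",
              x$Ki, x$se_Ki, x$Kis, x$se_Kis))
  if (isTRUE(x$prefers_free_enzyme))
    cat("  Ki < Kis: inhibitor binds free enzyme preferentially\n")
  invisible(x)
}

#' Full Lineweaver-Burk pipeline on a rate table
#'
#' Convenience wrapper: transform, primary fits, secondary fits.
#'
#' @inheritParams lineweaver_burk_transform
#' @inheritParams fit_secondary
#' @return a `kinetic_fit`
#' @export
fit_inhibition_kinetics <- function(rate_table, rel_tol = 0.10) {
  fit_secondary(fit_primary_lines(lineweaver_burk_transform(rate_table)),
                rel_tol = rel_tol)
}

#' Classify the inhibition type from Ki and Kis
#'
#' Competitive if only `Ki` is finite; uncompetitive if only `Kis` is
#' finite; noncompetitive if the two constants agree within `rel_tol`
#' (relative to the smaller one); otherwise mixed. Both infinite means no
#' inhibition was detected.
#'
#' @param Ki,Kis inhibition constants (umol/L, possibly `Inf`)
#' @param rel_tol relative tolerance separating noncompetitive from mixed
#' @return one of `"competitive"`, `"uncompetitive"`, `"noncompetitive"`,
#'   `"mixed"`
#' @export
classify_inhibition <- function(Ki, Kis, rel_tol = 0.10) {
  ki_fin <- is.finite(Ki)
  kis_fin <- is.finite(Kis)
  if (!ki_fin && !kis_fin) stop_domain("no inhibition detected: Ki and Kis both infinite")
  if (ki_fin && !kis_fin) return("competitive")
  if (!ki_fin && kis_fin) return("uncompetitive")
  if (abs(Ki - Kis) / min(Ki, Kis) <= rel_tol) "noncompetitive" else "mixed"
}

#' Intersection point of the uninhibited and most-inhibited primary lines
#'
#' Lineweaver-Burk lines of a mixed-type inhibitor intersect left of the
#' 1/v axis; the quadrant of the intersection (second: above the 1/[S]
#' axis, third: below) is a qualitative diagnostic. Classification is
#' driven by Ki/Kis, not by the quadrant.
#'
#' @param lines output of [fit_primary_lines()]
#' @return list with `x`, `y` of the intersection and `quadrant`
#' @export
lb_intersection <- function(lines) {
  lines <- lines[order(lines$inhibitor_uM), ]
  l1 <- lines[1, ]; l2 <- lines[nrow(lines), ]
  if (l1$slope == l2$slope)
    return(list(x = NA_real_, y = NA_real_, quadrant = "parallel"))
  x <- (l2$y_intercept - l1$y_intercept) / (l1$slope - l2$slope)
  y <- l1$y_intercept + l1$slope * x
  quadrant <- if (x >= 0 && y >= 0) "first"
    else if (x < 0 && y > 0) "second"
    else if (x < 0 && y < 0) "third"
    else "fourth"
  list(x = x, y = y, quadrant = quadrant)
}

#' Direct nonlinear fit of the mixed-inhibition rate law
#'
#' Cross-check for the graphical secondary-plot route: fits the
#' untransformed velocity equation by nonlinear least squares, started from
#' the secondary-plot estimates. On noiseless model data both routes agree
#' to numerical precision; on noisy data they differ because the reciprocal
#' transform reweights errors.
#'
#' @param rate_table data.frame with `substrate_uM`, `inhibitor_uM`,
#'   `velocity`
#' @param start optional list with `Vmax`, `Km`, `Ki`, `Kis`
#' @return list with fitted `Km`, `Vmax`, `Ki`, `Kis` and `converged`
#' @export
fit_mixed_direct <- function(rate_table, start = NULL) {
  if (is.null(start)) {
    g <- fit_inhibition_kinetics(rate_table)
    start <- list(Vmax = g$Vmax, Km = g$Km,
                  Ki = if (is.finite(g$Ki)) g$Ki else 1e6,
                  Kis = if (is.finite(g$Kis)) g$Kis else 1e6)
  }
  S <- rate_table$substrate_uM
  I <- rate_table$inhibitor_uM
  v <- rate_table$velocity
  fit <- tryCatch(
    stats::nls(v ~ Vmax * S / (Km * (1 + I / Ki) + S * (1 + I / Kis)),
               start = start, algorithm = "port",
               lower = c(Vmax = 1e-12, Km = 1e-12, Ki = 1e-12, Kis = 1e-12)),
    error = function(e) NULL)
  if (is.null(fit))
    return(c(start, list(converged = FALSE)))
  cf <- as.list(stats::coef(fit))
  c(cf[c("Km", "Vmax", "Ki", "Kis")], list(converged = TRUE))
}
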