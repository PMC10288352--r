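#' Inner-filter effect correction
#'
#' Re-absorption of excitation and emission light by an absorbing titrant
#' attenuates the measured intensity; the corrected intensity is
#' `Fc = Fm * exp((A1 + A2)/2)` where `A1` and `A2` are the quencher's
#' absorbances at the excitation and emission wavelengths.
#'
#' @param f_measured measured intensity (> 0)
#' @param a_ex,a_em absorbances at excitation / emission wavelengths (>= 0)
#' @return corrected intensity, always >= `f_measured`
#' @export
inner_filter_correct <- function(f_measured, a_ex, a_em) {
  if (any(!is.finite(f_measured)) || any(f_measured <= 0))
    stop_domain("measured intensities must be positive")
  if (any(a_ex < 0) || any(a_em < 0))
    stop_domain("absorbances must be non-negative")
  f_measured * exp((a_ex + a_em) / 2)
}

# adds f_corrected to a titration series (idempotent if already present)
correct_series <- function(series) {
  if (is.null(series$f_corrected))
    series$f_corrected <- inner_filter_correct(series$f_measured,
                                               series$a_ex, series$a_em)
  series
}

series_f0 <- function(series) {
  z <- which(series$quencher_uM == 0)
  if (!length(z)) stop_domain("no zero-quencher row: F0 undefined")
  series$f_corrected[z[1]]
}

#' Stern-Volmer fit of a quenching titration
#'
#' OLS of `F0/F` against quencher concentration in mol/L, with a free
#' intercept; the slope is the Stern-Volmer constant `Ksv`. `F0` is the
#' inner-filter-corrected intensity of the zero-addition row. A fitted
#' intercept deviating from 1 by more than 5% triggers a warning, since the
#' model predicts intercept 1 exactly.
#'
#' @param series a `titration_series` (corrected intensities are computed
#'   from `a_ex`/`a_em` if absent)
#' @param tau0 fluorophore lifetime (s) used for `Kq = Ksv/tau0`
#' @return list with `Ksv` (L/mol), `se_Ksv`, `r` (Pearson correlation),
#'   `intercept`, `Kq` (L/(mol s)), `F0`, `temperature_K`
#' @export
stern_volmer_fit <- function(series, tau0 = 1e-8) {
  series <- correct_series(series)
  F0 <- series_f0(series)
  nz <- series$quencher_uM > 0
  if (sum(nz) < 4) stop_domain("need >= 4 nonzero quencher levels")
  Q <- uM_to_M(series$quencher_uM[nz])
  y <- F0 / series$f_corrected[nz]
  fit <- stats::lm(y ~ Q)
  cf <- lm_summary(fit)$coefficients
  ksv <- cf[2, 1]
  b0 <- cf[1, 1]
  if (abs(b0 - 1) > 0.05)
    warning(sprintf("Stern-Volmer intercept %.3f deviates from 1 by > 5%%", b0),
            call. = FALSE)
  list(Ksv = ksv, se_Ksv = cf[2, 2], r = stats::cor(Q, y), intercept = b0,
       Kq = quenching_rate_constant(ksv, tau0), tau0 = tau0, F0 = F0,
       temperature_K = series$temperature_K[1])
}

#' Bimolecular quenching rate constant
#'
#' `Kq = Ksv / tau0`. A `Kq` far above the diffusion-controlled collisional
#' limit (~2e10 L/(mol s)) indicates static quenching (ground-state complex
#' formation) rather than collisional deactivation.
#'
#' @param Ksv Stern-Volmer constant (L/mol)
#' @param tau0 unquenched fluorophore lifetime (s), > 0
#' @return Kq in L/(mol s)
#' @export
quenching_rate_constant <- function(Ksv, tau0 = 1e-8) {
  if (any(tau0 <= 0)) stop_domain("tau0 must be positive")
  Ksv / tau0
}

#' Double-logarithmic binding fit
#'
#' For static quenching, `log10((F0 - F)/F) = log10(Ka) + n log10([Q])`:
#' OLS on the decadic logs gives the apparent binding constant `Ka`
#' (intercept) and the number of binding sites `n` (slope). `[Q]` is taken
#' in mol/L. Rows with `F >= F0` carry no quenching signal and are dropped
#' with a warning.
#'
#' @param series a `titration_series`
#' @return list with `Ka` (L/mol), `se_Ka`, `n`, `se_n`, `r`, `n_points`,
#'   `temperature_K`
#' @export
double_log_fit <- function(series) {
  series <- correct_series(series)
  F0 <- series_f0(series)
  nz <- series$quencher_uM > 0
  Fq <- series$f_corrected[nz]
  Q <- uM_to_M(series$quencher_uM[nz])
  usable <- Fq < F0
  if (!any(usable)) stop_domain("no quenching: all intensities >= F0")
  if (any(!usable)) {
    warning(sum(!usable), " row(s) with F >= F0 dropped from double-log fit",
            call. = FALSE)
    Fq <- Fq[usable]; Q <- Q[usable]
  }
  if (length(Q) < 4) stop_domain("need >= 4 usable titration points")
  x <- log10(Q)
  y <- log10((F0 - Fq) / Fq)
  fit <- stats::lm(y ~ x)
  cf <- lm_summary(fit)$coefficients
  ka <- 10^cf[1, 1]
  list(Ka = ka, se_Ka = log(10) * ka * cf[1, 2],
       n = cf[2, 1], se_n = cf[2, 2],
       r = stats::cor(x, y), n_points = length(Q),
       temperature_K = series$temperature_K[1])
}

#' Complete quenching analysis of one titration series
#'
#' Runs the inner-filter correction, the Stern-Volmer fit and the
#' double-log binding fit on one series and bundles the results.
#'
#' @inheritParams stern_volmer_fit
#' @return object of class `quench_fit` with fields `temperature_K`,
#'   `Ksv`, `se_Ksv`, `r_sv`, `sv_intercept`, `Kq`, `Ka`, `se_Ka`, `n`,
#'   `se_n`, `r_dl`, `F0`
#' @export
quench_analysis <- function(series, tau0 = 1e-8) {
  sv <- stern_volmer_fit(series, tau0 = tau0)
  dl <- double_log_fit(series)
  structure(list(temperature_K = sv$temperature_K,
                 Ksv = sv$Ksv, se_Ksv = sv$se_Ksv, r_sv = sv$r,
                 sv_intercept = sv$intercept,
                 Kq = sv$Kq, tau0 = tau0,
                 Ka = dl$Ka, se_Ka = dl$se_Ka,
                 n = dl$n, se_n = dl$se_n, r_dl = dl$r,
                 F0 = sv$F0),
            class = "quench_fit")
}

#' @export
print.quench_fit <- function(x, ...) {
  cat(sprintf("Quenching analysis at %g K\n", x$temperature_K))
  cat(sprintf("  Ksv = %.4g L/mol (SE %.3g, r = %.4f), Kq = %.4g L/(mol s)\n",
              x$Ksv, x$se_Ksv, x$r_sv, x$Kq))
  cat(sprintf("  Ka = %.4g L/mol (SE %.3g), n = %.4g (SE %.3g), r = %.4f\n",
              x$Ka, x$se_Ka, x$n, x$se_n, x$r_dl))
  invisible(x)
}

#' Classify the quenching mechanism across temperatures
#'
#' Static quenching (ground-state complex) is indicated when every `Kq`
#' exceeds the diffusion-controlled collisional limit and `Ksv` decreases
#' with temperature (complexes dissociate on heating). Dynamic quenching
#' shows the converse pattern. Conflicting evidence yields `"ambiguous"`
#' with the reasons listed.
#'
#' @param fits list of `quench_fit` objects at distinct temperatures
#' @param diffusion_limit maximal diffusion-collision rate constant,
#'   default 2.0e10 L/(mol s)
#' @return object of class `mechanism_verdict`: `verdict`,
#'   `kq_exceeds_diffusion` (per temperature), `ksv_decreasing_with_T`,
#'   `reasons`
#' @export
classify_quenching <- function(fits, diffusion_limit = 2.0e10) {
  temps <- vapply(fits, function(f) f$temperature_K, numeric(1))
  ord <- order(temps)
  kq <- vapply(fits, function(f) f$Kq, numeric(1))[ord]
  ksv <- vapply(fits, function(f) f$Ksv, numeric(1))[ord]
  exceeds <- kq > diffusion_limit
  trend <- if (length(ksv) >= 2) {
    if (all(diff(ksv) < 0)) "decreasing"
    else if (all(diff(ksv) > 0)) "increasing"
    else "non-monotone"
  } else "unknown"
  reasons <- character(0)
  if (all(exceeds))
    reasons <- c(reasons, sprintf("all Kq > diffusion limit %.3g L/(mol s)", diffusion_limit))
  else
    reasons <- c(reasons, "some Kq at or below the diffusion limit")
  reasons <- c(reasons, paste0("Ksv ", trend, " with temperature"))
  verdict <- if (all(exceeds) && trend %in% c("decreasing", "unknown"))
    "static"
  else if (!any(exceeds) && trend == "increasing")
    "dynamic"
  else "ambiguous"
  structure(list(verdict = verdict,
                 kq_exceeds_diffusion = exceeds,
                 ksv_decreasing_with_T = identical(trend, "decreasing"),
                 temperatures_K = temps[ord],
                 diffusion_limit = diffusion_limit,
                 reasons = reasons),
            class = "mechanism_verdict")
}

#' @export
print.mechanism_verdict <- function(x, ...) {
  cat("Quenching mechanism:", x$verdict, "\n")
  for (r in x$reasons) cat("  -", r, "\n")
  invisible(x)
}

#' Locate emission peaks in a spectrum
#'
#' Finds local maxima above a relative prominence threshold and refines
#' each by a three-point parabolic interpolation. A flat spectrum yields no
#' peaks.
#'
#' @param spectrum data.frame with columns `wavelength_nm` (increasing) and
#'   `intensity`
#' @param prominence minimal peak height above baseline, as a fraction of
#'   the global intensity range (default 0.05)
#' @return data.frame with `wavelength_nm` (refined) and `intensity` per
#'   peak, ordered by wavelength; zero rows if no peak
#' @export
emission_peak <- function(spectrum, prominence = 0.05) {
  wl <- spectrum$wavelength_nm
  y <- spectrum$intensity
  if (length(wl) < 5) stop_domain("spectrum needs >= 5 points")
  if (any(diff(wl) <= 0)) stop_domain("wavelengths must be strictly increasing")
  rng <- diff(range(y))
  if (rng == 0)
    return(data.frame(wavelength_nm = numeric(0), intensity = numeric(0)))
  thr <- min(y) + prominence * rng
  peaks <- list()
  for (i in 2:(length(y) - 1)) {
    if (y[i] >= y[i - 1] && y[i] > y[i + 1] && y[i] >= thr) {
      # parabolic refinement on the local triple
      denom <- y[i - 1] - 2 * y[i] + y[i + 1]
      delta <- if (denom != 0) 0.5 * (y[i - 1] - y[i + 1]) / denom else 0
      delta <- max(min(delta, 0.5), -0.5)
      h <- mean(diff(wl[(i - 1):(i + 1)]))
      peaks[[length(peaks) + 1]] <-
        data.frame(wavelength_nm = wl[i] + delta * h,
                   intensity = y[i] - 0.25 * (y[i - 1] - y[i + 1]) * delta)
    }
  }
  if (!length(peaks))
    return(data.frame(wavelength_nm = numeric(0), intensity = numeric(0)))
  do.call(rbind, peaks)
}
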