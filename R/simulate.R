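#' Mixed-inhibition rate law
#'
#' Direct (untransformed) form of the mixed-inhibition velocity equation,
#' \deqn{v = V_{max} S / (K_m (1 + I/K_i) + S (1 + I/K_{is}))}
#' which reduces to Michaelis-Menten at `I = 0` and is strictly decreasing
#' in `I` when both constants are finite. Vectorised over `S` and `I`.
#'
#' @param p [kinetic_params()]
#' @param S substrate concentration(s), umol/L, > 0
#' @param I inhibitor concentration(s), umol/L, >= 0
#' @return velocity in the units of `p$Vmax`
#' @export
mixed_inhibition_rate <- function(p, S, I = 0) {
  stopifnot(inherits(p, "kinetic_params"))
  if (any(!is.finite(S)) || any(S <= 0))
    stop_domain("substrate concentration S must be positive and finite")
  if (any(!is.finite(I)) || any(I < 0))
    stop_domain("inhibitor concentration I must be non-negative and finite")
  # I/Inf == 0 handles the pure-competitive / pure-uncompetitive sentinels
  p$Vmax * S / (p$Km * (1 + I / p$Ki) + S * (1 + I / p$Kis))
}

#' Simulate a UV absorbance progress curve
#'
#' Initial-rate regime model: the absorbance trace is affine in time,
#' `OD(t) = od_bg + k * E_scale * v * t`, with `v` from
#' [mixed_inhibition_rate()] and multiplicative Gaussian noise on the OD
#' readings. `k` converts velocity units to dOD per second (no extinction
#' coefficient is assumed; default 1).
#'
#' @param p [kinetic_params()]
#' @param S,I substrate / inhibitor concentration (umol/L)
#' @param E_scale enzyme activity multiplier (slope is proportional to it)
#' @param times sampling times in seconds, non-empty, strictly increasing
#' @param noise [noise_model()]
#' @param k velocity-to-dOD/s conversion constant
#' @param od_bg background absorbance at t = 0
#' @param condition_id label stored with the curve
#' @return data.frame of class `progress_curve` with columns
#'   `condition_id`, `t_s`, `od290`; condition metadata in attributes
#' @export
simulate_progress_curve <- function(p, S, I = 0, E_scale = 1, times = seq(0, 300, by = 60),
                                    noise = noise_model(), k = 1,
                                    od_bg = 0.05, condition_id = "c1") {
  if (length(times) == 0) stop_domain("time grid must be non-empty")
  if (any(times < 0) || any(diff(times) <= 0))
    stop_domain("times must be non-negative and strictly increasing")
  v <- mixed_inhibition_rate(p, S, I)
  od <- od_bg + k * E_scale * v * times
  od <- apply_noise(od, noise)
  out <- data.frame(condition_id = condition_id, t_s = times, od290 = od,
                    stringsAsFactors = FALSE)
  attr(out, "condition") <- list(S = S, I = I, E_scale = E_scale, k = k,
                                 od_bg = od_bg)
  class(out) <- c("progress_curve", "data.frame")
  out
}

#' Simulate an initial-velocity grid over substrate and inhibitor levels
#'
#' One row per (S, I) pair; noiseless velocities satisfy the mixed
#' inhibition rate law to machine precision.
#'
#' @param p [kinetic_params()]
#' @param S_levels substrate grid (umol/L), default the 6.25-50 assay grid
#' @param I_levels inhibitor grid (umol/L), default 0-41.67
#' @param noise [noise_model()]
#' @return data.frame (`rate_table`) with columns `substrate_uM`,
#'   `inhibitor_uM`, `enzyme_scale`, `velocity`
#' @export
simulate_rate_grid <- function(p,
                               S_levels = c(6.25, 12.5, 25, 50),
                               I_levels = c(0, 5.21, 10.42, 20.83, 41.67),
                               noise = noise_model()) {
  g <- expand.grid(substrate_uM = S_levels, inhibitor_uM = I_levels,
                   KEEP.OUT.ATTRS = FALSE)
  if (anyDuplicated(g)) stop_domain("duplicate (S, I) pairs in grid")
  v <- mixed_inhibition_rate(p, g$substrate_uM, g$inhibitor_uM)
  data.frame(substrate_uM = g$substrate_uM, inhibitor_uM = g$inhibitor_uM,
             enzyme_scale = 1, velocity = apply_noise(v, noise))
}

#' Simulate velocity versus enzyme amount at fixed substrate
#'
#' For a reversible inhibitor the velocity is proportional to total active
#' enzyme at every inhibitor level, so each noiseless v-vs-E line passes
#' through the origin with slope decreasing in `I`.
#'
#' @param p [kinetic_params()]
#' @param S substrate concentration (umol/L)
#' @param I_levels inhibitor levels (umol/L)
#' @param E_levels >= 2 distinct positive enzyme activity multipliers
#' @param noise [noise_model()]
#' @return `rate_table` data.frame with varying `enzyme_scale`
#' @export
simulate_enzyme_series <- function(p, S = 100,
                                   I_levels = c(0, 5.21, 10.42, 20.83, 41.67),
                                   E_levels = c(0.25, 0.5, 0.75, 1),
                                   noise = noise_model()) {
  E_levels <- unique(E_levels)
  if (length(E_levels) < 2 || any(E_levels <= 0))
    stop_domain("E_levels must contain >= 2 distinct positive values")
  g <- expand.grid(enzyme_scale = E_levels, inhibitor_uM = I_levels,
                   KEEP.OUT.ATTRS = FALSE)
  v1 <- mixed_inhibition_rate(p, S, g$inhibitor_uM)
  data.frame(substrate_uM = S, inhibitor_uM = g$inhibitor_uM,
             enzyme_scale = g$enzyme_scale,
             velocity = apply_noise(g$enzyme_scale * v1, noise))
}

#' Quencher concentrations of a cumulative-dilution titration
#'
#' @param s [titration_scheme()]
#' @return numeric vector of length `n_additions + 1` (including the zero
#'   point), strictly increasing, in umol/L
#' @export
titration_concentrations <- function(s) {
  stopifnot(inherits(s, "titration_scheme"))
  n <- 0:s$n_additions
  s$C_stock * n * s$Va / (s$V0 + n * s$Va)
}

#' Simulate a fluorescence quenching titration
#'
#' Two mutually exclusive generation laws are supported, because the linear
#' Stern-Volmer model and the double-log binding model with `n != 1` are
#' inconsistent forward models on the same data:
#' \itemize{
#'   \item `"stern_volmer"`: true corrected intensity satisfies
#'     `F0/Fc = 1 + Ksv [Q]` ([Q] in mol/L);
#'   \item `"double_log"`: `(F0 - Fc)/Fc = Ka [Q]^n`.
#' }
#' The emitted measured intensity is attenuated by the inner-filter effect,
#' `Fm = Fc * exp(-(A1 + A2)/2)` with `A1 = eps_ex [Q]`, `A2 = eps_em [Q]`
#' ([Q] in umol/L), then multiplicative noise is applied.
#'
#' @param q [quench_params()]
#' @param s [titration_scheme()]
#' @param temperature_K temperature in kelvin (metadata)
#' @param mode `"stern_volmer"` or `"double_log"`
#' @param noise [noise_model()]
#' @return data.frame of class `titration_series` with columns
#'   `temperature_K`, `addition_index`, `quencher_uM`, `f_measured`,
#'   `a_ex`, `a_em`
#' @export
simulate_titration <- function(q, s = titration_scheme(), temperature_K = 298,
                               mode = c("stern_volmer", "double_log"),
                               noise = noise_model()) {
  stopifnot(inherits(q, "quench_params"))
  mode <- match.arg(mode)
  Q_uM <- titration_concentrations(s)
  Q_M <- uM_to_M(Q_uM)
  Fc <- switch(mode,
    stern_volmer = q$F0 / (1 + q$Ksv * Q_M),
    double_log   = q$F0 / (1 + q$Ka * Q_M^q$n))
  a1 <- q$eps_ex * Q_uM
  a2 <- q$eps_em * Q_uM
  fm <- Fc * exp(-(a1 + a2) / 2)
  out <- data.frame(temperature_K = temperature_K,
                    addition_index = seq_along(Q_uM) - 1L,
                    quencher_uM = Q_uM,
                    f_measured = apply_noise(fm, noise),
                    a_ex = a1, a_em = a2)
  attr(out, "mode") <- mode
  attr(out, "tau0") <- q$tau0
  class(out) <- c("titration_series", "data.frame")
  out
}

#' Simulate a relative-activity dose-response table
#'
#' Forward model for IC50 fitting: two-parameter log-logistic with fixed
#' asymptotes 100 and 0, `RA(I) = 100 / (1 + (I/IC50)^h)`, plus
#' multiplicative noise.
#'
#' @param ic50 half-maximal inhibitory concentration (umol/L)
#' @param hill Hill slope (> 0)
#' @param I_levels inhibitor concentrations (umol/L)
#' @param noise [noise_model()]
#' @return data.frame with columns `inhibitor_uM`, `relative_activity_pct`
#' @export
simulate_dose_response <- function(ic50, hill = 1,
                                   I_levels = exp(seq(log(2), log(80), length.out = 8)),
                                   noise = noise_model()) {
  check_positive(ic50, "ic50")
  check_positive(hill, "hill")
  ra <- 100 / (1 + (I_levels / ic50)^hill)
  data.frame(inhibitor_uM = I_levels,
             relative_activity_pct = apply_noise(ra, noise))
}

#' Simulate a two-peak emission spectrum
#'
#' Minimal spectral model used only to exercise peak extraction: a sum of
#' Gaussian bands (defaults at 336 and 404 nm) on a flat baseline. The
#' default bands are deliberately narrow enough not to overlap, so each
#' local maximum of the sum coincides with its band centre; this is a
#' peak-extraction fixture, not a photophysical emission model.
#'
#' @param wavelengths_nm wavelength grid (nm)
#' @param peaks_nm peak centres (nm)
#' @param heights peak heights (same length as `peaks_nm`)
#' @param widths_nm Gaussian sd of each band (nm)
#' @param baseline additive baseline intensity
#' @param noise [noise_model()]
#' @return data.frame with columns `wavelength_nm`, `intensity`
#' @export
simulate_emission_spectrum <- function(wavelengths_nm = seq(290, 500, by = 1),
                                       peaks_nm = c(336, 404),
                                       heights = c(800, 1000),
                                       widths_nm = c(12, 14),
                                       baseline = 5,
                                       noise = noise_model()) {
  inten <- rep(baseline, length(wavelengths_nm))
  for (j in seq_along(peaks_nm))
    inten <- inten + heights[j] * exp(-(wavelengths_nm - peaks_nm[j])^2 / (2 * widths_nm[j]^2))
  data.frame(wavelength_nm = wavelengths_nm,
             intensity = apply_noise(inten, noise))
}
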