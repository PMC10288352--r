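#' Micromolar to molar conversion
#'
#' All concentrations in this package are stored in umol/L. Quenching and
#' binding constants are conventionally reported in L/mol, so fits convert
#' to mol/L internally through this single function.
#'
#' @param x concentration(s) in umol/L
#' @return concentration(s) in mol/L
#' @export
uM_to_M <- function(x) x * 1e-6

stop_domain <- function(...) stop(..., call. = FALSE)

check_positive <- function(x, name, allow_inf = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop_domain(name, " must be a single positive number")
  if (!allow_inf && !is.finite(x))
    stop_domain(name, " must be finite")
  invisible(x)
}

#' Michaelis-Menten / mixed-inhibition kinetic parameters
#'
#' Container for the four constants of the mixed-inhibition rate law:
#' \deqn{v = V_{max} S / (K_m (1 + I/K_i) + S (1 + I/K_{is}))}
#' `Ki` is the dissociation constant of the inhibitor from free enzyme,
#' `Kis` from the enzyme-substrate complex. Pure competitive inhibition is
#' expressed as `Kis = Inf`, pure uncompetitive as `Ki = Inf`; `Inf` is the
#' sentinel for "no binding to that species" and the term `I/K` is then 0.
#'
#' @param Vmax maximal velocity (arbitrary velocity units, e.g. dOD/min)
#' @param Km Michaelis constant (umol/L)
#' @param Ki inhibition constant for free enzyme (umol/L), may be `Inf`
#' @param Kis inhibition constant for enzyme-substrate complex (umol/L),
#'   may be `Inf`
#' @return object of class `kinetic_params`
#' @export
kinetic_params <- function(Vmax, Km, Ki = Inf, Kis = Inf) {
  check_positive(Vmax, "Vmax")
  check_positive(Km, "Km")
  check_positive(Ki, "Ki", allow_inf = TRUE)
  check_positive(Kis, "Kis", allow_inf = TRUE)
  structure(list(Vmax = Vmax, Km = Km, Ki = Ki, Kis = Kis),
            class = "kinetic_params")
}

#' Fluorescence quenching / binding parameters
#'
#' Forward-model parameters for a quenching titration. `eps_ex` and `eps_em`
#' are the quencher's decadic-style attenuation coefficients per umol/L at
#' the excitation and emission wavelengths, so the absorbances entering the
#' inner-filter correction are `A1 = eps_ex * [Q]` and `A2 = eps_em * [Q]`
#' with `[Q]` in umol/L.
#'
#' @param F0 unquenched fluorescence intensity (arbitrary units)
#' @param Ksv Stern-Volmer quenching constant (L/mol)
#' @param Ka apparent binding constant (L/mol)
#' @param n number of binding sites (dimensionless)
#' @param eps_ex,eps_em attenuation per umol/L at excitation / emission
#'   wavelengths (>= 0)
#' @param tau0 fluorophore lifetime in seconds (default 1e-8)
#' @return object of class `quench_params`
#' @export
quench_params <- function(F0 = 1000, Ksv = 1e5, Ka = 1e4, n = 1,
                          eps_ex = 0, eps_em = 0, tau0 = 1e-8) {
  check_positive(F0, "F0")
  check_positive(Ksv, "Ksv")
  check_positive(Ka, "Ka")
  check_positive(n, "n")
  check_positive(tau0, "tau0")
  if (eps_ex < 0 || eps_em < 0)
    stop_domain("eps_ex and eps_em must be non-negative")
  structure(list(F0 = F0, Ksv = Ksv, Ka = Ka, n = n,
                 eps_ex = eps_ex, eps_em = eps_em, tau0 = tau0),
            class = "quench_params")
}

#' Cumulative-dilution titration scheme
#'
#' Describes a cuvette titration in which `Va` mL of stock at `C_stock`
#' umol/L is added `n_additions` times to an initial volume `V0`. The
#' quencher concentration after n additions is
#' `C_n = C_stock * n * Va / (V0 + n * Va)`.
#'
#' @param V0 initial cuvette volume (mL)
#' @param Va aliquot volume per addition (mL)
#' @param C_stock stock quencher concentration (umol/L)
#' @param n_additions number of additions (integer >= 0)
#' @return object of class `titration_scheme`
#' @export
titration_scheme <- function(V0 = 2.0, Va = 0.1, C_stock = 100,
                             n_additions = 8) {
  check_positive(V0, "V0")
  check_positive(Va, "Va")
  check_positive(C_stock, "C_stock")
  if (n_additions < 0 || n_additions != round(n_additions))
    stop_domain("n_additions must be a non-negative integer")
  structure(list(V0 = V0, Va = Va, C_stock = C_stock,
                 n_additions = as.integer(n_additions)),
            class = "titration_scheme")
}

#' Multiplicative Gaussian noise model
#'
#' Instrument noise applied to simulated readings (OD, fluorescence) as
#' `y * (1 + N(0, rel_sd))`. `rel_sd = 0` reproduces the forward model
#' exactly; identical `(params, seed)` give bit-identical output. The seed
#' is applied locally and the caller's RNG state is restored.
#'
#' @param rel_sd relative standard deviation (>= 0)
#' @param seed integer RNG seed, or `NULL` to use the current RNG stream
#' @return object of class `noise_model`
#' @export
noise_model <- function(rel_sd = 0, seed = NULL) {
  if (rel_sd < 0) stop_domain("rel_sd must be >= 0")
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(rel_sd = rel_sd, seed = seed), class = "noise_model")
}

# summary.lm warns on zero-residual fits; noiseless simulated data are a
# designed case here, so that specific warning is muffled.
lm_summary <- function(fit) {
  withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

apply_noise <- function(x, noise) {
  stopifnot(inherits(noise, "noise_model"))
  if (noise$rel_sd == 0) return(x)
  if (!is.null(noise$seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(noise$seed)
  }
  x * (1 + stats::rnorm(length(x), 0, noise$rel_sd))
}
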