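#' Simulate every input table of a scenario
#'
#' Expands a scenario (see [read_scenario()]) into the four assay tables.
#' Quenching titrations are generated twice per temperature, once under the
#' linear Stern-Volmer law and once under the double-log binding law,
#' because the two are mutually inconsistent forward models; each analysis
#' consumes its matching series. All randomness derives from the scenario
#' seed; `rel_sd = 0` yields exact model data.
#'
#' @param scenario scenario list
#' @return list with `rate_grid`, `enzyme_series`, `dose_response`,
#'   `titrations_sv`, `titrations_dl` (the latter two keyed by temperature)
#' @export
simulate_scenario <- function(scenario) {
  sc <- scenario
  seed <- if (is.null(sc$seed)) 1L else as.integer(sc$seed)
  rel_sd <- if (is.null(sc$noise$rel_sd)) 0 else sc$noise$rel_sd
  nm <- function(off) noise_model(rel_sd = rel_sd, seed = seed + off)

  kp <- kinetic_params(Vmax = sc$kinetics$Vmax, Km = sc$kinetics$Km,
                       Ki = sc$kinetics$Ki, Kis = sc$kinetics$Kis)
  rate_grid <- simulate_rate_grid(kp, S_levels = sc$kinetics$S_levels,
                                  I_levels = sc$kinetics$I_levels,
                                  noise = nm(1L))
  enzyme_series <- simulate_enzyme_series(
    kp, S = sc$kinetics$enzyme_substrate_uM,
    I_levels = sc$kinetics$I_levels,
    E_levels = sc$kinetics$E_levels, noise = nm(2L))
  dose_response <- simulate_dose_response(
    ic50 = sc$dose_response$ic50, hill = sc$dose_response$hill,
    I_levels = sc$dose_response$I_levels, noise = nm(3L))

  sch <- titration_scheme(V0 = sc$quench$scheme$V0, Va = sc$quench$scheme$Va,
                          C_stock = sc$quench$scheme$C_stock,
                          n_additions = sc$quench$scheme$n_additions)
  temps <- sc$quench$temperatures
  titr <- function(row, mode, off) {
    qp <- quench_params(F0 = sc$quench$F0, Ksv = row$Ksv, Ka = row$Ka,
                        n = row$n, eps_ex = sc$quench$eps_ex,
                        eps_em = sc$quench$eps_em, tau0 = sc$quench$tau0)
    simulate_titration(qp, sch, temperature_K = row$T_K, mode = mode,
                       noise = nm(off))
  }
  rows <- split(temps, seq_len(nrow(temps)))
  titrations_sv <- lapply(seq_along(rows), function(i)
    titr(rows[[i]], "stern_volmer", 10L + i))
  titrations_dl <- lapply(seq_along(rows), function(i)
    titr(rows[[i]], "double_log", 20L + i))
  names(titrations_sv) <- names(titrations_dl) <- as.character(temps$T_K)

  list(rate_grid = rate_grid, enzyme_series = enzyme_series,
       dose_response = dose_response,
       titrations_sv = titrations_sv, titrations_dl = titrations_dl)
}

default_options <- function(opts = NULL) {
  defaults <- list(rel_tol = 0.10, origin_tol = 0.05, tau0 = 1e-8,
                   diffusion_limit = 2.0e10, force_rules = "default",
                   dilution_correction = FALSE)
  for (nm in names(opts)) defaults[[nm]] <- opts[[nm]]
  defaults
}

#' Run the complete characterisation pipeline
#'
#' Chains every analysis stage — dose-response IC50, reversibility,
#' Lineweaver-Burk kinetics with secondary plots, per-temperature quenching
#' fits, mechanism classification, and van't Hoff thermodynamics — on
#' either a simulation scenario or a set of measured CSV inputs (exactly
#' one of the two). Stages whose inputs are missing are skipped with a
#' recorded reason; the run fails only if every stage is skipped.
#'
#' @param scenario scenario list from [read_scenario()], or `NULL`
#' @param inputs named list of CSV paths (`rates`, `enzyme_rates`,
#'   `dose_response`, `titration`), or `NULL`
#' @param options named list overriding analysis options: `rel_tol`,
#'   `origin_tol`, `tau0`, `diffusion_limit`, `force_rules`
#' @return list of class `qk_report` with one element per stage plus
#'   `provenance`
#' @export
run_pipeline <- function(scenario = NULL, inputs = NULL, options = NULL) {
  if (is.null(scenario) == is.null(inputs))
    stop_domain("provide exactly one of scenario or inputs")
  opt <- default_options(if (!is.null(scenario)) c(scenario$options, options)
                         else options)

  skipped <- list()
  report <- list()

  if (!is.null(scenario)) {
    sim <- simulate_scenario(scenario)
    dose <- sim$dose_response
    enz <- sim$enzyme_series
    rates <- sim$rate_grid
    titr_sv <- sim$titrations_sv
    titr_dl <- sim$titrations_dl
    report$provenance <- list(mode = "scenario",
                              seed = scenario$seed,
                              schema_version = scenario$schema_version)
  } else {
    grab <- function(key, reader) {
      if (is.null(inputs[[key]])) return(NULL)
      reader(inputs[[key]])
    }
    dose <- grab("dose_response", read_dose_response)
    rates <- grab("rates", read_rate_table)
    enz <- grab("enzyme_rates", read_rate_table)
    titr_sv <- titr_dl <- grab("titration", read_titration)
    report$provenance <- list(
      mode = "files",
      files = lapply(inputs, function(p)
        list(path = p, md5 = unname(tools::md5sum(p)))))
  }

  if (!is.null(dose)) {
    report$ic50 <- unclass(fit_ic50(dose))
  } else skipped$ic50 <- "no dose-response input"

  if (!is.null(enz)) {
    rv <- reversibility_test(enz, tol = opt$origin_tol)
    report$reversibility <- list(verdict = rv$verdict,
                                 slopes_decreasing = rv$slopes_decreasing,
                                 lines = rv$lines)
  } else skipped$reversibility <- "no enzyme-series input"

  if (!is.null(rates)) {
    kf <- fit_inhibition_kinetics(rates, rel_tol = opt$rel_tol)
    report$kinetics <- list(
      Km = kf$Km, Vmax = kf$Vmax, Ki = kf$Ki, Kis = kf$Kis,
      se_Ki = kf$se_Ki, se_Kis = kf$se_Kis,
      secondary_r2_slope = kf$secondary_r2_slope,
      secondary_r2_intercept = kf$secondary_r2_intercept,
      inhibition_type = kf$inhibition_type,
      prefers_free_enzyme = kf$prefers_free_enzyme,
      lb_intersection = lb_intersection(kf$primary_lines),
      primary_lines = kf$primary_lines)
  } else skipped$kinetics <- "no rate-table input"

  if (!is.null(titr_sv)) {
    fits <- lapply(names(titr_sv), function(tk) {
      sv <- stern_volmer_fit(titr_sv[[tk]], tau0 = opt$tau0)
      dl <- double_log_fit(titr_dl[[tk]])
      structure(list(temperature_K = sv$temperature_K,
                     Ksv = sv$Ksv, se_Ksv = sv$se_Ksv, r_sv = sv$r,
                     sv_intercept = sv$intercept, Kq = sv$Kq,
                     tau0 = opt$tau0,
                     Ka = dl$Ka, se_Ka = dl$se_Ka,
                     n = dl$n, se_n = dl$se_n, r_dl = dl$r,
                     F0 = sv$F0),
                class = "quench_fit")
    })
    report$quenching <- lapply(fits, unclass)
    mech <- classify_quenching(fits, diffusion_limit = opt$diffusion_limit)
    report$mechanism <- list(verdict = mech$verdict,
                             kq_exceeds_diffusion = mech$kq_exceeds_diffusion,
                             ksv_decreasing_with_T = mech$ksv_decreasing_with_T,
                             reasons = mech$reasons)
    th <- vant_hoff_fit(vapply(fits, `[[`, 0, "temperature_K"),
                        vapply(fits, `[[`, 0, "Ka"),
                        force_rules = opt$force_rules)
    report$thermodynamics <- list(
      dH = th$dH, dS = th$dS, se_dH = th$se_dH, se_dS = th$se_dS,
      dG = as.list(th$dG), r_vh = th$r_vh,
      force_verdict = th$force_verdict, spontaneous = th$spontaneous)
  } else skipped$quenching <- "no titration input"

  if (length(skipped) >= 4)
    stop_domain("all pipeline stages skipped: no usable inputs")
  report$skipped <- skipped
  report$options <- opt
  class(report) <- c("qk_report", "list")
  report
}

#' Export a pipeline report as CSV and JSON artifacts
#'
#' Writes `report.json` (the full report) and `summary_by_temperature.csv`,
#' a per-temperature table of Ksv, r, Ka, r, n, dH, dG, dS in the layout
#' conventional for quenching/thermodynamics summaries. Thermodynamic
#' columns are empty when that stage was skipped.
#'
#' @param report a `qk_report`
#' @param dir output directory (created if missing)
#' @return named character vector of the written paths, invisibly
#' @export
export_tables <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null", force = TRUE)
  qf <- report$quenching
  tab <- if (!is.null(qf)) {
    data.frame(
      T_K = vapply(qf, `[[`, 0, "temperature_K"),
      Ksv_L_per_mol = vapply(qf, `[[`, 0, "Ksv"),
      r_sv = vapply(qf, `[[`, 0, "r_sv"),
      Ka_L_per_mol = vapply(qf, `[[`, 0, "Ka"),
      r_dl = vapply(qf, `[[`, 0, "r_dl"),
      n = vapply(qf, `[[`, 0, "n"),
      dH_kJ_per_mol = if (!is.null(report$thermodynamics))
        report$thermodynamics$dH else NA_real_,
      dG_kJ_per_mol = if (!is.null(report$thermodynamics))
        unlist(report$thermodynamics$dG) else NA_real_,
      dS_J_per_mol_K = if (!is.null(report$thermodynamics))
        report$thermodynamics$dS else NA_real_)
  } else {
    data.frame(T_K = numeric(0), Ksv_L_per_mol = numeric(0),
               r_sv = numeric(0), Ka_L_per_mol = numeric(0),
               r_dl = numeric(0), n = numeric(0),
               dH_kJ_per_mol = numeric(0), dG_kJ_per_mol = numeric(0),
               dS_J_per_mol_K = numeric(0))
  }
  csv_path <- file.path(dir, "summary_by_temperature.csv")
  write_assay_csv(tab, csv_path)
  invisible(c(report = json_path, summary = csv_path))
}

#' @export
print.qk_report <- function(x, ...) {
  cat("quenchkin pipeline report\n")
  if (!is.null(x$ic50))
    cat(sprintf("  IC50 = %.4g umol/L (Hill %.3g)\n", x$ic50$ic50, x$ic50$hill))
  if (!is.null(x$reversibility))
    cat("  reversibility:", x$reversibility$verdict, "\n")
  if (!is.null(x$kinetics))
    cat(sprintf("  %s inhibition: Ki = %.4g, Kis = %.4g umol/L\n",
                x$kinetics$inhibition_type, x$kinetics$Ki, x$kinetics$Kis))
  if (!is.null(x$quenching))
    for (q in x$quenching)
      cat(sprintf("  %g K: Ksv = %.4g L/mol, Ka = %.4g L/mol, n = %.3f\n",
                  q$temperature_K, q$Ksv, q$Ka, q$n))
  if (!is.null(x$mechanism))
    cat("  quenching mechanism:", x$mechanism$verdict, "\n")
  if (!is.null(x$thermodynamics))
    cat(sprintf("  dH = %.4g kJ/mol, dS = %.4g J/(mol K): %s\n",
                x$thermodynamics$dH, x$thermodynamics$dS,
                x$thermodynamics$force_verdict))
  for (nm in names(x$skipped))
    cat("  skipped", nm, "-", x$skipped[[nm]], "\n")
  invisible(x)
}
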