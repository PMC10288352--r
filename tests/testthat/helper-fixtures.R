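# Reference assay constants used across tests (values the analysis stages
# are expected to recover from synthetic data generated with them).
ref_kp <- function(Vmax = 1, Km = 20) {
  kinetic_params(Vmax = Vmax, Km = Km, Ki = 10.6, Kis = 57.24)
}

ref_scheme <- function() titration_scheme(V0 = 2.0, Va = 0.1, C_stock = 100,
                                          n_additions = 8)

ref_qp <- function(...) {
  args <- list(F0 = 1000, Ksv = 1.881e5, Ka = 1.67e4, n = 1.183,
               eps_ex = 0.010, eps_em = 0.004, tau0 = 1e-8)
  args[names(list(...))] <- list(...)
  do.call(quench_params, args)
}

# independent two-pass OLS slope/intercept, used as the regression oracle
ols_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  b <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  c(intercept = my - b * mx, slope = b)
}
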