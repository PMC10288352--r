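test_that("mixed_inhibition_rate matches hand-evaluated values and limits", {
  p <- kinetic_params(Vmax = 1, Km = 10, Ki = 10.6, Kis = 57.24)
  # I = 0 reduces to Michaelis-Menten
  expect_equal(mixed_inhibition_rate(p, S = 25, I = 0), 25 / 35)
  # hand evaluation of the direct form at I = Ki
  expect_equal(mixed_inhibition_rate(p, S = 25, I = 10.6),
               25 / (10 * 2 + 25 * (1 + 10.6 / 57.24)), tolerance = 1e-12)
  expect_equal(mixed_inhibition_rate(p, S = 25, I = 10.6), 0.50373,
               tolerance = 1e-4)
  # saturation limit
  expect_equal(mixed_inhibition_rate(p, S = 1e12, I = 0), 1, tolerance = 1e-9)
  # strictly decreasing in I at fixed S
  v <- mixed_inhibition_rate(p, S = 25, I = c(0, 5, 10, 20, 40))
  expect_true(all(diff(v) < 0))
})

test_that("infinite Ki/Kis sentinels give the pure competitive/uncompetitive laws", {
  comp <- kinetic_params(Vmax = 1, Km = 10, Ki = 5, Kis = Inf)
  expect_equal(mixed_inhibition_rate(comp, 20, 10),
               1 * 20 / (10 * 3 + 20))
  unc <- kinetic_params(Vmax = 1, Km = 10, Ki = Inf, Kis = 5)
  expect_equal(mixed_inhibition_rate(unc, 20, 10),
               1 * 20 / (10 + 20 * 3))
})

test_that("rate-law domain errors are raised", {
  p <- ref_kp()
  expect_error(mixed_inhibition_rate(p, S = 0, I = 0), "positive")
  expect_error(mixed_inhibition_rate(p, S = -1, I = 0), "positive")
  expect_error(mixed_inhibition_rate(p, S = 10, I = -1), "non-negative")
  expect_error(kinetic_params(Vmax = -1, Km = 10), "positive")
})

test_that("progress curves are affine with slope proportional to v and E_scale", {
  p <- kinetic_params(Vmax = 1, Km = 10)
  # v(S = 10) = 0.5; slope = k * E * v
  c1 <- simulate_progress_curve(p, S = 10, I = 0, times = c(0, 60, 120),
                                k = 1, od_bg = 0.05)
  expect_equal(c1$od290, c(0.05, 30.05, 60.05))
  c2 <- simulate_progress_curve(p, S = 10, I = 0, E_scale = 2,
                                times = c(0, 60, 120), k = 1, od_bg = 0.05)
  r1 <- estimate_initial_rate(c1)
  r2 <- estimate_initial_rate(c2)
  expect_equal(r2$rate / r1$rate, 2, tolerance = 1e-12)
  expect_error(simulate_progress_curve(p, 10, times = numeric(0)), "non-empty")
  expect_error(simulate_progress_curve(p, 10, times = c(0, 0, 60)),
               "strictly increasing")
})

test_that("seeded noise is deterministic and rel_sd = 0 is exact", {
  p <- ref_kp()
  n1 <- noise_model(rel_sd = 0.02, seed = 42)
  a <- simulate_rate_grid(p, noise = n1)
  b <- simulate_rate_grid(p, noise = noise_model(rel_sd = 0.02, seed = 42))
  expect_identical(a, b)
  d <- simulate_rate_grid(p, noise = noise_model(rel_sd = 0.02, seed = 43))
  expect_false(identical(a, d))
  clean <- simulate_rate_grid(p)
  expect_equal(clean$velocity,
               mixed_inhibition_rate(p, clean$substrate_uM, clean$inhibitor_uM))
})

test_that("noise application restores the caller's RNG state", {
  set.seed(7)
  before <- .Random.seed
  invisible(simulate_rate_grid(ref_kp(),
                               noise = noise_model(rel_sd = 0.1, seed = 99)))
  expect_identical(.Random.seed, before)
})

test_that("rate grid has one row per (S, I) pair and rejects duplicates", {
  g <- simulate_rate_grid(ref_kp())
  expect_equal(nrow(g), 20) # 4 substrate x 5 inhibitor levels
  expect_equal(anyDuplicated(g[c("substrate_uM", "inhibitor_uM")]), 0)
  expect_error(simulate_rate_grid(ref_kp(), S_levels = c(5, 5),
                                  I_levels = 0), "duplicate")
})

test_that("enzyme series is linear through the origin with slopes decreasing in I", {
  p <- ref_kp()
  es <- simulate_enzyme_series(p, S = 100, I_levels = c(0, 41.67),
                               E_levels = c(0.5, 1, 2))
  v0 <- es$velocity[es$inhibitor_uM == 0]
  expect_equal(v0 / v0[2], c(0.5, 1, 2))
  for (Ilev in unique(es$inhibitor_uM)) {
    d <- es[es$inhibitor_uM == Ilev, ]
    o <- ols_oracle(d$enzyme_scale, d$velocity)
    expect_equal(unname(o["intercept"]), 0, tolerance = 1e-12)
  }
  s0 <- ols_oracle(es$enzyme_scale[es$inhibitor_uM == 0],
                   es$velocity[es$inhibitor_uM == 0])["slope"]
  s1 <- ols_oracle(es$enzyme_scale[es$inhibitor_uM == 41.67],
                   es$velocity[es$inhibitor_uM == 41.67])["slope"]
  expect_lt(s1, s0)
  expect_error(simulate_enzyme_series(p, E_levels = 1), ">= 2 distinct")
})

test_that("titration concentrations reproduce the cumulative-dilution series", {
  s <- ref_scheme()
  conc <- titration_concentrations(s)
  expect_length(conc, 9)
  expect_true(all(diff(conc) > 0))
  expect_equal(conc[2], 4.7619, tolerance = 1e-4)
  expect_equal(conc[9], 28.5714, tolerance = 1e-4)
  expect_equal(titration_concentrations(titration_scheme(n_additions = 0)), 0)
})

test_that("simulate_titration implements both generation laws and the inner filter", {
  s <- ref_scheme()
  # linear quenching law, no inner filter, no noise
  q <- ref_qp(eps_ex = 0, eps_em = 0)
  ser <- simulate_titration(q, s, mode = "stern_volmer")
  expect_equal(ser$f_measured[1], 1000)
  expect_equal(ser$f_measured[9] / 1000, 1 / (1 + 1.881e5 * uM_to_M(ser$quencher_uM[9])))
  expect_equal(ser$f_measured[9] / 1000, 0.15688, tolerance = 1e-4)
  # binding law: (F0 - Fc)/Fc = Ka [Q]^n
  q2 <- ref_qp(eps_ex = 0, eps_em = 0)
  dl <- simulate_titration(q2, titration_scheme(n_additions = 4),
                           mode = "double_log")
  Qm <- uM_to_M(dl$quencher_uM[-1])
  expect_equal((1000 - dl$f_measured[-1]) / dl$f_measured[-1],
               1.67e4 * Qm^1.183, tolerance = 1e-12)
  # hand value: Ka = 1.67e4, n = 1.183, [Q] = 1e-5 M
  expect_equal(1.67e4 * (1e-5)^1.183, 0.020311, tolerance = 1e-4)
  # inner-filter attenuation is exp(-(A1+A2)/2)
  qf <- ref_qp()
  serf <- simulate_titration(qf, s, mode = "stern_volmer")
  expect_equal(serf$a_ex, 0.010 * serf$quencher_uM)
  expect_true(all(serf$f_measured[-1] < ser$f_measured[-1]))
  expect_error(simulate_titration(qf, s, mode = "bogus"))
})

test_that("noise scaling matches the declared relative SD", {
  # N = 2e4 draws of a constant signal: empirical sd of relative residuals
  # must match rel_sd within 3/sqrt(N) standard error of the SD
  p <- kinetic_params(Vmax = 1, Km = 10)
  N <- 2e4
  rel_sd <- 0.05
  g <- simulate_progress_curve(p, S = 10, times = seq_len(N),
                               noise = noise_model(rel_sd, seed = 11),
                               od_bg = 0)
  clean <- simulate_progress_curve(p, S = 10, times = seq_len(N), od_bg = 0)
  rel_resid <- (g$od290 - clean$od290) / clean$od290
  expect_lt(abs(sd(rel_resid) - rel_sd), 3 / sqrt(N) * rel_sd)
})

test_that("two-peak emission spectra are generated and peaks recovered", {
  sp <- simulate_emission_spectrum()
  pk <- emission_peak(sp)
  expect_equal(nrow(pk), 2)
  expect_equal(pk$wavelength_nm[1], 336, tolerance = 0.5 / 336)
  expect_equal(pk$wavelength_nm[2], 404, tolerance = 0.5 / 404)
})
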