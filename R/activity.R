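#' Estimate the initial rate of a progress curve
#'
#' Ordinary least-squares slope of OD versus time. By default all recorded
#' points are used (the assay reads only the linear early phase); with
#' `window = "max_r2"` a sliding window of `window_size` consecutive points
#' is scanned and the window with the highest R-squared is used, which
#' guards against late-phase curvature.
#'
#' @param curve a `progress_curve` or any data.frame with columns `t_s`
#'   and `od290`
#' @param window `"all"` or `"max_r2"`
#' @param window_size points per sliding window (>= 3), used by `"max_r2"`
#' @return list with `rate` (dOD/s), `se`, `r2`, `n_points`, `window`
#' @export
estimate_initial_rate <- function(curve, window = c("all", "max_r2"),
                                  window_size = 5) {
  window <- match.arg(window)
  t <- curve$t_s
  od <- curve$od290
  if (length(t) < 3) stop_domain("progress curve needs >= 3 points")
  if (window_size < 3) stop_domain("window must cover >= 3 points")
  idx <- seq_along(t)
  if (window == "max_r2") {
    if (length(t) < window_size)
      stop_domain("fewer points than window_size")
    starts <- seq_len(length(t) - window_size + 1)
    r2s <- vapply(starts, function(s) {
      ii <- s:(s + window_size - 1)
      suppressWarnings(stats::cor(t[ii], od[ii])^2)
    }, numeric(1))
    r2s[is.na(r2s)] <- 0
    s <- starts[which.max(r2s)]
    idx <- s:(s + window_size - 1)
  }
  fit <- stats::lm(od[idx] ~ t[idx])
  sm <- lm_summary(fit)
  list(rate = unname(stats::coef(fit)[2]),
       se = unname(sm$coefficients[2, 2]),
       r2 = sm$r.squared,
       n_points = length(idx),
       window = window)
}

#' Relative enzymatic activity
#'
#' `RA (%) = 100 * Ri / Rc`, the inhibited rate relative to the uninhibited
#' control. Scale-invariant: multiplying both rates by any positive factor
#' leaves RA unchanged.
#'
#' @param Ri reaction rate with inhibitor
#' @param Rc control rate without inhibitor (> 0)
#' @return relative activity in percent
#' @export
relative_activity <- function(Ri, Rc) {
  if (any(!is.finite(Rc)) || any(Rc <= 0))
    stop_domain("control rate Rc must be positive")
  100 * Ri / Rc
}

#' Fit an IC50 from a relative-activity dose-response table
#'
#' Two-parameter log-logistic model with fixed asymptotes 100 and 0,
#' `RA = 100 / (1 + (I/IC50)^h)`, fitted by nonlinear least squares. A
#' linearised fit (logit of RA/100 against log I) provides starting values
#' and is the exact solution for noiseless model data, where the nls
#' iteration cannot improve a zero residual.
#'
#' @param d data.frame with columns `inhibitor_uM`, `relative_activity_pct`
#' @return object of class `ic50_fit`: `ic50`, `hill`, `se_ic50`,
#'   `se_hill`, `r2`, `n`
#' @export
fit_ic50 <- function(d) {
  I <- d$inhibitor_uM
  ra <- d$relative_activity_pct
  keep <- is.finite(I) & is.finite(ra) & I > 0
  I <- I[keep]; ra <- ra[keep]
  if (length(unique(I)) < 4)
    stop_domain("need >= 4 distinct positive inhibitor levels")
  if (all(ra > 60) || all(ra < 40))
    stop_domain("IC50 not bracketed: relative activity never crosses 50%")

  # linearised start: log(100/RA - 1) = h log I - h log IC50
  lin <- ra > 0 & ra < 100
  lf <- stats::lm(log(100 / ra[lin] - 1) ~ log(I[lin]))
  h0 <- unname(stats::coef(lf)[2])
  ic0 <- exp(-unname(stats::coef(lf)[1]) / h0)
  if (!is.finite(h0) || h0 <= 0 || !is.finite(ic0) || ic0 <= 0) {
    h0 <- 1
    ic0 <- stats::approx(ra, I, xout = 50, ties = mean)$y
  }

  est <- c(ic50 = ic0, hill = h0)
  ses <- c(ic50 = NA_real_, hill = NA_real_)
  fit <- tryCatch(
    stats::nls(ra ~ 100 / (1 + (I / ic50)^h),
               start = list(ic50 = ic0, h = h0),
               algorithm = "port",
               lower = c(ic50 = 1e-12, h = 1e-6)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- lm_summary(fit)$coefficients
    est <- c(ic50 = cf["ic50", 1], hill = cf["h", 1])
    ses <- c(ic50 = cf["ic50", 2], hill = cf["h", 2])
  }
  pred <- 100 / (1 + (I / est["ic50"])^est["hill"])
  ss_res <- sum((ra - pred)^2)
  ss_tot <- sum((ra - mean(ra))^2)
  structure(list(ic50 = unname(est["ic50"]), hill = unname(est["hill"]),
                 se_ic50 = unname(ses["ic50"]), se_hill = unname(ses["hill"]),
                 r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
                 n = length(I)),
            class = "ic50_fit")
}

#' @export
print.ic50_fit <- function(x, ...) {
  cat(sprintf("IC50 fit: IC50 = %.4g umol/L (SE %.3g), Hill = %.4g (SE %.3g), R2 = %.5f, n = %d\n",
              x$ic50, x$se_ic50, x$hill, x$se_hill, x$r2, x$n))
  invisible(x)
}

#' Closed-form IC50 implied by mixed-inhibition kinetics
#'
#' At fixed substrate `S`, the inhibitor level halving the uninhibited
#' velocity under the mixed rate law is
#' `IC50 = (Km + S) / (Km/Ki + S/Kis)`. When `Ki = Kis = K` this equals `K`
#' for any substrate level (pure noncompetitive limit); otherwise the IC50
#' is substrate-dependent.
#'
#' @param p [kinetic_params()] with finite `Ki` and `Kis`
#' @param S substrate concentration (umol/L)
#' @return IC50 in umol/L
#' @export
ic50_from_mixed_kinetics <- function(p, S) {
  stopifnot(inherits(p, "kinetic_params"))
  (p$Km + S) / (p$Km / p$Ki + S / p$Kis)
}

#' Reversibility test from velocity-versus-enzyme lines
#'
#' A reversible inhibitor reduces the effective concentration of active
#' enzyme without inactivating it: plots of velocity against enzyme amount
#' at increasing inhibitor levels remain linear, intersect at the origin,
#' and have slopes decreasing with inhibitor. Per inhibitor level, velocity
#' is regressed on `enzyme_scale`; the intercept is accepted as zero if its
#' 95% confidence interval covers 0 or if its magnitude is at most
#' `tol * max(velocity)`.
#'
#' @param rate_table data.frame with columns `inhibitor_uM`, `enzyme_scale`,
#'   `velocity`; >= 2 enzyme levels per inhibitor level, >= 2 inhibitor
#'   levels
#' @param tol relative intercept tolerance (default 0.05)
#' @return object of class `reversibility_verdict` with per-level `lines`
#'   (slope, intercept, origin_ok), `slopes_decreasing`, `verdict`
#' @export
reversibility_test <- function(rate_table, tol = 0.05) {
  I_levels <- sort(unique(rate_table$inhibitor_uM))
  if (length(I_levels) < 2) stop_domain("need >= 2 inhibitor levels")
  vmax_obs <- max(rate_table$velocity)
  lines <- do.call(rbind, lapply(I_levels, function(Ilev) {
    d <- rate_table[rate_table$inhibitor_uM == Ilev, ]
    if (length(unique(d$enzyme_scale)) < 2)
      stop_domain("need >= 2 enzyme levels per inhibitor level")
    fit <- stats::lm(velocity ~ enzyme_scale, data = d)
    cf <- lm_summary(fit)$coefficients
    b0 <- cf[1, 1]
    se0 <- cf[1, 2]
    ci_ok <- is.finite(se0) &&
      abs(b0) <= stats::qt(0.975, max(fit$df.residual, 1)) * se0
    rel_ok <- abs(b0) <= tol * vmax_obs
    data.frame(inhibitor_uM = Ilev, slope = cf[2, 1], intercept = b0,
               intercept_se = se0, origin_ok = ci_ok || rel_ok)
  }))
  slopes_decreasing <- all(diff(lines$slope) < 0)
  verdict <- if (all(lines$origin_ok) && slopes_decreasing)
    "reversible" else "inconsistent"
  structure(list(lines = lines, slopes_decreasing = slopes_decreasing,
                 verdict = verdict, tol = tol),
            class = "reversibility_verdict")
}

#' @export
print.reversibility_verdict <- function(x, ...) {
  cat("Reversibility test:", x$verdict, "\n")
  cat(sprintf("  slopes decreasing with [I]: %s; all origin intercepts ok: %s\n",
              x$slopes_decreasing, all(x$lines$origin_ok)))
  invisible(x)
}
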