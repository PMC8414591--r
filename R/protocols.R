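#' Calcium drive for physiological protocols
#'
#' Either a constant concentration or a periodic transient built from a
#' product-of-exponentials pulse riding on a diastolic floor.  The transient
#' peaks at `peak` and decays to `diastolic_frac * peak` between beats,
#' emulating the residual ~10% diastolic calcium of a cardiomyocyte
#' transient at 60 beats per minute.
#'
#' @param mode `"transient"` or `"constant"`.
#' @param level constant concentration (uM), used when `mode = "constant"`.
#' @param peak systolic peak (uM).
#' @param diastolic_frac diastolic floor as a fraction of the peak.
#' @param tau_rise,tau_decay rise/decay time constants (ms).
#' @param period beat period (ms); 1000 ms = 60 beats per minute.
#' @export
ca_driver <- function(mode = c("transient", "constant"), level = 0.3,
                      peak = 1, diastolic_frac = 0.1,
                      tau_rise = 20, tau_decay = 110, period = 1000) {
  mode <- match.arg(mode)
  stopifnot(peak > 0, diastolic_frac >= 0, diastolic_frac < 1,
            tau_rise > 0, tau_decay > tau_rise, period > 0)
  # peak location and height of (e^{-t/td} - e^{-t/tr}), for normalisation
  tpk <- log(tau_decay / tau_rise) * tau_rise * tau_decay /
    (tau_decay - tau_rise)
  hpk <- exp(-tpk / tau_decay) - exp(-tpk / tau_rise)
  structure(list(mode = mode, level = level, peak = peak,
                 diastolic_frac = diastolic_frac, tau_rise = tau_rise,
                 tau_decay = tau_decay, period = period, .norm = hpk),
            class = "ca_driver")
}

#' Evaluate a calcium drive
#'
#' @param t time(s) (ms).
#' @param driver a [ca_driver()].
#' @return concentration(s) (uM).
#' @export
ca_transient <- function(t, driver) {
  stopifnot(inherits(driver, "ca_driver"), all(t >= 0))
  if (driver$mode == "constant") return(rep(driver$level, length(t)))
  tau <- t %% driver$period
  pulse <- (exp(-tau / driver$tau_decay) - exp(-tau / driver$tau_rise)) /
    driver$.norm
  dia <- driver$diastolic_frac * driver$peak
  dia + (driver$peak - dia) * pulse
}

#' Isometric steady-state run at constant calcium
#'
#' Holds the half-sarcomere at fixed stretch and constant calcium, records
#' the impulse-matched tension of every macro interval, and summarises the
#' steady-state window (the last `window` fraction of the run) by its mean,
#' a batch-means standard error, and a Kendall trend test.
#'
#' @param params an [xb_params()].
#' @param ca calcium (uM).
#' @param duration run length (ms).
#' @param DT macro interval (ms).
#' @param lambda fixed stretch.
#' @param window steady-window fraction.
#' @param n_batches batches for the standard error of the mean.
#' @return list with `tension` (mean, MPa), `se`, `R_B`, `atp_rate` (1/s per
#'   molecule), `trend_p`, and the per-interval `series`.
#' @export
run_isometric <- function(params, ca, duration = 1500, DT = 1.25,
                          lambda = 1, window = 0.5, n_batches = 8) {
  hs <- half_sarcomere(params, lambda = lambda)
  n_steps <- max(2L, floor(duration / DT))
  n <- num_mc_steps(DT, params$dt0)
  Tser <- RBser <- numeric(n_steps)
  atp <- integer(n_steps)
  for (m in seq_len(n_steps)) {
    res <- run_mc_interval(hs, DT = DT, n = n, ca = ca,
                           lambda_T = lambda, lambda_dot_T = 0)
    hs <- res$hs
    hs <- hs_commit(hs, res$record, lambda, lambda_dot_TdT = 0)
    Tser[m] <- explicit_active_tension(res$record)  # = implicit at rest
    RBser[m] <- binding_ratio(hs)
    atp[m] <- count_atp(res$record)
  }
  w <- seq.int(floor((1 - window) * n_steps) + 1L, n_steps)
  Tw <- Tser[w]
  batches <- split(Tw, cut(seq_along(Tw), n_batches, labels = FALSE))
  bm <- vapply(batches, mean, numeric(1))
  se <- stats::sd(bm) / sqrt(length(bm))
  trend <- suppressWarnings(
    stats::cor.test(seq_along(Tw), Tw, method = "kendall"))
  M <- params$NF * params$NM
  list(tension = mean(Tw), se = se, R_B = mean(RBser[w]),
       atp_rate = sum(atp[w]) / (length(w) * DT * 1e-3 * M),
       trend_p = trend$p.value,
       series = data.frame(t = seq_len(n_steps) * DT, T_act = Tser,
                           R_B = RBser, atp = atp))
}

#' Steady-state force-pCa relationship
#'
#' Runs [run_isometric()] on a grid of calcium concentrations at the
#' unloaded sarcomere length and reports the steady tension with Monte Carlo
#' standard errors; optionally fits a Hill curve.
#'
#' @param params an [xb_params()].
#' @param pca pCa grid (-log10 of molar calcium).
#' @param duration per-point run length (ms).
#' @param DT macro interval (ms).
#' @param hill fit a Hill curve and attach `n_H`, `pCa50`.
#' @return data frame (pCa, ca_uM, tension, se, R_B, atp_rate, non_steady);
#'   when `hill = TRUE`, attributes `n_H` and `pCa50`.
#' @export
force_pca_curve <- function(params = xb_params(),
                            pca = seq(6.8, 5.0, by = -0.3),
                            duration = 1500, DT = 1.25, hill = TRUE) {
  stopifnot(length(pca) >= 1)
  ca_uM <- 10^(-pca) * 1e6
  rows <- lapply(seq_along(pca), function(i) {
    r <- run_isometric(params, ca_uM[i], duration = duration, DT = DT)
    data.frame(pCa = pca[i], ca_uM = ca_uM[i], tension = r$tension,
               se = r$se, R_B = r$R_B, atp_rate = r$atp_rate,
               non_steady = is.finite(r$trend_p) && r$trend_p < 0.01)
  })
  out <- do.call(rbind, rows)
  if (hill && length(pca) >= 4) {
    fit <- tryCatch(hill_fit(out$ca_uM, out$tension), error = function(e) NULL)
    attr(out, "n_H") <- if (is.null(fit)) NA_real_ else fit$n_H
    attr(out, "pCa50") <- if (is.null(fit)) NA_real_ else fit$pCa50
  }
  out
}

#' Hill fit of a force-calcium relation
#'
#' Fits `T = Tmax * ca^h / (ca50^h + ca^h)` by nonlinear least squares.
#'
#' @param ca_uM calcium concentrations (uM).
#' @param tension tensions (MPa).
#' @return list `n_H`, `pCa50`, `Tmax`, and the `nls` fit.
#' @export
hill_fit <- function(ca_uM, tension) {
  stopifnot(length(ca_uM) == length(tension), length(ca_uM) >= 4)
  Tmax0 <- max(tension)
  ca50_0 <- ca_uM[which.min(abs(tension - Tmax0 / 2))]
  fit <- stats::nls(
    tension ~ Tmax * ca_uM^h / (ca50^h + ca_uM^h),
    start = list(Tmax = Tmax0, ca50 = ca50_0, h = 3),
    lower = c(Tmax = 0, ca50 = 1e-4, h = 0.2),
    upper = c(Tmax = 10 * Tmax0 + 1e-9, ca50 = 1e3, h = 30),
    algorithm = "port",
    control = stats::nls.control(maxiter = 200, warnOnly = TRUE))
  est <- stats::coef(fit)
  list(n_H = unname(est["h"]),
       pCa50 = -log10(unname(est["ca50"]) * 1e-6),
       Tmax = unname(est["Tmax"]), fit = fit)
}

#' Force-velocity relationship at constant calcium
#'
#' Imposes constant-velocity shortening ramps on the half-sarcomere at fixed
#' calcium (default 0.7 uM) and averages the impulse-matched tension over a
#' quasi-steady window.  The ATP turnover per molecule rises with the
#' shortening speed (power strokes are facilitated as strains shift
#' negative).
#'
#' @param params an [xb_params()].
#' @param velocities half-sarcomere shortening speeds (um/s, >= 0).
#' @param ca calcium (uM).
#' @param DT macro interval (ms).
#' @param excursion total stretch excursion allowed during a ramp.
#' @param settle isometric settling time before the ramp (ms).
#' @param lambda0 stretch at ramp start.
#' @return data frame (velocity_um_s, tension, se, atp_rate).
#' @export
force_velocity_curve <- function(params = xb_params(),
                                 velocities = c(0, 0.25, 0.5, 1, 2, 4),
                                 ca = 0.7, DT = 1.25, excursion = 0.08,
                                 settle = 600, lambda0 = 1.04) {
  L_um <- params$SL0 / 2 / 1000
  rows <- lapply(velocities, function(v) {
    lamdot <- -v / L_um / 1000               # 1/ms
    ramp_ms <- if (v > 0) excursion / abs(lamdot) else 1200
    hs <- half_sarcomere(params, lambda = lambda0)
    n <- num_mc_steps(DT, params$dt0)
    # settle isometrically at lambda0, then ramp
    for (m in seq_len(floor(settle / DT))) {
      res <- run_mc_interval(hs, DT = DT, n = n, ca = ca,
                             lambda_T = hs$lambda, lambda_dot_T = 0)
      hs <- hs_commit(res$hs, res$record, hs$lambda, 0)
    }
    n_ramp <- max(4L, floor(ramp_ms / DT))
    Tser <- numeric(n_ramp); atp <- integer(n_ramp)
    for (m in seq_len(n_ramp)) {
      lamT <- hs$lambda
      res <- run_mc_interval(hs, DT = DT, n = n, ca = ca,
                             lambda_T = lamT, lambda_dot_T = lamdot)
      hs <- hs_commit(res$hs, res$record, lamT + DT * lamdot, lamdot)
      Tser[m] <- explicit_active_tension(res$record)
      atp[m] <- count_atp(res$record)
    }
    w <- seq.int(max(1L, floor(0.25 * n_ramp)), n_ramp)
    M <- params$NF * params$NM
    data.frame(velocity_um_s = v, tension = mean(Tser[w]),
               se = stats::sd(Tser[w]) / sqrt(length(w)),
               atp_rate = sum(atp[w]) / (length(w) * DT * 1e-3 * M))
  })
  do.call(rbind, rows)
}

#' Explicit/implicit stability sweep on the uniaxial testbed
#'
#' Runs twitches across a grid of macro time steps for both schemes,
#' classifies each run as stable or divergent, and reports the closed-form
#' bound `mu_S / K_A(R_B)` at the peak binding ratio of an implicit
#' reference run for comparison.
#'
#' @param DT_grid macro time steps (ms).
#' @param schemes schemes to sweep.
#' @param duration run length (ms).
#' @param model rate law.
#' @param NF filaments.
#' @param seed base seed (each run offsets it deterministically).
#' @param ... forwarded to [uniaxial_config()].
#' @return data frame (scheme, DT_ms, stable, first_failure_ms) with
#'   attributes `R_B_peak` and `DT_bound_ms`.
#' @export
stability_sweep <- function(DT_grid = c(1.25, 0.01),
                            schemes = c("implicit", "explicit"),
                            duration = 700, model = "dse", NF = 16,
                            seed = 1, ...) {
  ref <- run_uniaxial_twitch(uniaxial_config(
    model = model, scheme = "implicit", NF = NF, DT = 1.25,
    duration = duration, seed = seed, ...))
  R_B_peak <- max(ref$R_B)
  K_A <- axial_stiffness_coefficient(xb_params(model, NF = NF), R_B_peak)
  bound <- explicit_stability_bound(0.03666, K_A)
  grid <- expand.grid(scheme = schemes, DT_ms = DT_grid,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    run <- run_uniaxial_twitch(uniaxial_config(
      model = model, scheme = grid$scheme[i], NF = NF, DT = grid$DT_ms[i],
      duration = duration, seed = seed + i, ...))
    data.frame(scheme = grid$scheme[i], DT_ms = grid$DT_ms[i],
               stable = !attr(run, "diverged"),
               first_failure_ms = attr(run, "first_divergence_time"))
  })
  out <- do.call(rbind, rows)
  attr(out, "R_B_peak") <- R_B_peak
  attr(out, "DT_bound_ms") <- bound
  out
}
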