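# Reduced mechanical testbeds driven by the half-sarcomere ensemble: a
# single-DOF uniaxial strip and a serial myofibril chain, both advanced by
# the Newmark-beta/Newton loop with implicit (MusAsi) or explicit active
# tension.

#' Exponential passive tension law
#'
#' `T_pas(lambda) = c * (exp(b (lambda - 1)) - 1)`: kPa-scale for strains
#' below 0.2 with the defaults (c = 2 kPa, b = 10), a titin-like restoring
#' force in the testbeds.  Returns tension and tangent stiffness.
#'
#' @param lambda stretch.
#' @param c scale (MPa).
#' @param b exponent (dimensionless).
#' @return list `T` (MPa), `K` (MPa per unit stretch).
#' @export
passive_tension <- function(lambda, c = 0.002, b = 10) {
  e <- exp(b * (lambda - 1))
  list(T = c * (e - 1), K = c * b * e)
}

#' Configuration for the uniaxial strip testbed
#'
#' A single half-sarcomere ensemble drives one stretch degree of freedom
#' against exponential passive tension, tissue viscosity `mu_S`, and a tiny
#' consistent mass (the quasi-static limit of the Newmark dynamics).
#'
#' @param model `"dse"` or `"bse"`.
#' @param scheme `"implicit"` (MusAsi) or `"explicit"` active tension.
#' @param NF filaments in the ensemble.
#' @param DT macro time step (ms).
#' @param duration simulated time (ms).
#' @param ca a [ca_driver()] or constant concentration (uM).
#' @param params an [xb_params()]; built from `model`/`NF` when NULL.
#' @param mu_S viscosity (MPa ms); 36.66 Pa s.
#' @param mass nodal mass (MPa ms^2); small, so dynamics are overdamped.
#' @param passive_c,passive_b passive law parameters ([passive_tension()]).
#' @param T_ext external tension load (MPa).
#' @param tol,max_iter Newton controls.
#' @param osc_tol divergence classifier bound on grid-frequency oscillation:
#'   the run is flagged when two consecutive stretch increments alternate in
#'   sign and both exceed `osc_tol` in magnitude.  The overdamped physical
#'   dynamics reverse velocity on the tension/calcium time scale (tens of
#'   ms), never within one macro step at macroscopic amplitude, so sustained
#'   step-to-step alternation is the signature of the unstable explicit
#'   scheme -- whose amplitude is saturated by forced detachment before the
#'   stretch itself leaves `|lambda - 1| < 0.5`.
#' @param seed RNG seed (set once per run; NULL leaves the RNG alone).
#' @export
uniaxial_config <- function(model = "dse", scheme = c("implicit", "explicit"),
                            NF = 16, DT = 1.25, duration = 1000,
                            ca = ca_driver(), params = NULL,
                            mu_S = 0.03666, mass = 0.01,
                            passive_c = 0.002, passive_b = 10,
                            T_ext = 0, tol = 1e-9, max_iter = 25,
                            osc_tol = 0.01, seed = NULL) {
  scheme <- match.arg(scheme)
  if (is.null(params)) params <- xb_params(model, NF = NF)
  list(scheme = scheme, DT = DT, duration = duration, ca = ca,
       params = params, mu_S = mu_S, mass = mass,
       passive_c = passive_c, passive_b = passive_b, T_ext = T_ext,
       tol = tol, max_iter = max_iter, osc_tol = osc_tol, seed = seed)
}

ca_at <- function(ca, t) {
  if (is.numeric(ca)) rep(ca[1], length(t)) else ca_transient(t, ca)
}

#' Run a uniaxial twitch
#'
#' Advances the strip over `duration/DT` macro steps.  Each step runs the
#' Monte Carlo micro-steps once, then solves the Newmark/Newton update; with
#' the implicit scheme the active tension and stiffness are re-evaluated from
#' the frozen record at every trial stretch, with the explicit scheme the
#' tension is frozen and contributes no stiffness.  Divergence (|lambda - 1|
#' > 0.5, a non-finite state, or a Newton breakdown) is reported via the
#' `diverged`/`first_divergence_time` attributes, not raised.
#'
#' @param config an [uniaxial_config()].
#' @return data frame (t, lambda, T_act, dT_dlambda, ca, R_B, atp,
#'   iterations) with attributes `diverged` and `first_divergence_time` (ms,
#'   NA when the run stayed stable).
#' @export
run_uniaxial_twitch <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  p <- config$params
  DT <- config$DT
  n_steps <- max(1L, floor(config$duration / DT))
  hs <- half_sarcomere(p)
  nm_state <- list(U = 1, V = 0, A = 0)
  M <- matrix(config$mass)
  C <- matrix(config$mu_S)
  out <- data.frame(t = numeric(n_steps), lambda = NA_real_,
                    T_act = NA_real_, dT_dlambda = NA_real_, ca = NA_real_,
                    R_B = NA_real_, atp = NA_integer_,
                    iterations = NA_integer_)
  diverged <- FALSE; t_div <- NA_real_
  dlam_prev <- 0
  n <- num_mc_steps(DT, p$dt0)
  for (m in seq_len(n_steps)) {
    t0 <- (m - 1) * DT
    ca_k <- ca_at(config$ca, t0 + seq_len(n) * (DT / n))
    res <- run_mc_interval(hs, DT = DT, n = n, ca = ca_k,
                           lambda_T = nm_state$U, lambda_dot_T = nm_state$V)
    hs <- res$hs
    rec <- res$record
    lam_T <- rec$lambda_T
    if (config$scheme == "implicit") {
      force <- function(U) {
        act <- musasi_tension(rec, lam_T, U[1])
        pas <- passive_tension(U[1], config$passive_c, config$passive_b)
        list(F = act$T_act + pas$T - config$T_ext,
             K = matrix(act$dT_dlambda + pas$K))
      }
    } else {
      T_exp <- explicit_active_tension(rec)
      force <- function(U) {
        pas <- passive_tension(U[1], config$passive_c, config$passive_b)
        list(F = T_exp + pas$T - config$T_ext, K = matrix(pas$K))
      }
    }
    step <- tryCatch(
      newmark_newton_step(nm_state, DT, force, M, C,
                          tol = config$tol, max_iter = config$max_iter),
      musasi_newton_error = function(e) e)
    if (inherits(step, "condition")) {
      diverged <- TRUE; t_div <- t0 + DT
      break
    }
    lam_acc <- step$U[1]
    d_now <- lam_acc - lam_T
    oscillating <- is.finite(d_now) && d_now * dlam_prev < 0 &&
      min(abs(d_now), abs(dlam_prev)) > config$osc_tol
    if (!is.finite(lam_acc) || abs(lam_acc - 1) > 0.5 || oscillating) {
      diverged <- TRUE; t_div <- t0 + DT
      break
    }
    dlam_prev <- d_now
    nm_state <- step
    hs <- hs_commit(hs, rec, lam_acc, lambda_dot_TdT = step$V[1],
                    remap = config$scheme == "implicit")
    tk <- musasi_tension(rec, lam_T, lam_acc)
    out$t[m] <- t0 + DT
    out$lambda[m] <- lam_acc
    out$T_act[m] <- if (config$scheme == "implicit") tk$T_act
                    else explicit_active_tension(rec)
    out$dT_dlambda[m] <- tk$dT_dlambda
    out$ca[m] <- ca_k[n]
    out$R_B[m] <- binding_ratio(hs)
    out$atp[m] <- count_atp(rec)
    out$iterations[m] <- step$iterations
  }
  out <- out[!is.na(out$lambda), , drop = FALSE]
  attr(out, "diverged") <- diverged
  attr(out, "first_divergence_time") <- t_div
  attr(out, "config") <- config
  out
}

#' Configuration for the serial myofibril chain testbed
#'
#' `N_HS` half-sarcomeres in series (default 40 = 20 sarcomeres) with both
#' chain ends fixed, per-half-sarcomere MusAsi tension/stiffness and
#' exponential (titin-like) passive tension, half-sarcomere viscosity, and a
#' small nodal drag.  Node positions are the degrees of freedom; the
#' tangent matrix is tridiagonal.
#'
#' @param model `"dse"` or `"bse"`.
#' @param N_HS number of half-sarcomeres.
#' @param NF filaments per half-sarcomere.
#' @param DT macro step (ms).
#' @param duration simulated time (ms).
#' @param ca calcium concentration (uM), constant for SPOC protocols.
#' @param params an [xb_params()]; built from `model`/`NF` when NULL.
#' @param mu_hs half-sarcomere viscosity (MPa ms).
#' @param drag nodal drag (MPa ms).
#' @param mass nodal mass (MPa ms^2).
#' @param passive_c,passive_b passive law ([passive_tension()]).
#' @param tol,max_iter Newton controls.
#' @param seed RNG seed.
#' @export
chain_config <- function(model = "dse", N_HS = 40, NF = 4, DT = 1.25,
                         duration = 3500, ca = 0.3, params = NULL,
                         mu_hs = 0.03666, drag = 1, mass = 1e-6,
                         passive_c = 0.0015, passive_b = 10,
                         tol = 1e-9, max_iter = 25, seed = NULL) {
  if (is.null(params)) params <- xb_params(model, NF = NF)
  list(N_HS = as.integer(N_HS), DT = DT, duration = duration, ca = ca,
       params = params, mu_hs = mu_hs, drag = drag, mass = mass,
       passive_c = passive_c, passive_b = passive_b,
       tol = tol, max_iter = max_iter, seed = seed)
}

#' Run the serial myofibril chain
#'
#' @param config a [chain_config()].
#' @return list with `sl` (matrix time x half-sarcomere of half-sarcomere
#'   lengths, um), `lambda` (stretch matrix), `tension` (per-step mean
#'   tension, MPa), `t` (ms), `iterations`, `atp`, `R_B`, and the config.
#' @export
run_myofibril_chain <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  p <- config$params
  N <- config$N_HS
  DT <- config$DT
  n_steps <- max(1L, floor(config$duration / DT))
  n <- num_mc_steps(DT, p$dt0)
  L_um <- p$SL0 / 2 / 1000
  hss <- replicate(N, half_sarcomere(p), simplify = FALSE)
  d <- N - 1                       # free internal nodes; ends fixed
  nm_state <- list(U = seq_len(d), V = numeric(d), A = numeric(d))
  M <- diag(config$mass, d)
  C <- diag(2 * config$mu_hs + config$drag, d)
  if (d > 1) {
    idx <- cbind(seq_len(d - 1), 2:d)
    C[idx] <- C[idx[, 2:1]] <- -config$mu_hs
  }
  lam_of <- function(U) diff(c(0, U, N))
  out_lam <- matrix(NA_real_, n_steps, N)
  out_T <- numeric(n_steps); out_it <- integer(n_steps)
  out_atp <- integer(n_steps); out_RB <- numeric(n_steps)
  events_all <- vector("list", n_steps)
  for (m in seq_len(n_steps)) {
    lam_T <- lam_of(nm_state$U)
    lamdot_T <- diff(c(0, nm_state$V, 0))
    recs <- vector("list", N)
    for (i in seq_len(N)) {
      res <- run_mc_interval(hss[[i]], DT = DT, n = n, ca = config$ca,
                             lambda_T = lam_T[i], lambda_dot_T = lamdot_T[i])
      hss[[i]] <- res$hs
      recs[[i]] <- res$record
    }
    force <- function(U) {
      lam <- lam_of(U)
      Tn <- Kn <- numeric(N)
      for (i in seq_len(N)) {
        act <- musasi_tension(recs[[i]], lam_T[i], lam[i])
        pas <- passive_tension(lam[i], config$passive_c, config$passive_b)
        Tn[i] <- act$T_act + pas$T
        Kn[i] <- act$dT_dlambda + pas$K
      }
      Fv <- Tn[seq_len(d)] - Tn[2:N]
      K <- diag(Kn[seq_len(d)] + Kn[2:N], d)
      if (d > 1) {
        idx <- cbind(seq_len(d - 1), 2:d)
        K[idx] <- K[idx[, 2:1]] <- -Kn[2:d]
      }
      list(F = Fv, K = K, T_hs = Tn)
    }
    step <- newmark_newton_step(nm_state, DT, force, M, C,
                                tol = config$tol, max_iter = config$max_iter)
    nm_state <- step
    lam_acc <- lam_of(step$U)
    lamdot_acc <- diff(c(0, step$V, 0))
    Tmean <- 0
    for (i in seq_len(N)) {
      hss[[i]] <- hs_commit(hss[[i]], recs[[i]], lam_acc[i],
                            lambda_dot_TdT = lamdot_acc[i])
      Tmean <- Tmean + musasi_tension(recs[[i]], lam_T[i], lam_acc[i])$T_act / N
    }
    out_lam[m, ] <- lam_acc
    out_T[m] <- Tmean
    out_it[m] <- step$iterations
    out_atp[m] <- sum(vapply(recs, count_atp, integer(1)))
    out_RB[m] <- mean(vapply(hss, binding_ratio, numeric(1)))
    events_all[[m]] <- do.call(rbind, lapply(seq_len(N), function(i) {
      ev <- recs[[i]]$events
      if (nrow(ev)) cbind(step = m, hs = i, ev) else NULL
    }))
  }
  list(t = seq_len(n_steps) * DT,
       lambda = out_lam,
       sl = out_lam * L_um,
       tension = out_T,
       iterations = out_it,
       atp = out_atp,
       R_B = out_RB,
       events = do.call(rbind, events_all),
       config = config)
}

#' Detect spontaneous oscillatory contraction in chain output
#'
#' A half-sarcomere is classified as oscillating when, after discarding an
#' initial transient, its length trace has a peak-to-peak amplitude (5th to
#' 95th percentile) above `min_amplitude` and repeats its excursion at least
#' `min_cycles` times, counted two ways and combined with *or*: full
#' excursions between the lower and upper quartile bands (robust for fast
#' oscillations), and rapid-lengthening yield events — a stretch increase of
#' at least `yield_jump` within `yield_window` ms — which identify the
#' sawtooth (slow-shortening / fast-lengthening) waveform even when the
#' period is a sizeable fraction of the observation window.  The asymmetry
#' statistic is the ratio of mean lengthening to mean shortening speed
#' (> 1 for sawtooth oscillation).
#'
#' @param chain output of [run_myofibril_chain()], or a stretch matrix.
#' @param discard fraction of the trace discarded as initial transient.
#' @param min_amplitude minimum peak-to-peak stretch amplitude.
#' @param min_cycles minimum number of repeats (band cycles or yield events).
#' @param yield_jump stretch increase defining a yield event.
#' @param yield_window time window of a yield event (ms).
#' @param DT sample spacing (ms); taken from `chain` when available.
#' @return list with `fraction` of oscillating half-sarcomeres, `per_hs`
#'   data frame (amplitude, cycles, yields, asymmetry, oscillating), and the
#'   window used.
#' @export
detect_spoc <- function(chain, discard = 0.2, min_amplitude = 0.08,
                        min_cycles = 2, yield_jump = 0.05,
                        yield_window = 250, DT = NULL) {
  lam <- if (is.list(chain)) chain$lambda else chain
  if (is.null(DT)) {
    DT <- if (is.list(chain) && length(chain$t) > 1) diff(chain$t[1:2]) else 1
  }
  n <- nrow(lam)
  win <- seq.int(max(1L, floor(discard * n) + 1L), n)
  w0 <- max(1L, round(yield_window / DT))
  per <- lapply(seq_len(ncol(lam)), function(i) {
    x <- lam[win, i]
    q <- stats::quantile(x, c(0.05, 0.25, 0.75, 0.95), names = FALSE)
    amp <- q[4] - q[1]
    # full lower->upper band excursions (hysteresis crossing counter)
    lo <- q[2]; hi <- q[3]
    phase <- 0L; cycles <- 0L
    for (v in x) {
      if (phase == 0L && v <= lo) phase <- 1L
      else if (phase == 1L && v >= hi) { cycles <- cycles + 1L; phase <- 0L }
    }
    # yield events: rise of >= yield_jump within w0 samples, with refractory
    yields <- 0L; j <- 1L; m <- length(x)
    while (j < m) {
      jj <- min(j + w0, m)
      if (max(x[j:jj]) - x[j] >= yield_jump) {
        yields <- yields + 1L
        j <- jj
      } else {
        j <- j + 1L
      }
    }
    dv <- diff(x)
    up <- dv[dv > 0]; down <- dv[dv < 0]
    asym <- if (length(up) && length(down)) mean(up) / mean(-down) else NA_real_
    data.frame(amplitude = amp, cycles = cycles, yields = yields,
               asymmetry = asym)
  })
  per <- do.call(rbind, per)
  per$oscillating <- per$amplitude > min_amplitude &
    pmax(per$cycles, per$yields) >= min_cycles
  list(fraction = mean(per$oscillating), per_hs = per, window = range(win))
}
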