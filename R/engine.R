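#' Outgoing transition rates of a single myosin molecule
#'
#' Enumerates the outgoing edges of the molecular state graph with their
#' current rates: attachment gating by the T/T unit and nearest-neighbour
#' cooperativity (`gamma^ng` promoting attachment, `gamma^-ng` suppressing
#' detachment from the weak-binding state), strain-dependent power/reverse
#' stroke rates via [stroke_rates()], and the cycle-completing transitions to
#' `N_XB`.  This is the reference (R) enumeration of the same edge set used
#' by the compiled engine.
#'
#' @param state molecular state, one of
#'   `"N_XB", "P_XB", "N_ATP", "XB_PreR", "XB_PostR1", "XB_PostR2"`.
#' @param tt_state T/T unit state, one of `"off", "on_Ca", "open"`.
#' @param ng number of attached neighbours (0, 1 or 2).
#' @param x current rod strain (nm); required for strong-binding states.
#' @param ca calcium concentration (uM); unused here (it enters the T/T
#'   kinetics, not the molecular edges) but accepted for context.
#' @param lambda current stretch; scales the attachment rate through
#'   [overlap_factor()].
#' @param params an [xb_params()].
#' @return a data frame with columns `target` and `rate` (1/s).
#' @export
transition_rates <- function(state, tt_state, ng, x = NA_real_, ca = 0,
                             lambda = 1, params = xb_params()) {
  stopifnot(state %in% XB_STATES, tt_state %in% TT_STATES, ng %in% 0:2,
            ca >= 0, inherits(params, "xb_params"))
  if (state %in% XB_STATES[4:6] && !is.finite(x)) {
    stop("strong-binding state requires a finite rod strain")
  }
  g <- params$gamma^ng
  # stroke destinations may overshoot the forced-detachment bound; rates are
  # evaluated on the smooth quadratic extension (the engine detaches the head
  # on the next step), so widen the domain for rate evaluation only
  rod <- params$rod
  rod$strain_max <- Inf
  rm_ <- params$rates
  s1 <- params$ladder$s1; s2 <- params$ladder$s2
  edge <- function(target, rate) data.frame(target = target, rate = rate)
  out <- switch(
    state,
    N_XB = {
      ttf <- if (tt_state == "open") 1 else params$tt_blocked_factor
      edge("P_XB", params$k_np * params$knp_factor * g * ttf)
    },
    P_XB = rbind(edge("N_XB", params$k_pn / g),
                 edge("XB_PreR",
                      params$f_attach * overlap_factor(lambda, params))),
    N_ATP = edge("N_XB", params$k_atp),
    XB_PreR = {
      sr <- stroke_rates(rm_, rod, 1L, x)
      rbind(edge("XB_PostR1", sr$h_f), edge("P_XB", params$d_detach))
    },
    XB_PostR1 = {
      b1 <- stroke_rates(rm_, rod, 1L, x - s1)
      f2 <- stroke_rates(rm_, rod, 2L, x)
      rbind(edge("XB_PreR", b1$h_b), edge("XB_PostR2", f2$h_f))
    },
    XB_PostR2 = {
      b2 <- stroke_rates(rm_, rod, 2L, x - s2)
      rbind(edge("XB_PostR1", b2$h_b), edge("N_XB", params$d_post2))
    }
  )
  out
}

#' Advance a half-sarcomere by one Monte Carlo micro-step
#'
#' Resolves at most one transition per molecule and per T/T unit with
#' probability `(r_e / r_tot) * (1 - exp(-r_tot * dt))`, evaluating rod
#' strains at the supplied stretch.
#'
#' @param hs a [half_sarcomere()].
#' @param lambda_tilde stretch at which rod strains are evaluated.
#' @param ca calcium concentration (uM).
#' @param dt micro time step (ms).
#' @return list with the updated `hs` and an `events` data frame.
#' @export
mc_micro_step <- function(hs, lambda_tilde, ca, dt) {
  res <- run_mc_interval(hs, DT = dt, n = 1L, ca = ca,
                         lambda_T = lambda_tilde, lambda_dot_T = 0)
  list(hs = res$hs, events = res$record$events)
}

#' Run the Monte Carlo micro-steps of one macro interval
#'
#' Performs `n` micro-steps of size `DT / n` with stretches extrapolated from
#' the macro state, `lambda(k) = lambda_T + k * dt * lambda_dot_T`, and
#' returns the interval record that the implicit tension/stiffness kernels
#' re-read during Newton iterations.
#'
#' @param hs a [half_sarcomere()].
#' @param DT macro interval length (ms).
#' @param n number of micro-steps (default [num_mc_steps()] at the
#'   parameter set's `dt0`).
#' @param ca calcium concentration: scalar or length-`n` vector (uM).
#' @param lambda_T,lambda_dot_T stretch and stretch rate at the beginning of
#'   the interval; default to the values stored in `hs`.
#' @return list with `hs` (advanced to the end of the interval, still at the
#'   extrapolated stretch; see [hs_commit()]) and `record`, an
#'   `mc_interval_record`.
#' @export
run_mc_interval <- function(hs, DT, n = NULL, ca = 0,
                            lambda_T = hs$lambda,
                            lambda_dot_T = hs$lambda_dot) {
  stopifnot(inherits(hs, "half_sarcomere"), DT > 0)
  p <- hs$params
  if (is.null(n)) n <- num_mc_steps(DT, p$dt0)
  n <- as.integer(n)
  stopifnot(n >= 1)
  dt <- DT / n
  if (length(ca) == 1) ca <- rep(ca, n)
  stopifnot(length(ca) == n, all(ca >= 0))
  kp <- kernel_par(p)
  res <- mc_interval_cpp(hs$state, hs$x_A, hs$s, hs$lambda_A, hs$tt,
                         kp, lambda_T, lambda_dot_T, dt, n, ca)
  hs$state <- res$state
  hs$x_A <- res$x_A
  hs$s <- res$s
  hs$lambda_A <- res$lambda_A
  hs$tt <- res$tt
  hs$lambda <- lambda_T + DT * lambda_dot_T
  hs$lambda_dot <- lambda_dot_T
  record <- structure(list(
    n = n, dt = dt, DT = DT,
    lambda_T = lambda_T, lambda_dot_T = lambda_dot_T,
    delta_A = res$delta_A,
    x_A = res$x_A_rec,
    s = res$s_rec,
    k_A = res$k_A,
    lambda_A_carry = res$lambda_A_carry,
    x_tilde = res$x_tilde,
    events = data.frame(k = res$ev_k, molecule = res$ev_mol,
                        from = XB_STATES[res$ev_from + 1L],
                        to = XB_STATES[res$ev_to + 1L]),
    compressed = res[c("b_k", "b_kA", "b_xA", "b_s", "b_lamA", "b_xT")],
    params = p
  ), class = "mc_interval_record")
  list(hs = hs, record = record)
}

#' @export
print.mc_interval_record <- function(x, ...) {
  cat(sprintf(
    "<mc_interval_record> %d micro-steps x %d molecules, %d events, %d ATP\n",
    x$n, ncol(x$delta_A), nrow(x$events), count_atp(x)))
  invisible(x)
}

#' Export an interval event log as a columnar CSV
#'
#' Writes one row per transition with columns `t` (ms from the start of the
#' interval), `k` (micro-step), `filament`, `molecule` (index within the
#' filament), `from`, `to`.
#'
#' @param record an `mc_interval_record`.
#' @param path output CSV path.
#' @return the exported data frame, invisibly.
#' @export
export_events <- function(record, path) {
  stopifnot(inherits(record, "mc_interval_record"))
  ev <- record$events
  NM <- record$params$NM
  out <- data.frame(
    t = ev$k * record$dt,
    k = ev$k,
    filament = (ev$molecule - 1L) %/% NM + 1L,
    molecule = (ev$molecule - 1L) %% NM + 1L,
    from = ev$from, to = ev$to)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Count ATP-consuming transitions in an interval record
#'
#' ATP consumption is counted as the number of transitions into `N_XB` from
#' either `XB_PostR2` (cycle completion) or `N_ATP` (recovery after forced
#' detachment).
#'
#' @param record an `mc_interval_record`, or its `events` data frame.
#' @return integer count.
#' @export
count_atp <- function(record) {
  ev <- if (inherits(record, "mc_interval_record")) record$events else record
  if (!nrow(ev)) return(0L)
  sum(ev$to == "N_XB" & ev$from %in% c("XB_PostR2", "N_ATP"))
}

#' Per-edge transition rates from an event log
#'
#' Rates are computed by dividing the number of transitions per edge by the
#' observation time and the number of myosin molecules, giving events per
#' second per molecule.
#'
#' @param events events data frame (columns `from`, `to`), or an
#'   `mc_interval_record`.
#' @param n_molecules total number of myosin molecules observed.
#' @param duration observation time (s).
#' @return data frame with columns `from`, `to`, `count`, `rate` (1/s per
#'   molecule).
#' @export
transition_rate_stats <- function(events, n_molecules, duration) {
  stopifnot(duration > 0, n_molecules >= 1)
  ev <- if (inherits(events, "mc_interval_record")) events$events else events
  if (!nrow(ev)) {
    return(data.frame(from = character(0), to = character(0),
                      count = integer(0), rate = numeric(0)))
  }
  agg <- stats::aggregate(list(count = rep(1L, nrow(ev))),
                          by = list(from = ev$from, to = ev$to), FUN = sum)
  agg$rate <- agg$count / (duration * n_molecules)
  agg[order(agg$from, agg$to), , drop = FALSE]
}
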