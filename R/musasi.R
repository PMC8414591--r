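#' Number of Monte Carlo micro-steps per macro interval
#'
#' `n = floor((DT - 0.5 * dt0) / dt0) + 1`, so the realised micro-step
#' `DT / n` stays as close as possible to the baseline `dt0`.  With
#' `dt0 = 5 us`, macro steps of 1.25 ms, 0.625 ms and 0.3125 ms give 250,
#' 125 and 63 micro-steps.
#'
#' @param DT macro interval (ms).
#' @param dt0 baseline micro-step (ms).
#' @return integer number of steps (>= 1).
#' @export
num_mc_steps <- function(DT, dt0) {
  stopifnot(DT > 0, dt0 > 0)
  n <- floor((DT - 0.5 * dt0) / dt0) + 1
  as.integer(pmax(n, 1))
}

#' Implicitly re-evaluated rod strain of one recorded molecule-step
#'
#' During Newton iterations the Monte Carlo events are frozen but the rod
#' strains are re-derived from the trial end-of-step stretch: the stretch at
#' micro-step `k` is interpolated,
#' `lambda(k) = lambda_T + (k/n) (lambda_TdT - lambda_T)`, the attachment
#' stretch is the interpolated stretch at the attachment step for
#' within-interval attachments (and the carried value otherwise), and
#' `x = x_A + s + (SL0/2) (lambda(k) - lambda_A)`.
#'
#' @param record an `mc_interval_record` from [run_mc_interval()].
#' @param k micro-step index (1..n).
#' @param molecule molecule index (column of the record).
#' @param lambda_T stretch at the beginning of the interval.
#' @param lambda_TdT trial stretch at the end of the interval.
#' @return strain (nm), or `NA` if the molecule is not bound at step `k`.
#' @export
implicit_strain <- function(record, k, molecule, lambda_T, lambda_TdT) {
  stopifnot(inherits(record, "mc_interval_record"),
            k >= 1, k <= record$n)
  if (!record$delta_A[k, molecule]) return(NA_real_)
  n <- record$n
  kA <- record$k_A[k, molecule]
  if (kA > k) stop("record bookkeeping violation: k_A > k")
  lam_k <- lambda_T + (k / n) * (lambda_TdT - lambda_T)
  lam_A <- if (kA > 0) {
    lambda_T + (kA / n) * (lambda_TdT - lambda_T)
  } else {
    record$lambda_A_carry[k, molecule]
  }
  record$x_A[k, molecule] + record$s[k, molecule] +
    (record$params$SL0 / 2) * (lam_k - lam_A)
}

#' Implicit (MusAsi) active tension
#'
#' Active tension over one macro interval by impulse matching: the sum of
#' bound-head rod forces over all molecules and micro-steps,
#' `T_act = 2 R_S / (SA0 N_F n) * sum delta_A dW/dx(x)`, with the rod strains
#' re-evaluated implicitly from the trial end-of-step stretch
#' ([implicit_strain()]).  Strains beyond the rod domain edge (possible for
#' aggressive Newton trial stretches, since the frozen event set cannot
#' detach) are clamped at the edge.
#'
#' @inheritParams implicit_strain
#' @return tension (MPa).
#' @seealso [active_stiffness()], [explicit_active_tension()]
#' @export
active_tension <- function(record, lambda_T, lambda_TdT) {
  musasi_tension(record, lambda_T, lambda_TdT)$T_act
}

#' Implicit (MusAsi) active stiffness
#'
#' The derivative of [active_tension()] with respect to the end-of-step
#' stretch:
#' `dT/dlambda = 2 R_S / (SA0 N_F n) * sum delta_A d2W/dx2(x) (SL0/2) (k/n - dlambda_A/dlambda)`,
#' where `dlambda_A/dlambda = k_A/n` for attachments made within the
#' interval and 0 for carried attachments.  Every factor `k/n - k_A/n` is
#' non-negative, so the stiffness is non-negative whenever the rod energy is
#' convex -- the property that stabilises the implicit scheme.
#'
#' @inheritParams implicit_strain
#' @return stiffness (MPa per unit stretch).
#' @export
active_stiffness <- function(record, lambda_T, lambda_TdT) {
  musasi_tension(record, lambda_T, lambda_TdT)$dT_dlambda
}

# Tension and stiffness in one kernel pass (used by the Newton loops).
musasi_tension <- function(record, lambda_T, lambda_TdT) {
  stopifnot(inherits(record, "mc_interval_record"))
  kp <- kernel_par(record$params)
  cb <- record$compressed
  musasi_tension_cpp(cb$b_k, cb$b_kA, cb$b_xA, cb$b_s, cb$b_lamA,
                     record$n, lambda_T, lambda_TdT, kp,
                     record$params$include_RS_in_stiffness)
}

#' Explicit active tension
#'
#' The impulse-matched tension evaluated with the strains frozen at their
#' Monte Carlo values (stretches extrapolated from `lambda_T` and
#' `lambda_dot_T`).  It does not depend on the end-of-step stretch, so its
#' contribution to the stiffness matrix is zero -- the source of the explicit
#' scheme's conditional stability.
#'
#' @param record an `mc_interval_record`.
#' @return tension (MPa).
#' @export
explicit_active_tension <- function(record) {
  stopifnot(inherits(record, "mc_interval_record"))
  kp <- kernel_par(record$params)
  explicit_tension_cpp(record$compressed$b_xT, record$n, kp)
}

#' Commit an accepted macro step to the half-sarcomere state
#'
#' After the Newton loop accepts an end-of-step stretch, the stored
#' attachment stretches of molecules that attached within the interval are
#' re-mapped from their extrapolated values to the accepted interpolated
#' values, and the macro state (`lambda`, `lambda_dot`) is updated, so the
#' next interval starts from strains consistent with the accepted trajectory.
#'
#' @param hs the half-sarcomere returned by [run_mc_interval()].
#' @param record the matching `mc_interval_record`.
#' @param lambda_TdT accepted end-of-step stretch.
#' @param lambda_dot_TdT accepted end-of-step stretch rate (1/ms); defaults
#'   to the secant rate over the interval.
#' @param remap re-map within-interval attachment stretches to the accepted
#'   interpolated values (TRUE for the implicit scheme; the explicit scheme
#'   keeps the extrapolated Monte Carlo values).
#' @return the updated `half_sarcomere`.
#' @export
hs_commit <- function(hs, record, lambda_TdT,
                      lambda_dot_TdT = (lambda_TdT - record$lambda_T) / record$DT,
                      remap = TRUE) {
  stopifnot(inherits(hs, "half_sarcomere"),
            inherits(record, "mc_interval_record"))
  n <- record$n
  lambda_T <- record$lambda_T
  # final-step attachment bookkeeping: k_A at the last recorded bound step
  bound <- hs$state %in% .BOUND
  if (remap && any(bound)) {
    kA_final <- record$k_A[n, ]
    fresh <- bound & kA_final > 0
    hs$lambda_A[fresh] <- lambda_T +
      (kA_final[fresh] / n) * (lambda_TdT - lambda_T)
  }
  hs$lambda <- lambda_TdT
  hs$lambda_dot <- lambda_dot_TdT
  hs
}
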