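#' Fiber stretch and stretch rate from the deformation gradient
#'
#' `stretch()` returns `lambda = ||F f||`; `stretch_rate()` returns
#' `lambda_dot = (Fdot f) . (F f) / lambda`.
#'
#' @param F 3x3 deformation gradient (det F > 0).
#' @param Fdot 3x3 time derivative of `F`.
#' @param f unit fiber direction in reference coordinates.
#' @return scalar stretch (dimensionless) or stretch rate (same time unit as
#'   `Fdot`).
#' @export
stretch <- function(F, f) {
  check_kinematics(F, f)
  v <- as.vector(F %*% f)
  lam <- sqrt(sum(v^2))
  if (lam == 0) stop("degenerate deformation: lambda = 0")
  lam
}

#' @rdname stretch
#' @export
stretch_rate <- function(F, Fdot, f) {
  lam <- stretch(F, f)
  sum(as.vector(Fdot %*% f) * as.vector(F %*% f)) / lam
}

check_kinematics <- function(F, f) {
  stopifnot(is.matrix(F), all(dim(F) == c(3, 3)), length(f) == 3)
  if (det(F) <= 0) stop("deformation gradient must have positive determinant")
  if (abs(sum(f^2) - 1) > 1e-8) stop("fiber direction must be a unit vector")
  invisible(TRUE)
}

#' Second Piola-Kirchhoff active stress tensor
#'
#' `S_act = (T_act / lambda) f (x) f`: rank-1, symmetric, aligned with the
#' fiber direction, chosen so that the work identity
#' `S_act : dE = T_act dlambda` holds for any variation of the deformation.
#'
#' @param T_act active tension (MPa).
#' @param lambda fiber stretch (> 0).
#' @param f unit fiber direction (reference coordinates).
#' @return 3x3 matrix (MPa).
#' @export
active_pk2 <- function(T_act, lambda, f) {
  stopifnot(lambda > 0, length(f) == 3)
  (T_act / lambda) * tcrossprod(f)
}

#' Second variation of the fiber stretch
#'
#' For a variation `dF` of the deformation gradient,
#' `d2lambda = (1/lambda) * ((dF f).(dF f) - (a.(dF f))^2)` with
#' `a = F f / lambda`.  By Cauchy-Schwarz this is always non-negative, which
#' makes the geometric part of the active stiffness positive semi-definite
#' whenever the active tension is non-negative.
#'
#' @param F 3x3 deformation gradient.
#' @param f unit fiber direction.
#' @param dF 3x3 variation of the deformation gradient.
#' @return scalar `d2lambda` (>= 0).
#' @export
stretch_hessian <- function(F, f, dF) {
  lam <- stretch(F, f)
  w <- as.vector(dF %*% f)
  a <- as.vector(F %*% f) / lam
  (sum(w^2) - sum(a * w)^2) / lam
}

#' Macroscopic axial active stiffness coefficient
#'
#' Closed-form estimate of the fiber-direction stiffness of the active
#' tension at binding ratio `R_B`, assuming every bound rod contributes its
#' (positive-strain) spring constant:
#' `K_A = (R_S / SA0) R_B 2 N_M k_rod (SL0/2)`.
#' With the reference parameters (R_S = 0.5, SA0 = 693 nm^2, N_M = 38,
#' k_rod = 2 pN/nm, SL0/2 = 950 nm) this gives 104.2 * R_B MPa.
#'
#' @param params an [xb_params()] (supplies geometry and the rod).
#' @param R_B binding ratio in `[0, 1]`.
#' @return stiffness (MPa).
#' @export
axial_stiffness_coefficient <- function(params = xb_params(), R_B = 1) {
  stopifnot(inherits(params, "xb_params"), R_B >= 0, R_B <= 1)
  (params$RS / params$SA0) * R_B * 2 * params$NM * params$rod$k_pos *
    (params$SL0 / 2)
}

#' Explicit-scheme stable time step bound
#'
#' When the active tension is applied explicitly (no active stiffness in the
#' Newton matrix), the macro time step is limited by the ratio of tissue
#' viscosity to active stiffness: `DT_max = mu_S / K_A`.  With
#' mu_S = 36.66 Pa s and K_A = 104.2 MPa this is ~0.35 us at full binding
#' (scaling as 1/R_B).
#'
#' @param mu_S viscosity (MPa ms; 36.66 Pa s = 0.03666 MPa ms).
#' @param K_A active stiffness coefficient (MPa).
#' @return time step bound (ms); `Inf` when `K_A = 0`.
#' @export
explicit_stability_bound <- function(mu_S, K_A) {
  stopifnot(mu_S > 0, K_A >= 0)
  if (K_A == 0) return(Inf)
  mu_S / K_A
}
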