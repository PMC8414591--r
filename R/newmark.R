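#' One Newmark-beta step solved by Newton iterations
#'
#' Advances the second-order system `R(U, V, A) = M A + C V + F(U) = 0` from
#' `T` to `T + DT` with the Newmark-beta interpolation rules, solving for the
#' acceleration increment at every Newton iteration:
#' `(M + gammaN DT C + beta DT^2 K) dA = rhs`, with the special right-hand
#' side at the first iteration accounting for the initial guesses not yet
#' satisfying the interpolation rules.  With `beta = 1/4`,
#' `gammaN = 1/2` the scheme is the unconditionally stable average
#' acceleration method and conserves the discrete energy of linear undamped
#' systems.
#'
#' @param state list with numeric vectors `U`, `V`, `A` (displacement,
#'   velocity, acceleration).
#' @param DT time step (ms).
#' @param force function `force(U)` returning `list(F = internal force
#'   vector (includes external loads with their sign), K = tangent stiffness
#'   matrix dF/dU)`; re-evaluated at every Newton iteration, which is where
#'   an implicit active tension provider plugs in.
#' @param M mass matrix.
#' @param C damping matrix.
#' @param beta,gammaN Newmark parameters.
#' @param tol convergence tolerance on the residual norm.
#' @param max_iter maximum Newton iterations.
#' @return list `U`, `V`, `A`, `iterations`, `residual`.  Non-convergence is
#'   an error of class `musasi_newton_error` carrying the last residual norm.
#' @export
newmark_newton_step <- function(state, DT, force, M, C,
                                beta = 0.25, gammaN = 0.5,
                                tol = 1e-9, max_iter = 25) {
  U <- state$U; V <- state$V; A <- state$A
  d <- length(U)
  M <- as.matrix(M); C <- as.matrix(C)
  U_T <- U; V_T <- V; A_T <- A

  fk <- force(U)
  R <- as.vector(M %*% A + C %*% V + fk$F)
  rn <- sqrt(sum(R^2))
  if (rn <= tol) {
    return(list(U = U, V = V, A = A, iterations = 1L, residual = rn))
  }
  for (k in 0:(max_iter - 1)) {
    K <- as.matrix(fk$K)
    LHS <- M + gammaN * DT * C + beta * DT^2 * K
    rhs <- if (k == 0) {
      -R - as.vector(C %*% (DT * A_T)) -
        as.vector(K %*% (DT * V_T + 0.5 * DT^2 * A_T))
    } else {
      -R
    }
    dA <- solve(LHS, rhs)
    if (k == 0) {
      A <- A_T + dA
      V <- V_T + DT * (gammaN * dA + A_T)
      U <- U_T + DT * V_T + DT^2 * (beta * dA + 0.5 * A_T)
      fk <- force(U)
      R <- as.vector(M %*% A + C %*% V + fk$F)
      rn <- sqrt(sum(R^2))
    } else {
      # damped update: backtrack when the piecewise rod stiffness (kinks,
      # domain clamps) makes the full Newton step overshoot
      rn_old <- rn
      step_scale <- 1
      for (ls in 1:6) {
        A_try <- A + step_scale * dA
        V_try <- V + gammaN * DT * step_scale * dA
        U_try <- U + beta * DT^2 * step_scale * dA
        fk_try <- force(U_try)
        R_try <- as.vector(M %*% A_try + C %*% V_try + fk_try$F)
        rn_try <- sqrt(sum(R_try^2))
        if (is.finite(rn_try) && (rn_try < rn_old || rn_try <= tol)) break
        step_scale <- step_scale / 2
      }
      A <- A_try; V <- V_try; U <- U_try
      fk <- fk_try; R <- R_try; rn <- rn_try
    }
    if (!is.finite(rn)) break
    if (rn <= tol) {
      return(list(U = U, V = V, A = A, iterations = k + 1L, residual = rn))
    }
  }
  cond <- structure(
    class = c("musasi_newton_error", "error", "condition"),
    list(message = sprintf(
      "Newton iterations did not converge: residual %.3g after %d iterations",
      rn, max_iter),
      call = sys.call(-1), residual = rn, state = list(U = U, V = V, A = A)))
  stop(cond)
}
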