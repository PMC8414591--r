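# Molecular state codes shared with the C++ kernel.
XB_STATES <- c("N_XB", "P_XB", "N_ATP", "XB_PreR", "XB_PostR1", "XB_PostR2")
TT_STATES <- c("off", "on_Ca", "open")
.BOUND <- 3:5  # zero-based codes of the strong-binding states

#' Construct a half-sarcomere ensemble
#'
#' A half-sarcomere holds `NF` thin filaments of `NM` myosin molecules, one
#' troponin/tropomyosin (T/T) regulatory unit per molecule, and the current
#' macroscopic stretch and stretch rate.  All molecules start detached
#' (`N_XB`) and all T/T units start without calcium (`off`).
#'
#' @param params an [xb_params()] object.
#' @param lambda initial stretch (dimensionless, > 0).
#' @param lambda_dot initial stretch rate (1/ms).
#' @return an object of class `half_sarcomere`.
#' @export
half_sarcomere <- function(params, lambda = 1, lambda_dot = 0) {
  stopifnot(inherits(params, "xb_params"), lambda > 0)
  M <- params$NF * params$NM
  structure(list(
    params = params,
    state = integer(M),          # all N_XB
    x_A = rep(NA_real_, M),
    s = rep(0, M),
    lambda_A = rep(NA_real_, M),
    tt = integer(M),             # all off
    lambda = lambda,
    lambda_dot = lambda_dot
  ), class = "half_sarcomere")
}

#' @export
print.half_sarcomere <- function(x, ...) {
  frac <- state_fractions(x)
  cat(sprintf("<half_sarcomere> %d molecules, lambda = %.4f, binding ratio = %.3f\n",
              length(x$state), x$lambda, binding_ratio(x)))
  print(round(frac, 4))
  invisible(x)
}

#' State occupancy fractions of a half-sarcomere
#'
#' @param hs a [half_sarcomere()].
#' @return named numeric vector over the six molecular states (sums to 1).
#' @export
state_fractions <- function(hs) {
  stopifnot(inherits(hs, "half_sarcomere"))
  tab <- tabulate(hs$state + 1L, nbins = 6L)
  stats::setNames(tab / length(hs$state), XB_STATES)
}

#' Binding ratio (duty ratio) of a half-sarcomere
#'
#' Fraction of myosin molecules in a strong-binding state.
#'
#' @param hs a [half_sarcomere()].
#' @export
binding_ratio <- function(hs) {
  stopifnot(inherits(hs, "half_sarcomere"))
  mean(hs$state %in% .BOUND)
}

#' Current rod strains of the bound molecules
#'
#' Strain of molecule (i,j) at the current stretch:
#' `x = x_A + s + (SL0/2) * (lambda - lambda_A)`.
#'
#' @param hs a [half_sarcomere()].
#' @return numeric vector (one entry per bound molecule) with the molecular
#'   state as names.
#' @export
bound_strains <- function(hs) {
  b <- hs$state %in% .BOUND
  x <- hs$x_A[b] + hs$s[b] + (hs$params$SL0 / 2) * (hs$lambda - hs$lambda_A[b])
  stats::setNames(x, XB_STATES[hs$state[b] + 1L])
}

#' Histogram of rod strains per binding state
#'
#' Normalised densities of the current rod strains of bound molecules,
#' computed separately for each strong-binding state over the rod strain
#' domain (default bins covering -10 to 10 nm).
#'
#' @param hs a [half_sarcomere()], or a numeric vector of strains with state
#'   names as produced by [bound_strains()].
#' @param breaks bin edges (nm), strictly increasing.
#' @return a data frame with columns `state`, `mid`, `density`.
#' @export
strain_histogram <- function(hs, breaks = seq(-10, 10, by = 0.5)) {
  stopifnot(length(breaks) >= 2, all(diff(breaks) > 0))
  x <- if (inherits(hs, "half_sarcomere")) bound_strains(hs) else hs
  states <- XB_STATES[4:6]
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  out <- lapply(states, function(st) {
    xs <- x[names(x) == st]
    if (!length(xs)) {
      return(data.frame(state = character(0), mid = numeric(0),
                        density = numeric(0)))
    }
    h <- graphics::hist(xs, breaks = breaks, plot = FALSE)
    data.frame(state = st, mid = mids, density = h$density)
  })
  do.call(rbind, out)
}
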