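#' Myosin rod elasticity model
#'
#' The myosin rod is modelled as a piecewise-quadratic spring: strain energy
#' \eqn{W(x) = k_{pos} x^2/2} for non-negative strain and
#' \eqn{W(x) = k_{neg} x^2/2} for negative strain.  The form is convex for any
#' non-negative stiffnesses, which is what guarantees a non-negative active
#' stiffness in the implicit scheme.  Outside the closed strain domain the
#' rod is considered over-strained and the head is forcibly detached by the
#' Monte Carlo engine.
#'
#' @param k_pos stiffness for x >= 0 (pN/nm); default 2 pN/nm.
#' @param k_neg stiffness for x < 0 (pN/nm); must not exceed `k_pos`.
#' @param kBT thermal energy (pN nm); default 4.28 pN nm (310 K).
#' @param strain_max half-width of the admissible strain domain
#'   `[-strain_max, strain_max]` (nm); default 10 nm.
#' @return an object of class `rod_model`.
#' @examples
#' rod <- rod_model()
#' rod_energy(rod, 4)   # W = 16 pN nm, dW/dx = 8 pN
#' @export
rod_model <- function(k_pos = 2, k_neg = 1, kBT = 4.28, strain_max = 10) {
  stopifnot(k_pos >= 0, k_neg >= 0, k_neg <= k_pos, kBT > 0, strain_max > 0)
  structure(
    list(k_pos = k_pos, k_neg = k_neg, kBT = kBT, strain_max = strain_max),
    class = "rod_model"
  )
}

#' @export
print.rod_model <- function(x, ...) {
  cat(sprintf(
    "<rod_model> k_pos = %g pN/nm, k_neg = %g pN/nm, kBT = %g pN nm, |x| <= %g nm\n",
    x$k_pos, x$k_neg, x$kBT, x$strain_max))
  invisible(x)
}

#' Rod strain energy, force, and stiffness
#'
#' @param rod a [rod_model()].
#' @param x rod strain(s) (nm); must lie within the rod's strain domain.
#' @return a list with numeric vectors `W` (pN nm), `dWdx` (pN) and
#'   `d2Wdx2` (pN/nm).
#' @export
rod_energy <- function(rod, x) {
  stopifnot(inherits(rod, "rod_model"), is.numeric(x))
  if (any(!is.finite(x)) || any(abs(x) > rod$strain_max)) {
    stop("rod strain outside the admissible domain [-", rod$strain_max, ", ",
         rod$strain_max, "] nm; the head should have been detached", call. = FALSE)
  }
  k <- ifelse(x >= 0, rod$k_pos, rod$k_neg)
  list(W = 0.5 * k * x^2, dWdx = k * x, d2Wdx2 = k)
}

#' Sample an attachment strain from the rod Boltzmann distribution
#'
#' Fresh attachments take their initial strain from
#' \eqn{p(x) \propto \exp(-W(x)/k_B T)} restricted to the strain domain: a
#' two-sided (generally asymmetric) truncated Gaussian.  The sampler picks the
#' side with probability proportional to each half-Gaussian's truncated mass,
#' then draws the half-normal magnitude by rejection against the domain edge
#' (acceptance probability is the truncated mass fraction, ~1 for the default
#' parameters, so termination is immediate in practice).  A zero-stiffness rod
#' degenerates to the uniform distribution on the domain.
#'
#' @param rod a [rod_model()].
#' @param n number of draws.
#' @return numeric vector of strains (nm).
#' @export
sample_attachment_strain <- function(rod, n = 1) {
  stopifnot(inherits(rod, "rod_model"), n >= 1)
  xm <- rod$strain_max
  if (rod$k_pos == 0 && rod$k_neg == 0) {
    return(stats::runif(n, -xm, xm))
  }
  if (rod$k_pos == 0 || rod$k_neg == 0) {
    stop("one-sided zero stiffness rod has no normalisable Boltzmann weight split")
  }
  sd_pos <- sqrt(rod$kBT / rod$k_pos)
  sd_neg <- sqrt(rod$kBT / rod$k_neg)
  # truncated half-Gaussian masses
  m_pos <- sd_pos * (stats::pnorm(xm / sd_pos) - 0.5)
  m_neg <- sd_neg * (stats::pnorm(xm / sd_neg) - 0.5)
  side_pos <- stats::runif(n) < m_pos / (m_pos + m_neg)
  out <- numeric(n)
  for (i in seq_len(n)) {
    sd <- if (side_pos[i]) sd_pos else sd_neg
    repeat {
      v <- abs(stats::rnorm(1, sd = sd))
      if (v <= xm) break
    }
    out[i] <- if (side_pos[i]) v else -v
  }
  out
}
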