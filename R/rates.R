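#' Free-energy ladder of the power-stroke states
#'
#' Chemical free energies of the three strong-binding states at zero rod
#' strain, and the two power-stroke distances.  Each stroke must release free
#' energy (E0 > E1 > E2); the released chemical energy is converted into rod
#' strain energy and, via filament sliding, external work.
#'
#' Values are supplementary-material quantities treated as configuration;
#' the defaults here are fallbacks chosen so that the destination-strain-energy
#' model gives a duty ratio of order 0.1 at saturating calcium (see the
#' methods vignette).
#'
#' @param E0,E1,E2 free energies of XB_PreR, XB_PostR1, XB_PostR2 (pN nm).
#' @param s1,s2 power-stroke distances (nm).
#' @export
free_energy_ladder <- function(E0 = 0, E1 = -28, E2 = -50, s1 = 6, s2 = 4) {
  stopifnot(E0 > E1, E1 > E2, s1 > 0, s2 > 0)
  structure(list(E0 = E0, E1 = E1, E2 = E2, s1 = s1, s2 = s2),
            class = "free_energy_ladder")
}

#' Power/reverse stroke rate model (DSE or BSE)
#'
#' Two strain-dependent rate laws for the lever-arm strokes, both satisfying
#' detailed balance with respect to the total free energy
#' \eqn{\Delta G_i(x) = E_i + W(x+s_i) - E_{i-1} - W(x)}:
#'
#' * `"dse"` (destination strain energy): the forward rate is penalised by the
#'   strain energy at the destination, \eqn{h_{f,i}(x) = h_i
#'   \exp(-(W(x+s_i) - (E_{i-1}-E_i))/k_BT)}, and the reverse rate by the
#'   strain energy at the origin, \eqn{h_{b,i}(x+s_i) = h_i \exp(-W(x)/k_BT)}.
#' * `"bse"` (barrier strain energy): Kramers-type rates referencing the
#'   strain energy at the mid-stroke barrier,
#'   \eqn{h_{f,i}(x) = g_i \exp((E_{i-1} + W(x) - E_i - W(x+s_i/2))/k_BT)},
#'   \eqn{h_{b,i}(x+s_i) = g_i \exp((W(x+s_i) - W(x+s_i/2))/k_BT)}.
#'
#' Rates are capped at `r_max`; when one member of a forward/backward pair
#' exceeds the cap it is replaced by `r_max` and the other member is rescaled
#' so the detailed-balance ratio is preserved exactly ([cap_rates()]).
#'
#' @param kind `"dse"` or `"bse"`.
#' @param prefactors length-2 numeric: the stroke attempt frequencies
#'   (h1, h2) for DSE or (g1, g2) for BSE, in 1/s.  BSE defaults g1 = 20/s,
#'   g2 = 0.1/s; DSE defaults are non-supplementary fallbacks.
#' @param ladder a [free_energy_ladder()].
#' @param r_max rate cap (1/s); default 1e5/s.
#' @export
rate_model <- function(kind = c("dse", "bse"),
                       prefactors = NULL,
                       ladder = free_energy_ladder(),
                       r_max = 1e5) {
  kind <- match.arg(kind)
  if (is.null(prefactors)) {
    prefactors <- if (kind == "dse") c(3000, 3000) else c(20, 0.1)
  }
  stopifnot(length(prefactors) == 2, all(prefactors > 0), r_max > 0,
            inherits(ladder, "free_energy_ladder"))
  structure(list(kind = kind, prefactors = prefactors, ladder = ladder,
                 r_max = r_max),
            class = "rate_model")
}

#' @export
print.rate_model <- function(x, ...) {
  cat(sprintf("<rate_model> %s, prefactors = (%g, %g) 1/s, r_max = %g 1/s\n",
              toupper(x$kind), x$prefactors[1], x$prefactors[2], x$r_max))
  invisible(x)
}

#' Cap a forward/backward rate pair while preserving detailed balance
#'
#' If either rate exceeds `r_max`, both are scaled by the same factor
#' `r_max / max(h_f, h_b)` so that the larger becomes `r_max` and the ratio
#' `h_f / h_b` -- hence the Boltzmann equilibrium condition -- is preserved
#' exactly.
#'
#' @param h_f,h_b non-negative rates (1/s).
#' @param r_max cap (1/s).
#' @return list with `h_f`, `h_b`.
#' @export
cap_rates <- function(h_f, h_b, r_max) {
  stopifnot(h_f >= 0, h_b >= 0, r_max > 0)
  hi <- pmax(h_f, h_b)
  scale <- ifelse(hi > r_max, r_max / hi, 1)
  list(h_f = pmin(h_f * scale, r_max), h_b = pmin(h_b * scale, r_max))
}

#' Strain-dependent power/reverse stroke rates
#'
#' Returns the matched pair for stroke `i` evaluated at pre-stroke strain `x`:
#' the forward rate \eqn{h_{f,i}(x)} (transition x -> x + s_i) and the
#' backward rate \eqn{h_{b,i}(x + s_i)} (transition x + s_i -> x).  The pair
#' is capped together so the detailed-balance ratio
#' \eqn{h_{f,i}(x)/h_{b,i}(x+s_i) = \exp(-\Delta G_i(x)/k_BT)} survives the
#' cap exactly.
#'
#' @param model a [rate_model()].
#' @param rod a [rod_model()].
#' @param i stroke index, 1 or 2.
#' @param x pre-stroke rod strain (nm); `x` and `x + s_i` must lie in the
#'   rod strain domain.
#' @return list with `h_f`, `h_b` (1/s), vectorised over `x`.
#' @export
stroke_rates <- function(model, rod, i, x) {
  stopifnot(inherits(model, "rate_model"), inherits(rod, "rod_model"),
            i %in% c(1L, 2L))
  ld <- model$ladder
  si <- if (i == 1) ld$s1 else ld$s2
  dE <- if (i == 1) ld$E0 - ld$E1 else ld$E1 - ld$E2   # free-energy drop > 0
  if (any(abs(x) > rod$strain_max) || any(abs(x + si) > rod$strain_max)) {
    stop("stroke_rates: strain or destination strain outside rod domain")
  }
  kBT <- rod$kBT
  W <- function(z) rod_energy(rod, z)$W
  pref <- model$prefactors[i]
  if (model$kind == "dse") {
    h_f <- pref * exp(-(W(x + si) - dE) / kBT)
    h_b <- pref * exp(-W(x) / kBT)
  } else {
    Wb <- 0.5 * ifelse(x + si / 2 >= 0, rod$k_pos, rod$k_neg) * (x + si / 2)^2
    h_f <- pref * exp((dE + W(x) - Wb) / kBT)
    h_b <- pref * exp((W(x + si) - Wb) / kBT)
  }
  # non-finite exponents: overflow to Inf is resolved by the cap; underflow is 0
  h_f[is.nan(h_f)] <- 0
  h_b[is.nan(h_b)] <- 0
  h_f <- pmin(h_f, .Machine$double.xmax)
  h_b <- pmin(h_b, .Machine$double.xmax)
  cap_rates(h_f, h_b, model$r_max)
}
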