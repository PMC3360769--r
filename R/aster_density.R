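#' Radial microtubule density of a planar aster
#'
#' Number of microtubules crossing the circumference of radius `x` around the
#' centrosome, per unit arc length:
#' `m(x) = N exp(-N x / xi) / (2 pi x)`.
#' The exponent uses the linearized steady state (valid for `N << nu`), under
#' which the only kinetic dependence is through the length constant `xi` —
#' i.e. through the critical concentration and the pool size, not through the
#' rate constants individually. Setting `linearized = FALSE` substitutes the
#' exact steady-state drift; the difference is a diagnostic for leaving the
#' small-`N` regime.
#'
#' @param x Distance(s) from the centrosome, um; strictly positive (the
#'   density diverges at the centrosome itself).
#' @param N Nucleation capacity.
#' @param params A [tubulin_params()] object.
#' @param linearized Use the linearized steady state (default, as in the
#'   closed-form theory) or the exact one.
#' @return Density m(x), um^-1.
#' @export
planar_density <- function(x, N, params, linearized = TRUE) {
  stopifnot(inherits(params, "tubulin_params"), N >= 0)
  if (any(x <= 0)) {
    stop("x must be strictly positive: the planar density diverges at the ",
         "centrosome", call. = FALSE)
  }
  N * exp(-decay_rate(N, params, linearized) * x) / (2 * pi * x)
}

## spatial decay rate of the aster density, um^-1: N/xi under the
## linearized steady state, -b/a under the exact one.
decay_rate <- function(N, params, linearized = TRUE) {
  dc <- derived_constants(params)
  if (linearized) return(N / dc$xi)
  if (N == 0) return(0)
  -steady_c_exact(N, params)$b / params$a
}

#' Sensitivity of the planar density to nucleation capacity
#'
#' Derivative of [planar_density()] with respect to `N`:
#' `dm/dN = exp(-N x / xi) (1 - N x / xi) / (2 pi x)`.
#' The bracket changes sign at `N = xi / x`: adding nucleation sites raises
#' the density at `x` only up to that point, beyond which pool depletion
#' (shorter microtubules) wins.
#'
#' @inheritParams planar_density
#' @return dm/dN, um^-1.
#' @export
density_dN <- function(x, N, params) {
  stopifnot(inherits(params, "tubulin_params"), N >= 0)
  if (any(x <= 0)) stop("x must be strictly positive", call. = FALSE)
  xi <- derived_constants(params)$xi
  exp(-N * x / xi) * (1 - N * x / xi) / (2 * pi * x)
}

#' Nucleation capacity maximizing the density at a given distance
#'
#' The root of the bracket in [density_dN()]: `N_c = xi / x`, inversely
#' proportional to the distance from the centrosome. Maximizing the density
#' at one radius is paid for by lower density elsewhere.
#'
#' @inheritParams planar_density
#' @return Optimal nucleation capacity (dimensionless).
#' @export
optimal_nucleation <- function(x, params) {
  stopifnot(inherits(params, "tubulin_params"))
  if (any(x <= 0)) stop("x must be strictly positive", call. = FALSE)
  derived_constants(params)$xi / x
}

#' Probability of organelle capture by a planar aster
#'
#' An organelle of diameter `d_o` at distance `x` from the centrosome is
#' "captured" when at least one microtubule crosses the arc of length `d_o`
#' it subtends. With randomly directed microtubules the number of crossings
#' is Poisson with mean `m(x) d_o`, so
#' `P(x) = 1 - exp(-m(x) d_o)`.
#' `d_o` should be small relative to `x`, the mean microtubule length and the
#' cell size; a warning is issued when `d_o > x / 5`.
#'
#' @inheritParams planar_density
#' @param d_o Organelle diameter, um.
#' @return Capture probability in `[0, 1]`.
#' @export
capture_probability <- function(x, N, d_o, params, linearized = TRUE) {
  stopifnot(d_o > 0)
  if (any(d_o > x / 5)) {
    warning("d_o > x/5: the small-organelle arc approximation is strained",
            call. = FALSE)
  }
  -expm1(-planar_density(x, N, params, linearized) * d_o)
}
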