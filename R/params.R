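#' @keywords internal
"_PACKAGE"

## Avogadro constant, dimers per mole (2019 SI exact value)
AVOGADRO <- 6.02214076e23

#' Kinetic and cellular tubulin parameters
#'
#' Bundles the constants of the diffusion-with-drift description of
#' microtubule dynamics together with the cellular tubulin pool they draw on.
#' Internally the package works in micrometres, minutes and micromolar; the
#' cytoplasmic volume is kept in litres and converted only where concentration
#' meets dimer counts.
#'
#' @param lambda_nm Microtubule length increment per tubulin alpha-beta dimer,
#'   in nanometres. Default 0.612 nm.
#' @param a Apparent diffusion coefficient of the dynamic microtubule ends
#'   (second central moment of the length-change process), um^2/min.
#'   Default 7.5.
#' @param k Elongation rate constant, um min^-1 uM^-1. Default 1.
#' @param c_c Critical concentration of tubulin, uM. Default 11.5.
#' @param c_t Total concentration of tubulin, uM. Default 25.
#' @param V Cytoplasmic volume, litres. Default 4e-12 (a 4 pL "generic"
#'   cultured cell).
#'
#' @details A parameter set with `c_t <= c_c` (sub-critical: the whole pool
#'   sits below the critical concentration, so no polymer can persist without
#'   a length bound) is representable and merely triggers a warning here;
#'   the solvers that require a super-critical pool raise a classed error
#'   (`mtaster_subcritical_error`) when given one.
#'
#' @return An object of class `tubulin_params`: a list with elements
#'   `lambda_um`, `a`, `k`, `c_c`, `c_t`, `V`.
#' @seealso [derived_constants()], [cell_preset()]
#' @examples
#' p <- tubulin_params()
#' derived_constants(p)
#' @export
tubulin_params <- function(lambda_nm = 0.612, a = 7.5, k = 1,
                           c_c = 11.5, c_t = 25, V = 4e-12) {
  vals <- c(lambda_nm = lambda_nm, a = a, k = k, c_c = c_c, c_t = c_t, V = V)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all tubulin parameters must be finite and strictly positive",
         call. = FALSE)
  }
  if (c_t < c_c) {
    warning("sub-critical parameter set (c_t < c_c): no unbounded polymer ",
            "steady state exists", call. = FALSE)
  }
  structure(
    list(lambda_um = lambda_nm * 1e-3, a = a, k = k,
         c_c = c_c, c_t = c_t, V = V),
    class = "tubulin_params"
  )
}

#' @export
print.tubulin_params <- function(x, ...) {
  cat("Tubulin parameters (um / min / uM):\n")
  cat(sprintf("  lambda = %g nm per dimer\n", x$lambda_um * 1e3))
  cat(sprintf("  a  = %g um^2/min   k = %g um/min/uM\n", x$a, x$k))
  cat(sprintf("  c_c = %g uM   c_t = %g uM   V = %g L\n", x$c_c, x$c_t, x$V))
  invisible(x)
}

#' Named parameter presets
#'
#' `"generic"` is a 4 pL cultured animal cell; `"beroe"` uses the same
#' kinetics but the cytoplasmic volume of the ectoplasmic shell of a
#' *Beroe ovata* egg (diameter 1 mm, ectoplasm thickness 5 um), computed with
#' [ectoplasm_volume()].
#'
#' @param preset `"generic"` or `"beroe"`.
#' @param geometry Egg geometry used for the `"beroe"` volume; default
#'   [egg_geometry()].
#' @return A [tubulin_params()] object.
#' @export
cell_preset <- function(preset = c("generic", "beroe"),
                        geometry = egg_geometry()) {
  preset <- match.arg(preset)
  switch(preset,
    generic = tubulin_params(),
    beroe   = tubulin_params(V = ectoplasm_volume(geometry))
  )
}

#' Egg geometry
#'
#' Geometry of a spherical egg whose microtubules and organelles are confined
#' to a thin outer cytoplasmic shell (the ectoplasm). Defaults are the
#' *Beroe ovata* egg: 1 mm diameter, 5 um ectoplasm, 15 um female pronucleus.
#'
#' @param d_e Egg diameter, um.
#' @param h Ectoplasm thickness, um. Must be small relative to `d_e` for the
#'   thin-shell geometry to hold; a warning is issued when `h > d_e / 20`.
#' @param d_f Female pronucleus diameter, um. Must be smaller than `d_e`.
#' @return An object of class `egg_geometry`.
#' @export
egg_geometry <- function(d_e = 1000, h = 5, d_f = 15) {
  if (any(!is.finite(c(d_e, h, d_f))) || d_e <= 0 || h <= 0 || d_f <= 0) {
    stop("egg geometry fields must be finite and strictly positive",
         call. = FALSE)
  }
  if (d_f >= d_e) stop("pronucleus diameter d_f must be < egg diameter d_e",
                       call. = FALSE)
  if (h > d_e / 20) {
    warning("ectoplasm thickness h > d_e/20: thin-shell approximation is ",
            "questionable", call. = FALSE)
  }
  structure(list(d_e = d_e, h = h, d_f = d_f), class = "egg_geometry")
}

#' @export
print.egg_geometry <- function(x, ...) {
  cat(sprintf("Egg geometry: d_e = %g um, h = %g um, d_f = %g um\n",
              x$d_e, x$h, x$d_f))
  cat(sprintf("  ectoplasm volume = %.4g L\n", ectoplasm_volume(x)))
  invisible(x)
}

#' Ectoplasm volume of a spherical egg
#'
#' Volume of the thin cytoplasmic shell under the egg surface,
#' `pi * d_e^2 * h`, converted from cubic micrometres to litres
#' (1 um^3 = 1e-15 L). For the default *Beroe* geometry this is 15.7 nL.
#'
#' @param geometry An [egg_geometry()] object.
#' @return Volume in litres.
#' @examples
#' ectoplasm_volume(egg_geometry())  # 1.57e-8 L = 15.7 nL
#' @export
ectoplasm_volume <- function(geometry) {
  stopifnot(inherits(geometry, "egg_geometry"))
  pi * geometry$d_e^2 * geometry$h * 1e-15
}

#' Derived natural constants of the tubulin system
#'
#' The steady-state theory collapses the raw parameters into three compound
#' constants:
#' \describe{
#'   \item{xi}{length, um: the total microtubule length the cell would hold if
#'     the free tubulin concentration sat exactly at the critical one;
#'     `xi = lambda * (c_t - c_c) * N_A * V` with the concentration converted
#'     to moles.}
#'   \item{chi}{length, um: the mean microtubule length the aster would have
#'     if the drift were set by the full super-critical pool;
#'     `chi = a / (k * (c_t - c_c))`.}
#'   \item{nu}{dimensionless: the natural unit of nucleation capacity,
#'     `nu = xi / chi`. Nucleation capacities small compared with `nu` barely
#'     perturb the free tubulin concentration.}
#' }
#' The three satisfy the identity `nu * chi == xi` by construction.
#'
#' @param params A [tubulin_params()] object.
#' @return An object of class `derived_constants`: list with `nu`, `xi`,
#'   `chi`, `dimers_above_critical` (the dimer count corresponding to
#'   `c_t - c_c` in volume `V`).
#' @examples
#' derived_constants(cell_preset("beroe"))  # nu ~ 1.4e8
#' @export
derived_constants <- function(params) {
  stopifnot(inherits(params, "tubulin_params"))
  if (params$c_t < params$c_c) {
    stop(structure(
      class = c("mtaster_subcritical_error", "error", "condition"),
      list(message = paste0(
             "sub-critical parameter set (c_t = ", params$c_t, " < c_c = ",
             params$c_c, " uM): nu and xi are undefined"),
           call = sys.call(-1))
    ))
  }
  excess <- params$c_t - params$c_c             # uM
  dimers <- excess * 1e-6 * AVOGADRO * params$V # count
  xi  <- params$lambda_um * dimers              # um
  chi <- params$a / (params$k * excess)         # um; Inf when c_t == c_c
  structure(
    list(nu = xi / chi, xi = xi, chi = chi, dimers_above_critical = dimers),
    class = "derived_constants"
  )
}

#' @export
print.derived_constants <- function(x, ...) {
  cat(sprintf("Derived constants: nu = %.4g (dimensionless)\n", x$nu))
  cat(sprintf("  xi = %.4g um   chi = %.4g um   (nu * chi = xi)\n",
              x$xi, x$chi))
  cat(sprintf("  dimers above critical = %.4g\n", x$dimers_above_critical))
  invisible(x)
}
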