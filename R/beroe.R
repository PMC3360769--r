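#' Fertilized-egg scenario
#'
#' Couples an [egg_geometry()] with tubulin kinetics whose pool volume is the
#' ectoplasmic shell of that egg. All microtubules in the egg — the maternal
#' acentrosomal ones (`N_f`) and every sperm aster — draw on this one pool,
#' so they share a single steady-state concentration; only the microtubules
#' radiating from a given sperm centrosome contribute to that aster's spatial
#' density.
#'
#' @param geometry An [egg_geometry()] object; default the *Beroe ovata* egg.
#' @param params Optional [tubulin_params()]; by default the standard
#'   kinetics with `V = ectoplasm_volume(geometry)`. If supplied, `V` should
#'   match the geometry (not enforced, for what-if analyses).
#' @return An object of class `egg_scenario` with elements `geometry`,
#'   `params`, and the derived `xi` (um).
#' @export
egg_scenario <- function(geometry = egg_geometry(), params = NULL) {
  stopifnot(inherits(geometry, "egg_geometry"))
  if (is.null(params)) {
    params <- tubulin_params(V = ectoplasm_volume(geometry))
  }
  stopifnot(inherits(params, "tubulin_params"))
  structure(
    list(geometry = geometry, params = params,
         xi = derived_constants(params)$xi),
    class = "egg_scenario"
  )
}

#' @export
print.egg_scenario <- function(x, ...) {
  cat("Egg scenario:\n")
  print(x$geometry)
  cat(sprintf("  xi = %.4g um,  nu = %.4g\n", x$xi,
              derived_constants(x$params)$nu))
  invisible(x)
}

check_microtubule_count <- function(n, name) {
  if (n > 0 && (n < 1e2 || n > 1e6)) {
    warning(name, " = ", format(n), " lies outside the plausible range ",
            "[1e2, 1e6] for the egg", call. = FALSE)
  }
  invisible(n)
}

#' Microtubule density of a sperm aster on the egg surface
#'
#' Density of one aster's microtubules at geodesic distance `x` from its
#' centrosome, with microtubules running within the spherical ectoplasm:
#' `m(x) = N_own exp(-N_total x / xi) / (pi d_e sin(2 x / d_e))`.
#' The denominator is the circumference at geodesic distance `x` on a sphere
#' of diameter `d_e` (it reduces to `2 pi x` near the centrosome). The
#' exponent carries the total nucleation capacity `N_total` competing for the
#' pool; the numerator only the microtubules of the aster in question.
#' Distances at or beyond the antipodal half-circumference `pi d_e / 2` are
#' outside the model (microtubules longer than half the circumference are
#' excluded).
#'
#' @param x Geodesic distance(s) from the sperm centrosome, um, in
#'   `(0, pi d_e / 2)`.
#' @param N_own Microtubule count of the aster itself.
#' @param N_total Total nucleation capacity in the egg (`>= N_own`);
#'   e.g. `N_f + N_m` for a single aster, `N_f + n N_a` under polyspermy.
#' @param scenario An [egg_scenario()].
#' @return Density, um^-1.
#' @export
spherical_density <- function(x, N_own, N_total, scenario) {
  stopifnot(inherits(scenario, "egg_scenario"),
            N_own >= 0, N_total >= N_own)
  d_e <- scenario$geometry$d_e
  if (any(x <= 0) || any(x >= pi * d_e / 2)) {
    stop("x must lie strictly inside (0, pi*d_e/2): microtubules longer ",
         "than half the egg circumference are outside the model",
         call. = FALSE)
  }
  N_own * exp(-N_total * x / scenario$xi) / (pi * d_e * sin(2 * x / d_e))
}

#' Distribution of the centrosome-to-pronucleus geodesic distance
#'
#' With the sperm entry point uniform over the egg surface, the geodesic
#' distance between the sperm centrosome and the female pronucleus has
#' probability density `sin(2 x / d_e) / d_e` on `[0, pi d_e / 2]` — zero at
#' the poles, maximal at the equator.
#'
#' @param x Geodesic distance(s), um, in `[0, pi d_e / 2]`.
#' @param geometry An [egg_geometry()].
#' @return Density, um^-1.
#' @export
distance_pdf <- function(x, geometry) {
  stopifnot(inherits(geometry, "egg_geometry"))
  d_e <- geometry$d_e
  if (any(x < 0) || any(x > pi * d_e / 2)) {
    stop("x must lie in [0, pi*d_e/2]", call. = FALSE)
  }
  sin(2 * x / d_e) / d_e
}

## integrate P(x) * distance_pdf(x) over the half-circumference; the
## integrand tends to 0 at both endpoints (the pdf vanishes there).
capture_quadrature <- function(N_own, N_total, scenario) {
  d_e <- scenario$geometry$d_e
  d_f <- scenario$geometry$d_f
  xi  <- scenario$xi
  f <- function(x) {
    m <- N_own * exp(-N_total * x / xi) / (pi * d_e * sin(2 * x / d_e))
    val <- -expm1(-m * d_f) * sin(2 * x / d_e) / d_e
    val[!is.finite(val) | x <= 0 | x >= pi * d_e / 2] <- 0
    val
  }
  q <- tryCatch(
    stats::integrate(f, 0, pi * d_e / 2, rel.tol = 1e-8, abs.tol = 1e-12,
                     subdivisions = 1000L),
    error = function(e) stop("capture quadrature failed: ",
                             conditionMessage(e), call. = FALSE)
  )
  structure(list(P = min(q$value, 1), quad_error = q$abs.error,
                 subdivisions = q$subdivisions),
            class = "capture_result")
}

#' @export
print.capture_result <- function(x, ...) {
  cat(sprintf("Capture probability P = %.6g (quadrature error %.2g)\n",
              x$P, x$quad_error))
  invisible(x)
}

#' Total probability of female pronucleus capture (monospermy)
#'
#' Probability that the sperm aster captures the randomly positioned female
#' pronucleus, marginalized over the entry geometry: the capture probability
#' at distance `x` (Poisson crossing of an arc of length `d_f`) integrated
#' against the geodesic-distance density, by adaptive quadrature at relative
#' tolerance 1e-8.
#'
#' @param N_m Microtubules in the sperm aster (its nucleation capacity).
#' @param N_f Acentrosomal (maternal) microtubule count; enters only through
#'   pool competition in the exponent.
#' @param scenario An [egg_scenario()].
#' @return A `capture_result`: list with `P` and `quad_error`.
#' @export
total_capture <- function(N_m, N_f, scenario = egg_scenario()) {
  stopifnot(inherits(scenario, "egg_scenario"), N_m >= 0, N_f >= 0)
  check_microtubule_count(N_m, "N_m")
  check_microtubule_count(N_f, "N_f")
  if (N_m == 0) {
    return(structure(list(P = 0, quad_error = 0, subdivisions = 0L),
                     class = "capture_result"))
  }
  capture_quadrature(N_m, N_f + N_m, scenario)
}

#' Per-aster capture probability under polyspermy
#'
#' Probability that one given aster, out of `n` identical sperm asters each
#' of `N_a` microtubules, captures the female pronucleus. All `n * N_a`
#' aster microtubules plus the `N_f` maternal ones deplete the shared pool,
#' but only the given aster's `N_a` count toward its own density.
#'
#' @param N_a Microtubules per sperm aster.
#' @param n Number of sperm (asters), a positive integer.
#' @param N_f Acentrosomal microtubule count.
#' @param scenario An [egg_scenario()].
#' @return A `capture_result`.
#' @export
per_aster_capture <- function(N_a, n, N_f, scenario = egg_scenario()) {
  stopifnot(inherits(scenario, "egg_scenario"),
            N_a >= 0, N_f >= 0, n >= 1, n == round(n))
  check_microtubule_count(N_a, "N_a")
  if (N_a == 0) {
    return(structure(list(P = 0, quad_error = 0, subdivisions = 0L),
                     class = "capture_result"))
  }
  capture_quadrature(N_a, N_f + n * N_a, scenario)
}

#' Optimal sperm nucleation capacity
#'
#' Maximizes the per-aster capture probability over the aster's nucleation
#' capacity by a logarithmic grid scan (25 points per decade) followed by
#' golden-section refinement around the best grid point. When capture is
#' essentially certain over a wide range, the maximum is a plateau rather
#' than a point: the set of capacities within 1e-3 of the maximum is
#' reported, the plateau flag is set when it spans more than one decade, and
#' the reported argmax is then the geometric midpoint of the plateau (a
#' single representative value with honest width).
#'
#' @param n Number of sperm asters.
#' @param N_f Acentrosomal microtubule count.
#' @param scenario An [egg_scenario()].
#' @param search_range Search interval for `log10(N)`; default `c(1, 8)`.
#' @return An object of class `aster_optimum`: list with `argmax_N`,
#'   `P_max`, `plateau` (logical), `plateau_lo`, `plateau_hi`.
#' @export
optimal_sperm_nucleation <- function(n, N_f, scenario = egg_scenario(),
                                     search_range = c(1, 8)) {
  stopifnot(inherits(scenario, "egg_scenario"),
            length(search_range) == 2, diff(search_range) > 0)
  objective <- function(logN) {
    suppressWarnings(per_aster_capture(10^logN, n, N_f, scenario))$P
  }
  grid <- seq(search_range[1], search_range[2],
              by = 1 / 25)                     # 25 points per decade
  vals <- vapply(grid, objective, numeric(1))
  P_max <- max(vals)
  if (P_max <= 0) {
    return(structure(
      list(argmax_N = 10^mean(search_range), P_max = 0, plateau = TRUE,
           plateau_lo = 10^search_range[1], plateau_hi = 10^search_range[2]),
      class = "aster_optimum"))
  }
  i_best <- which.max(vals)
  lo <- grid[max(1L, i_best - 1L)]
  hi <- grid[min(length(grid), i_best + 1L)]
  opt <- stats::optimize(objective, lower = lo, upper = hi,
                         maximum = TRUE, tol = 1e-4)
  P_max <- max(P_max, opt$objective)
  near <- grid[vals >= P_max - 1e-3]
  plateau_lo <- if (length(near)) 10^min(near) else 10^opt$maximum
  plateau_hi <- if (length(near)) 10^max(near) else 10^opt$maximum
  plateau <- log10(plateau_hi / plateau_lo) > 1
  argmax <- if (plateau) sqrt(plateau_lo * plateau_hi) else 10^opt$maximum
  structure(
    list(argmax_N = argmax, P_max = P_max, plateau = plateau,
         plateau_lo = plateau_lo, plateau_hi = plateau_hi),
    class = "aster_optimum")
}

#' @export
print.aster_optimum <- function(x, ...) {
  cat(sprintf("Optimal nucleation capacity: N = %.4g (P = %.4g)\n",
              x$argmax_N, x$P_max))
  if (x$plateau) {
    cat(sprintf("  plateau: [%.4g, %.4g] (argmax is its geometric midpoint)\n",
                x$plateau_lo, x$plateau_hi))
  }
  invisible(x)
}
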