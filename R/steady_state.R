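#' Drift of microtubule ends at a given free tubulin concentration
#'
#' First moment of the length-change process: `b = k * (c - c_c)`, um/min.
#' Negative drift (net shortening) is meaningful and required for an
#' unbounded steady state.
#'
#' @param c Free tubulin concentration, uM. May be a vector.
#' @param params A [tubulin_params()] object.
#' @return Drift in um/min.
#' @export
drift <- function(c, params) {
  stopifnot(inherits(params, "tubulin_params"), all(c >= 0))
  params$k * (c - params$c_c)
}

## mean of the truncated-exponential length density on [0, R],
## density proportional to exp(beta * x) with beta = b / a.
## Stable for beta * R -> 0 (-> R/2) and beta * R -> -Inf (-> -1/beta).
mean_length_bounded <- function(b, a, R) {
  beta <- b / a
  t <- beta * R
  if (abs(t) < 1e-6) {
    # E/R = 1/2 + t/12 - t^3/720 + ...
    return(R * (0.5 + t / 12))
  }
  if (t < -700) return(-1 / beta)      # exp(t) underflows; exact tail limit
  if (t > 700) return(R * (1 - 1 / t)) # exp(t) overflows; asymptotic form
  R * (t * exp(t) - expm1(t)) / (t * expm1(t))
}

#' Steady-state microtubule length density
#'
#' Probability density of microtubule length `x` at free tubulin
#' concentration `c`. With no length bound (`R = Inf`) the density is the
#' normalized exponential `p(x) = (-b/a) exp(b x / a)` with mean `-a/b`,
#' which requires `b < 0` (free tubulin below critical). With a finite bound
#' `R` (microtubules abutting on the cell margin) the density is the
#' truncated exponential on `[0, R]`, with the `b -> 0` limit `1/R` taken
#' analytically.
#'
#' @param x Length(s), um, in `[0, R]`.
#' @param c Free tubulin concentration, uM.
#' @param params A [tubulin_params()] object.
#' @param R Length bound in um, or `Inf` (default) for unbounded growth.
#' @return Density values, um^-1.
#' @export
length_density <- function(x, c, params, R = Inf) {
  stopifnot(inherits(params, "tubulin_params"))
  if (any(x < 0) || any(x > R)) stop("x must lie in [0, R]", call. = FALSE)
  b <- drift(c, params)
  beta <- b / params$a
  if (is.infinite(R)) {
    if (b >= 0) {
      stop("unbounded length density requires negative drift: the ",
           "steady-state concentration must be lower than the critical one",
           call. = FALSE)
    }
    return(-beta * exp(beta * x))
  }
  if (abs(beta * R) < 1e-12) return(rep(1 / R, length(x)))
  beta * exp(beta * x) / expm1(beta * R)
}

new_steady_state <- function(c, params, N, method, R = Inf, residual = NA_real_) {
  # not drift(): the linear law's analytic continuation can dip below c = 0
  # far outside its validity range, and the record should still be printable
  b <- params$k * (c - params$c_c)
  mean_len <- if (is.infinite(R)) {
    if (b < 0) -params$a / b else Inf
  } else {
    mean_length_bounded(b, params$a, R)
  }
  structure(
    list(c = c, b = b, mean_length = mean_len, N = N,
         method = method, R = R, residual = residual),
    class = "steady_state"
  )
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("Steady state (%s%s): N = %g\n", x$method,
              if (is.finite(x$R)) sprintf(", R = %g um", x$R) else "", x$N))
  cat(sprintf("  c = %.6g uM   b = %.4g um/min   mean length = %.4g um\n",
              x$c, x$b, x$mean_length))
  if (!is.na(x$residual)) {
    cat(sprintf("  conservation residual = %.3g uM\n", x$residual))
  }
  invisible(x)
}

subcritical_stop <- function(params) {
  stop(structure(
    class = c("mtaster_subcritical_error", "error", "condition"),
    list(message = paste0("requires a super-critical pool (c_t > c_c); got ",
                          "c_t = ", params$c_t, ", c_c = ", params$c_c, " uM"),
         call = sys.call(-2))
  ))
}

#' Exact steady-state free tubulin concentration (unbounded growth)
#'
#' Closed-form solution of tubulin conservation when microtubule length is
#' not limited by the cell boundary. The normalized deviation of the steady
#' state from critical obeys
#' `(c_c - c) / (c_t - c_c) = (sqrt(1 + 4 N / nu) - 1) / 2`,
#' the physical root of the quadratic conservation law (the root with the
#' plus sign would put `c` above critical, where no unbounded steady state
#' exists). At `N = 0` the limit `c = c_c` is returned.
#'
#' @param N Nucleation capacity (number of nucleation sites; unoccupied sites
#'   count as zero-length microtubules). Treated as a continuous
#'   non-negative real.
#' @param params A [tubulin_params()] object with `c_t > c_c`.
#' @return A `steady_state` object (`method = "exact"`).
#' @seealso [steady_c_linear()], [steady_c_bounded()]
#' @export
steady_c_exact <- function(N, params) {
  stopifnot(inherits(params, "tubulin_params"), N >= 0)
  if (params$c_t <= params$c_c) subcritical_stop(params)
  dc <- derived_constants(params)
  u <- (sqrt(1 + 4 * N / dc$nu) - 1) / 2
  c <- params$c_c - (params$c_t - params$c_c) * u
  new_steady_state(c, params, N, "exact")
}

#' Linearized steady-state free tubulin concentration
#'
#' Small-`N` approximation `(c_c - c)/(c_t - c_c) = N / nu`, valid when `N`
#' is small compared with `nu`; it is the tangent of the exact law at
#' `N = 0`, whose slope there is `-1/nu`.
#'
#' @inheritParams steady_c_exact
#' @return A `steady_state` object (`method = "linear"`).
#' @export
steady_c_linear <- function(N, params) {
  stopifnot(inherits(params, "tubulin_params"), N >= 0)
  if (params$c_t <= params$c_c) subcritical_stop(params)
  dc <- derived_constants(params)
  c <- params$c_c - (params$c_t - params$c_c) * N / dc$nu
  new_steady_state(c, params, N, "linear")
}

#' Tubulin conservation residual
#'
#' The conservation function `F(c) = c + polymer(c) - c_t` in uM, where
#' `polymer(c)` is the concentration equivalent of `N` microtubules of mean
#' length `E[x | c, R]` (truncated-exponential mean for finite `R`, `-a/b`
#' for `R = Inf`). `F` is strictly increasing in `c` and zero at a true
#' steady state; it is the objective the bounded solver roots.
#'
#' @param c Free tubulin concentration, uM.
#' @param N Nucleation capacity.
#' @param params A [tubulin_params()] object.
#' @param R Length bound, um, or `Inf`.
#' @return Residual in uM. For `R = Inf` and `c >= c_c` with `N > 0` the
#'   polymer demand is unbounded and `Inf` is returned.
#' @export
conservation_residual <- function(c, N, params, R = Inf) {
  stopifnot(inherits(params, "tubulin_params"), c >= 0, N >= 0)
  if (N == 0) return(c - params$c_t)
  b <- drift(c, params)
  if (is.infinite(R)) {
    if (b >= 0) return(Inf)
    mean_len <- -params$a / b
  } else {
    mean_len <- mean_length_bounded(b, params$a, R)
  }
  polymer_uM <- N * mean_len / params$lambda_um * 1e6 / (AVOGADRO * params$V)
  c + polymer_uM - params$c_t
}

#' Numerical steady state with a microtubule length bound
#'
#' Solves the tubulin conservation equation for the steady-state free
#' tubulin concentration when microtubule length is capped at `R` (radial
#' microtubules abutting on the cell margin). The conservation function is
#' strictly increasing in `c`, so the root in `[0, c_t]` is unique; it is
#' found by bracketing (bisection-safeguarded interpolation,
#' [stats::uniroot()]) to a relative tolerance of 1e-10. With a length bound
#' the steady state can sit at or above the critical concentration, which is
#' why this case has no closed form.
#'
#' @inheritParams steady_c_exact
#' @param R Length bound, um (finite, positive).
#' @return A `steady_state` object (`method = "bounded"`) whose `residual`
#'   element records the conservation residual at the returned root.
#' @export
steady_c_bounded <- function(N, R, params) {
  stopifnot(inherits(params, "tubulin_params"), N >= 0,
            is.finite(R), R > 0)
  if (N == 0) {
    return(new_steady_state(params$c_t, params, 0, "bounded", R,
                            residual = 0))
  }
  f <- function(c) conservation_residual(c, N, params, R)
  lo <- f(0)
  if (lo >= 0) {
    stop("no steady state with non-negative free tubulin: polymer demand ",
         "exceeds the total pool even at c = 0 (N too large for this cell)",
         call. = FALSE)
  }
  # tolerance well below 1e-10 relative: uniroot's tol is on c, and the
  # conservation function can be steep, so the residual needs headroom
  root <- stats::uniroot(f, lower = 0, upper = params$c_t,
                         f.lower = lo, f.upper = f(params$c_t),
                         tol = max(1e-14 * params$c_t,
                                   4 * .Machine$double.eps),
                         maxiter = 1000L)
  new_steady_state(root$root, params, N, "bounded", R,
                   residual = f(root$root))
}
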