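#' Configuration of the stochastic length simulator
#'
#' @param M Number of simulated microtubules in the ensemble. When `M` is
#'   smaller than the nucleation capacity `N` being modelled, the pool
#'   feedback is scaled by `N/M` so that the concentration dynamics match
#'   `N` real microtubules (valid because the pool couples only through the
#'   ensemble mean length).
#' @param dt Euler-Maruyama time step, min.
#' @param t_total Simulated duration, min.
#' @param burn_in Fraction of the run discarded before collecting
#'   stationary statistics, in `[0, 1)`.
#' @param seed Integer RNG seed; identical seeds give bit-identical results.
#' @param R Optional length bound, um (`Inf` for unbounded).
#' @param c_clamp Optional fixed free tubulin concentration, uM; when set,
#'   pool feedback is disabled and every microtubule sees constant drift.
#' @param sample_every Interval between recorded snapshots, min.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(M = 500, dt = 1e-3, t_total = 200, burn_in = 0.5,
                       seed = 1, R = Inf, c_clamp = NULL,
                       sample_every = 0.25) {
  stopifnot(M >= 1, dt > 0, t_total > dt, burn_in >= 0, burn_in < 1,
            R > 0, sample_every >= dt)
  structure(
    list(M = as.integer(M), dt = dt, t_total = t_total, burn_in = burn_in,
         seed = as.integer(seed), R = R, c_clamp = c_clamp,
         sample_every = sample_every),
    class = "sim_config")
}

#' Stochastic simulation of microtubule lengths sharing a tubulin pool
#'
#' Simulates `config$M` microtubule lengths as reflected drift-diffusion
#' processes by the Euler-Maruyama scheme: each step,
#' `dx = b(c) dt + sqrt(2 a dt) z` with standard normal `z`, reflection at 0
#' (unoccupied nucleation sites are zero-length microtubules) and, if
#' bounded, at `R`. After every step the free concentration is recomputed
#' from conservation, `c = c_t - (N/M) * sum(lengths) / lambda` in
#' concentration units, unless `c_clamp` fixes it. The stationary density of
#' this process at clamped `c < c_c` is the exponential with mean `-a/b`,
#' which is the analytical length density being verified.
#'
#' @param params A [tubulin_params()] object.
#' @param N Nucleation capacity represented by the ensemble.
#' @param config A [sim_config()].
#' @return An object of class `sim_result`: list with `c_mean`, `c_se`
#'   (batch-means standard error), `mean_length`, `mean_length_se`,
#'   `final_lengths` (the last snapshot, one value per simulated
#'   microtubule), `samples` (all post-burn-in snapshot lengths, pooled),
#'   `c_series` and `times` (snapshot trace), `polymer_fraction`, and
#'   `config`.
#' @export
simulate_lengths <- function(params, N, config = sim_config()) {
  stopifnot(inherits(params, "tubulin_params"), N >= 0,
            inherits(config, "sim_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(config$seed)

  M <- config$M
  dt <- config$dt
  n_steps <- ceiling(config$t_total / dt)
  snap_stride <- max(1L, round(config$sample_every / dt))
  sigma <- sqrt(2 * params$a * dt)
  clamped <- !is.null(config$c_clamp)
  ## uM of free tubulin bound in one um of one represented microtubule
  uM_per_um <- (N / M) * 1e6 / (params$lambda_um * AVOGADRO * params$V)

  x <- numeric(M)                       # all sites start unoccupied
  c_free <- if (clamped) config$c_clamp else params$c_t
  burn_steps <- floor(config$burn_in * n_steps)
  snaps_c <- numeric(0); snaps_t <- numeric(0)
  snap_lengths <- list()

  for (step in seq_len(n_steps)) {
    b <- params$k * (c_free - params$c_c)
    x <- x + b * dt + sigma * stats::rnorm(M)
    x <- abs(x)                         # reflect at 0
    if (is.finite(config$R)) x <- config$R - abs(config$R - x)
    if (!clamped && N > 0) {
      c_free <- params$c_t - uM_per_um * sum(x)
      if (c_free < 0) {
        stop("free tubulin concentration driven below zero; use a smaller ",
             "dt (the discrete step overshot the pool)", call. = FALSE)
      }
    }
    if (step > burn_steps && step %% snap_stride == 0L) {
      snaps_c <- c(snaps_c, c_free)
      snaps_t <- c(snaps_t, step * dt)
      snap_lengths[[length(snap_lengths) + 1L]] <- x
    }
  }
  if (!length(snap_lengths)) {
    stop("no post-burn-in snapshots recorded; lengthen t_total or reduce ",
         "sample_every", call. = FALSE)
  }
  lengths_mat <- do.call(rbind, snap_lengths)   # snapshots x M
  snap_means <- rowMeans(lengths_mat)
  polymer_uM <- uM_per_um * sum(x)
  structure(
    list(c_mean = mean(snaps_c), c_se = batch_se(snaps_c),
         mean_length = mean(snap_means), mean_length_se = batch_se(snap_means),
         final_lengths = x,
         samples = as.vector(lengths_mat),
         c_series = snaps_c, times = snaps_t,
         polymer_fraction = if (clamped) NA_real_ else polymer_uM / params$c_t,
         N = N, config = config),
    class = "sim_result")
}

## batch-means standard error for an autocorrelated series
batch_se <- function(x, n_batches = 10L) {
  n_batches <- min(n_batches, length(x))
  if (n_batches < 2L) return(NA_real_)
  batches <- split(x, cut(seq_along(x), n_batches, labels = FALSE))
  means <- vapply(batches, mean, numeric(1))
  stats::sd(means) / sqrt(length(means))
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("Stochastic ensemble (M = %d, N = %g, seed = %d):\n",
              x$config$M, x$N, x$config$seed))
  cat(sprintf("  c = %.5g +/- %.2g uM   mean length = %.4g +/- %.2g um\n",
              x$c_mean, x$c_se, x$mean_length, x$mean_length_se))
  if (!is.na(x$polymer_fraction)) {
    cat(sprintf("  polymer fraction of pool = %.3g\n", x$polymer_fraction))
  }
  invisible(x)
}

#' Compare the stochastic simulator with the analytical steady state
#'
#' Runs [simulate_lengths()] with pool feedback and checks that the
#' time-averaged free concentration agrees with the analytical solver —
#' [steady_c_exact()] when unbounded, [steady_c_bounded()] when a length
#' bound is set — within `z_max` batch-means standard errors.
#'
#' @inheritParams simulate_lengths
#' @param z_max Agreement threshold in standard errors (default 3).
#' @return A list with `c_sim`, `c_se`, `c_analytic`, `z`, `pass`, `method`,
#'   and the full `sim_result`.
#' @export
compare_to_analytic <- function(params, N, config = sim_config(),
                                z_max = 3) {
  stopifnot(is.null(config$c_clamp))
  sim <- simulate_lengths(params, N, config)
  analytic <- if (is.finite(config$R)) {
    steady_c_bounded(N, config$R, params)
  } else {
    steady_c_exact(N, params)
  }
  z <- if (N == 0) 0 else (sim$c_mean - analytic$c) / sim$c_se
  list(c_sim = sim$c_mean, c_se = sim$c_se, c_analytic = analytic$c,
       z = z, pass = abs(z) <= z_max, method = analytic$method, sim = sim)
}
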