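test_that("spherical density reduces to the planar one near the centrosome", {
  scen <- egg_scenario()
  N_m <- 1e4
  for (x in c(1, 0.1, 0.01)) {
    ratio <- spherical_density(x, N_m, N_m, scen) /
      planar_density(x, N_m, scen$params)
    expect_equal(ratio, 1, tolerance = (2 * x / scen$geometry$d_e)^2)
  }
  # at the equator the circumference is exactly pi * d_e
  x_eq <- pi * scen$geometry$d_e / 4
  xi <- scen$xi
  expect_equal(spherical_density(x_eq, 1e4, 1.01e4, scen),
               1e4 * exp(-1.01e4 * x_eq / xi) / (pi * 1000))
  expect_equal(spherical_density(x_eq, 1e4, 1.01e4, scen), 2.875877,
               tolerance = 1e-6)
  expect_error(spherical_density(pi * 1000 / 2, 1e4, 1e4, scen),
               "half the egg circumference")
  expect_error(spherical_density(-1, 1e4, 1e4, scen), "inside")
})

test_that("centrosome-to-pronucleus distance is sine-distributed on the sphere", {
  g <- egg_geometry()
  expect_equal(stats::integrate(function(x) distance_pdf(x, g),
                                0, pi * g$d_e / 2)$value, 1,
               tolerance = 1e-8)
  expect_equal(distance_pdf(c(0, pi * g$d_e / 2), g), c(0, 0))
  # mode at the equator
  x <- seq(1, pi * g$d_e / 2 - 1, length.out = 501)
  expect_equal(x[which.max(distance_pdf(x, g))], pi * g$d_e / 4,
               tolerance = 1e-2)
  expect_error(distance_pdf(2000, g), "lie in")
})

test_that("total capture probability integrates the capture-times-distance product", {
  scen <- egg_scenario()
  expect_equal(total_capture(0, 1e2, scen)$P, 0)
  res <- total_capture(1e4, 1e2, scen)
  expect_gt(res$P, 0.99)
  expect_lt(res$quad_error, 1e-6)
  # frozen independent quadrature value on the rising flank
  expect_equal(total_capture(1e3, 1e2, scen)$P, 0.995716, tolerance = 1e-5)
  # agrees with a finer independent quadrature to 1e-6 relative
  d_e <- scen$geometry$d_e
  f <- function(x) {
    m <- spherical_density(x, 1e3, 1e2 + 1e3, scen)
    (1 - exp(-m * scen$geometry$d_f)) * distance_pdf(x, scen$geometry)
  }
  fine <- stats::integrate(f, 1e-9, pi * d_e / 2 - 1e-9,
                           rel.tol = 1e-10, subdivisions = 4000L)$value
  expect_equal(total_capture(1e3, 1e2, scen)$P, fine, tolerance = 1e-6)
  # a larger pronucleus is easier to catch
  P_small <- total_capture(2e5, 3e5, egg_scenario(egg_geometry(d_f = 10)))$P
  P_large <- total_capture(2e5, 3e5, egg_scenario(egg_geometry(d_f = 20)))$P
  expect_gt(P_large, P_small)
})

test_that("per-aster capture is consistent with the single-aster case and falls with n", {
  scen <- egg_scenario()
  expect_equal(per_aster_capture(2e4, 1, 3e5, scen)$P,
               total_capture(2e4, 3e5, scen)$P)
  P_n <- vapply(c(1, 3, 6, 9), function(n)
    per_aster_capture(3e4, n, 3e5, scen)$P, numeric(1))
  expect_true(all(diff(P_n) < 0))
  # pool-competition identity: the other n-1 asters act exactly like
  # additional acentrosomal microtubules
  for (n in c(2, 5)) {
    expect_equal(per_aster_capture(3e4, n, 1e5, scen)$P,
                 suppressWarnings(
                   total_capture(3e4, 1e5 + (n - 1) * 3e4, scen))$P)
  }
  # n -> large at fixed N_a: the shared pool is drained and P_a -> 0;
  # the egg's xi ~ 8e7 um is so large that this takes n*N_a ~ 1e8
  expect_lt(per_aster_capture(100, 1e6, 1e5, scen)$P, 1e-4)
})

test_that("optimal sperm nucleation: plateau at low N_f, sharp optimum at high N_f", {
  scen <- egg_scenario()
  low <- optimal_sperm_nucleation(1, 1e2, scen)
  expect_true(low$plateau)
  expect_gt(low$P_max, 0.99)
  # the near-certainty band spans more than a decade inside [1e3, 1e6]
  expect_gt(log10(low$plateau_hi / low$plateau_lo), 1)
  expect_gt(low$plateau_lo, 1e3 / 2)
  expect_lt(low$plateau_hi, 1e6)
  expect_true(low$plateau_lo <= low$argmax_N && low$argmax_N <= low$plateau_hi)

  high <- optimal_sperm_nucleation(1, 1e6, scen)
  expect_false(high$plateau)
  expect_lt(high$P_max, 0.5)
  expect_gt(high$P_max, 0.05)
  expect_gt(high$argmax_N, 1e4)      # interior maximum, not at an edge
  expect_lt(high$argmax_N, 1e7)
})

test_that("competition from other sperm lowers the optimal nucleation capacity", {
  scen <- egg_scenario()
  opts <- lapply(c(1, 3, 9), function(n)
    optimal_sperm_nucleation(n, 3e5, scen))
  argmax <- vapply(opts, `[[`, numeric(1), "argmax_N")
  expect_true(all(diff(argmax) < 0))
  P_max <- vapply(opts, `[[`, numeric(1), "P_max")
  expect_true(all(diff(P_max) < 0))
})
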