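test_that("drift is linear in the deviation from critical", {
  p <- generic()
  expect_equal(drift(p$c_c, p), 0)
  expect_equal(drift(12.5, p), 1.0)
  expect_equal(drift(10.0, p), -1.5)
})

test_that("length density is the (truncated) exponential and normalizes", {
  p <- generic()  # a = 7.5, k = 1, c_c = 11.5
  # unbounded: p(0) = -b/a with b = -1 at c = 10.5
  expect_equal(length_density(0, 10.5, p), 1 / 7.5)
  expect_error(length_density(0, p$c_c, p),
               "lower than the critical")
  # normalization, unbounded and bounded, at assorted drifts
  for (cc in c(9, 10.5, 11.2)) {
    expect_equal(stats::integrate(function(x) length_density(x, cc, p),
                                  0, Inf)$value, 1, tolerance = 1e-6)
  }
  for (cc in c(10, 11.5, 13)) {
    expect_equal(stats::integrate(function(x) length_density(x, cc, p, R = 40),
                                  0, 40)$value, 1, tolerance = 1e-6)
  }
  # zero-drift limit: uniform on [0, R]
  expect_equal(length_density(c(0, 3, 10), p$c_c, p, R = 10),
               rep(0.1, 3))
})

test_that("exact steady state obeys the square-root law", {
  p <- generic()
  nu <- derived_constants(p)$nu
  # zero nucleation capacity: concentration reaches critical
  expect_equal(steady_c_exact(0, p)$c, p$c_c)
  # N = nu: normalized deviation is (sqrt(5) - 1) / 2
  u <- (p$c_c - steady_c_exact(nu, p)$c) / (p$c_t - p$c_c)
  expect_equal(u, (sqrt(5) - 1) / 2, tolerance = 1e-12)
  # Beroe egg with a 1e6-strong aster barely dents the pool
  expect_equal(steady_c_exact(1e6, beroe())$c, 11.40471, tolerance = 1e-6)
  # negative drift and mean length -a/b for N > 0
  ss <- steady_c_exact(1000, p)
  expect_lt(ss$b, 0)
  expect_equal(ss$mean_length, -p$a / ss$b)
  expect_error(steady_c_exact(10, tubulin_params(c_t = 11.5)),
               class = "mtaster_subcritical_error")
})

test_that("exact solution satisfies the conservation law; c decreases in N", {
  set.seed(7)
  for (i in 1:20) {
    p <- random_params()
    nu <- derived_constants(p)$nu
    # keep the sweep inside the physical branch (c > 0): the quadratic law
    # crosses c = 0 at u = c_c/(c_t - c_c)
    u_max <- 0.9 * p$c_c / (p$c_t - p$c_c)
    N_max <- min(nu, nu * (u_max^2 + u_max))
    N_grid <- N_max * 10^runif(5, -4, 0)
    cs <- vapply(N_grid[order(N_grid)],
                 function(N) steady_c_exact(N, p)$c, numeric(1))
    expect_true(all(diff(cs) < 0))
    for (N in N_grid) {
      res <- conservation_residual(steady_c_exact(N, p)$c, N, p, R = Inf)
      expect_lt(abs(res), 1e-10 * p$c_t)
    }
  }
})

test_that("linearization is the small-N tangent of the exact law", {
  p <- generic()
  nu <- derived_constants(p)$nu
  expect_equal(steady_c_linear(0, p)$c, p$c_c)
  # within 1% of exact throughout N <= 0.01 nu
  for (f in 10^seq(-4, -2, by = 0.25)) {
    ce <- steady_c_exact(f * nu, p)$c
    cl <- steady_c_linear(f * nu, p)$c
    expect_lt(abs(cl - ce) / abs(p$c_c - ce), 0.01)
  }
  # slope of the normalized concentration at N = 0 is -1/nu
  h <- nu * 1e-9
  slope <- (steady_c_exact(h, p)$c - steady_c_exact(0, p)$c) /
    (h * (p$c_t - p$c_c))
  expect_equal(slope, -1 / nu, tolerance = 1e-4)
})

test_that("bounded solver conserves tubulin and matches the exact solver", {
  p <- generic()
  nu <- derived_constants(p)$nu
  expect_equal(steady_c_bounded(0, 10, p)$c, p$c_t)
  for (f in c(1e-4, 1e-2, 1e-1)) {
    N <- f * nu
    exact <- steady_c_exact(N, p)
    ss <- steady_c_bounded(N, 60 * exact$mean_length, p)
    expect_lt(abs(ss$c - exact$c) / exact$c, 1e-3)
    expect_lt(abs(ss$residual), 1e-9 * p$c_t)
    expect_lt(abs(conservation_residual(ss$c, N, p, R = ss$R)),
              1e-9 * p$c_t)
  }
  # monotone convergence to the unbounded solution as R grows
  N <- 0.05 * nu
  exact <- steady_c_exact(N, p)
  gaps <- vapply(c(5, 20, 50, 200), function(mult) {
    steady_c_bounded(N, mult * exact$mean_length, p)$c - exact$c
  }, numeric(1))
  # a length cap leaves more tubulin free; beyond ~20 mean lengths the
  # truncated tail (e^-50, e^-200) is below double precision, so only the
  # first gaps are resolvable and the rest must sit at numerical zero
  expect_true(all(gaps[1:2] > 0))
  expect_gt(gaps[1], gaps[2])
  expect_lt(max(abs(gaps[3:4])), 1e-8 * exact$c)
})

test_that("conservation residual is signed and monotone at the endpoints", {
  p <- generic()
  expect_gt(conservation_residual(p$c_t, 100, p, R = 50), 0)
  expect_lt(conservation_residual(0, 100, p, R = 50), 0)
  expect_equal(conservation_residual(p$c_t, 0, p, R = 50), 0)
})
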