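## shared fixtures: parameter sets are built in code, nothing is stored

AVOGADRO <- 6.02214076e23

generic <- function() cell_preset("generic")
beroe   <- function() cell_preset("beroe")

## independent single-expression formulas for the derived constants,
## written out from first principles (dimer bookkeeping), used as oracles
## against the package's staged computation
oracle_xi <- function(p) {
  (p$lambda_um) * (p$c_t - p$c_c) * 1e-6 * AVOGADRO * p$V
}
oracle_chi <- function(p) p$a / (p$k * (p$c_t - p$c_c))
oracle_nu <- function(p) {
  p$lambda_um * AVOGADRO * p$V * p$k * (p$c_t - p$c_c)^2 * 1e-6 / p$a
}

## random valid super-critical parameter set for property tests
random_params <- function() {
  tubulin_params(
    lambda_nm = runif(1, 0.3, 1.2),
    a   = runif(1, 1, 20),
    k   = runif(1, 0.2, 5),
    c_c = runif(1, 2, 20),
    c_t = runif(1, 21, 60),
    V   = 10^runif(1, -13, -9))
}
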