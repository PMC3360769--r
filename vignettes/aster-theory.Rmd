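---
title: "Nucleation capacity, tubulin partitioning and organelle capture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nucleation capacity, tubulin partitioning and organelle capture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtaster)
```

## The model and its assumptions

A cell holds a finite pool of tubulin at total concentration $c_t$ in a
cytoplasmic volume $V$. Microtubules are nucleated at $N$ centrosomal sites
(an unoccupied site is a microtubule of zero length), and each microtubule's
length performs a diffusion-with-drift random walk: drift
$b = k\,(c - c_c)$ — net growth above the critical concentration $c_c$, net
shrinkage below — and diffusion coefficient $a$, the two-parameter
coarse-graining of dynamic instability that is accurate on the cell scale.
Polymerized tubulin is subtracted from the free pool ($\lambda$ length of
microtubule per dimer), which closes the feedback: more nucleation means
more polymer, a lower free concentration, and therefore shorter
microtubules.

When microtubule growth is not limited by the cell boundary (microtubules
run along the margin rather than abutting it — true of the *Beroe* egg
ectoplasm), the steady state requires $b < 0$ and the length distribution is
exponential with mean $-a/b$. Conservation then closes in a quadratic whose
physical root is

$$\frac{c_c - c}{c_t - c_c} \;=\; \frac{\sqrt{1 + 4N/\nu} - 1}{2},
\qquad
\nu = \frac{\lambda N_A V k (c_t-c_c)^2}{a}.$$

The package also carries the tangent law at $N = 0$ (slope $-1/\nu$),
$(c_c - c)/(c_t-c_c) = N/\nu$, valid for $N \ll \nu$, and a numerical solver
for the length-bounded case (reflecting cap at $R$; truncated-exponential
length density), where the steady state can sit at or even above $c_c$ and
no closed form exists.

Three derived constants organize everything (`derived_constants()`):
$\xi = \lambda\,N_A V\,(c_t - c_c)$ in micrometres (total microtubule length
at exactly critical free tubulin), $\chi = a/(k(c_t-c_c))$ in micrometres
(the mean length if the drift were set by the full super-critical pool), and
the dimensionless $\nu = \xi/\chi$. The identity $\nu\chi = \xi$ holds by
construction and is enforced by a property test. The printed equations of
the theory leave the mole-to-count conversion implicit; this package places
Avogadro's number inside $\xi$ and $\nu$ as written above, the only
placement that reproduces the known magnitude $\nu \approx 1.4\times10^8$
for the *Beroe* egg — that reproduction is an acceptance test.

```{r constants}
derived_constants(cell_preset("generic"))
derived_constants(cell_preset("beroe"))
```

## Density, optimality, capture

For a planar radial aster the density at radius $x$ — microtubules crossing
the circle of radius $x$ per unit arc length — is
$m(x) = N e^{-Nx/\xi}/(2\pi x)$, using the linearized steady state exactly
as the closed-form theory does (`planar_density(..., linearized = TRUE)` is
the default; the exact-law variant is kept as a diagnostic for leaving the
$N \ll \nu$ regime). Its derivative in $N$ changes sign at
$N_c = \xi/x$: nucleation helps locally only up to that capacity, beyond
which pool depletion wins. An organelle of diameter $d_o$ at radius $x$ is
captured when at least one microtubule crosses its arc; with isotropic
directions the crossing count is Poisson with mean $m(x)\,d_o$, so
$P(x) = 1 - e^{-m(x) d_o}$. The organelle is modelled as an arc, not a
disc, which is adequate while $d_o$ is small against $x$ and the mean
length; the package warns when $d_o > x/5$.

## The Beroe egg and polyspermy

The egg is a sphere of diameter $d_e = 1$ mm whose microtubules and free
tubulin are confined to an ectoplasmic shell of thickness $h = 5\,\mu$m, of
volume $\pi d_e^2 h = 15.7$ nL (`ectoplasm_volume()`). On the sphere the
circumference at geodesic distance $x$ from the sperm centrosome is
$\pi d_e \sin(2x/d_e)$, replacing $2\pi x$; the random entry point makes the
centrosome-to-pronucleus distance density $\sin(2x/d_e)/d_e$. All
microtubules — $N_f$ maternal acentrosomal ones and every sperm aster —
share the pool and so appear in the exponent, but only the focal aster's
count appears in the numerator of its density. Integrating
$1 - e^{-m_e(x) d_f}$ against the distance density over
$x \in (0, \pi d_e/2)$ gives the total capture probability
(`total_capture()`, `per_aster_capture()`). Microtubules longer than half
the circumference are excluded from the model's domain; the integrand is
assigned its limit (zero) at both endpoints, where the distance density
vanishes.

```{r beroe}
scen <- egg_scenario()
total_capture(1e4, 1e2, scen)
optimal_sperm_nucleation(9, 3e5, scen)
```

## Tunable parameters

| parameter | meaning | unit | default |
|---|---|---|---|
| `lambda_nm` | microtubule length per dimer | nm | 0.612 |
| `a` | length-diffusion coefficient of ends | µm²/min | 7.5 |
| `k` | elongation rate constant | µm min⁻¹ µM⁻¹ | 1 |
| `c_c` | critical concentration | µM | 11.5 |
| `c_t` | total tubulin concentration | µM | 25 |
| `V` | pool volume | L | 4e-12 (generic) / 1.57e-8 (egg shell) |
| `d_e`, `h`, `d_f` | egg diameter, shell thickness, pronucleus diameter | µm | 1000, 5, 15 |

The kinetic defaults are the standard in-vivo estimates for animal cells;
the egg values are the measured *Beroe ovata* geometry. $N$, $N_f$, $N_m$,
$N_a$ are free inputs; the plausible range in the egg is $10^2$–$10^6$
(values outside it warn, not error), and $N$ is treated as a continuous
capacity throughout — integer semantics are never enforced. Because
$c_t \approx 20$–$30\,\mu$M is uncertain, $\xi \propto c_t - c_c$ spans
0.63–1.37 of its default (a 2.18-fold band); a matching rescaling of the
microtubule numbers compensates exactly, since both enter the model only
through $N/\xi$ — this compensation is an acceptance test.

## Numerical choices

* **Bounded steady state.** The conservation function
  $F(c) = c + \mathrm{polymer}(c) - c_t$ is strictly increasing, so the
  root in $[0, c_t]$ is unique; it is found with `stats::uniroot` at an
  $x$-tolerance of $10^{-14} c_t$, leaving the residual comfortably below
  the $10^{-9} c_t$ contract even where $F$ is steep. The
  truncated-exponential mean uses `expm1` and series/asymptotic branches at
  $|bR/a| < 10^{-6}$ and beyond $\pm 700$ to avoid overflow and
  cancellation.
* **Degenerate inputs.** $N = 0$: the unbounded closed form returns its
  limit $c = c_c$, while the bounded (conservation) solver returns
  $c = c_t$ exactly — both limits are meaningful and documented. A
  sub-critical pool ($c_t < c_c$) is representable but the unbounded
  solvers raise a classed error rather than returning NaN. At
  $c_t = c_c$, $\xi = \nu = 0$ and $\chi = \infty$, following the defining
  formulas.
* **Capture quadrature.** `stats::integrate` (adaptive Gauss–Kronrod) at
  relative tolerance $10^{-8}$; a test pins the result to an independent
  finer quadrature within $10^{-6}$.
* **Optimum search.** 25 grid points per decade of $N$ over
  $\log_{10} N \in [1, 8]$, then golden-section refinement
  (`stats::optimize`) around the best point. The near-maximum set
  $\{N : P \ge P_{\max} - 10^{-3}\}$ is reported as a plateau when it spans
  more than one decade, and the reported argmax is then the plateau's
  geometric midpoint — a single representative value with honest width,
  since any point of a near-certainty plateau is equally "optimal".

## The stochastic simulator, and what a green test establishes

`simulate_lengths()` integrates $M$ reflected drift-diffusion lengths by
Euler–Maruyama ($\Delta x = b\,\Delta t + \sqrt{2a\,\Delta t}\,z$,
reflection at 0 and optionally at $R$), recomputing $c$ from conservation
after every step. The noise amplitude $\sqrt{2a\,\Delta t}$ is fixed by
requiring the stationary density $\propto e^{bx/a}$ — the exponential law
the analytics use — and a Kolmogorov–Smirnov test against that law is part
of the acceptance suite. For egg-scale $N$, a scaled ensemble is used:
$M \ll N$ simulated microtubules with pool feedback weighted by $N/M$,
valid because the pool couples only through the ensemble mean length.
Defaults: $M = 500$, $\Delta t = 10^{-3}$ min, 200 min with the first half
discarded, seed 1; standard errors come from batch means over snapshots, so
autocorrelation is accounted for.

The simulator emulates the stated world of the theory — shared pool,
two-parameter length dynamics, reflecting nucleation sites. It does not
emulate real microtubule arrays: no explicit catastrophe/rescue
(four-parameter) dynamics, no spatial embedding of capture events, no
pre-steady-state transients (so no sperm-entry-order effects), and no
pronucleus motility. Agreement between simulator and solver therefore
validates the mathematics of the steady state, not the biological
approximations behind it.

## Known limitations

The planar theory is strictly two-dimensional; the spherical correction
applies only to the thin-shell egg. The linearized density is hard-wired
into the capture formulas, as in the closed-form theory — negligible error
for realistic $N \ll \nu$, but not checked beyond that regime. First-contact
*times* (how long capture takes) are outside scope; the model predicts only
whether contact is made at steady state.
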