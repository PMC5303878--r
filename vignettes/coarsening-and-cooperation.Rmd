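---
title: "Models and methods: killing-driven phase separation and the evolution of cooperation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: killing-driven phase separation and the evolution of cooperation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(t6phase)
```

# The scientific problem

Many bacteria carry contact-dependent weapons — most prominently the type VI
secretion system (T6SS) — that kill adjacent cells lacking the matching
immunity proteins. In a dense, surface-attached population of two mutually
antagonistic strains, killing removes cells preferentially at strain
boundaries. Cells inside a clonal patch are safe; cells at an interface are
not. The population therefore behaves like a two-phase system with a
non-conserved order parameter: an initially well-mixed community demixes
into growing single-strain domains. This package implements three model
families for this process plus the spatial statistics used to quantify it,
and an extension in which one strain secretes a costly diffusible public
good, asking when the self-generated spatial structure rescues cooperation
from exploitation by non-producing cheats.

# The three simulators

## Individual-based lattice model (`run_ibm`)

A W x H grid holds strain A (+1), strain B (-1) or empty (0), initialised
fully occupied with an exact quota `round(W H f_A)` of A cells at uniformly
random positions. Each step, every occupied cell is independently marked a
*killer* with probability `kill_fraction` and a *reproducer* with
probability `repro_fraction` (defaults 0.05 each, the standard rates that
resolve the dynamics without freezing them). The sweep then visits sites in
row-major order from the top-left corner: a live killer empties all
8-neighbours of the opposite strain; a live reproducer copies itself into
one uniformly chosen adjacent empty site, aborting when all neighbours are
occupied.

Choices the verbal rule leaves open, and how they are resolved here:

* *Quota versus probability.* "A fraction of cells act" is implemented as
  independent Bernoulli marks rather than an exact 5% quota: it matches the
  stated rate in expectation, avoids a global sort, and differs from a
  quota only at order 1/sqrt(N).
* *Double marks.* A cell may be both killer and reproducer; killing is
  applied first at the visit. At 5% rates the overlap is rare and the
  ordering has no measurable effect.
* *Dead cells do not act.* Marks are tied to the cell present at the start
  of the step; a cell killed earlier in the sweep loses its marks, and a
  newborn carries none until the next step. This is the reading most
  consistent with sequential propagation of state.
* *Boundary.* Default `closed` (no wrap), matching a finite colony whose
  statistics are edge-trimmed anyway; `periodic` is available and is what
  the Fourier analysis prefers.

## Ising spin model (`run_ising`)

The statistical-mechanics reference point: spins +1/-1 on a periodic grid,
local Hamiltonian `H = (sum of the 8 Moore neighbours) x (centre spin)`
(+8 fully aligned, -8 fully opposed). A candidate site is chosen uniformly
at random; a flip negates the local Hamiltonian, so its energy change is
`dE = 2 H_old` in units of k_B T, and the move is accepted iff
`exp(-beta dE) > u`, `u ~ Uniform[0,1)`. Favourable and neutral moves are
therefore always accepted and unfavourable ones with Boltzmann probability
— a Glauber-type single-spin-flip rule that does not conserve
magnetisation (the defining feature of Model A dynamics). One sweep is
`W x H` attempts; `beta = 1` is the standard coarsening condition. The
acceptance expression is a reconstruction from the verbal description
("compare the exponential to a uniform number; flip iff larger") — a
`min(1, .)` Metropolis cap would change nothing, since capping at 1 cannot
alter the comparison with `u < 1`.

## Two-strain reaction-diffusion model (`integrate_fields`)

Densities A(x, y) and B(x, y) obey

    dA/dt = A (r - s (A + B) - alpha_AB B) + d lap A
    dB/dt = B (r - s (A + B) - alpha_BA A) + d lap B

with shared growth rate `r` (1/time), density-dependent mortality `s`,
cross-killing rates `alpha_AB` (B kills A) and `alpha_BA`, and cell
dispersal `d` (length^2/time). Defaults r = 2, s = 2, alpha = 0.5, d =
0.01 are the standard simulation values. The right-hand sides are
reconstructions validated against every closed-form result of the
well-mixed system: the four equilibria, the coexistence composition ratio
`A*/B* = alpha_AB/alpha_BA`, the saddle classification (negative trace
*and* negative determinant), and the cooperator stability threshold below
— all are mandatory tests (`test-wellmixed.R`, `test-pde.R`).

The public-goods extension adds a concentration field S produced by the
cooperator strain A at rate `rho`, decaying at `lambda`, diffusing with
`big_d`, raising both strains' growth by `b S`, and costing the producer
`c` in growth rate:

    dA/dt = A (r - c + b S - s (A + B) - alpha B) + d lap A
    dB/dt = B (r     + b S - s (A + B) - alpha A) + d lap B
    dS/dt = rho A - lambda S + big_d lap S

with the defaults b = 1.9, c = 0.1, rho = lambda = 100, big_d = 0.1. The
constraint `s > rho b / lambda` (checked at construction) keeps the
cooperator-only equilibrium `A* = lambda (r - c) / (lambda s - rho b)`
finite.

# Well-mixed theory (`equilibria_two_strain`, `cooperator_equilibria`)

Closed forms are hard-coded from the analytic results and then verified
numerically: every reported equilibrium must zero the implemented
right-hand side to below 1e-12, and classifications come from numerical
Jacobian eigenvalues (central differences, tolerance 1e-9 on real parts)
with the trace/determinant reported alongside. The killing model is
bistable: whichever strain starts above the separatrix ratio
`A/B = alpha_AB/alpha_BA` excludes the other. With a public good under the
quasi-steady-state reduction `S = rho A / lambda`, the per-capita advantage
of the cooperator is `w_A - w_B = -c + alpha (A - B)`: the shared good
cancels and killing converts numerical dominance into a growth advantage
(positive frequency dependence). The pure-cooperator state is stable iff
`alpha > c (lambda s - rho b) / (lambda r - lambda c)`; the pure-cheat
state is always stable; between them sits a saddle whose A-coordinate
exceeds its B-coordinate whenever `c > 0`, so the cooperator basin is
always the smaller one. At `c = 0` and `alpha = 0` exactly, cooperator and
cheat are the same strain and the "equilibrium" is a neutral line; the
classifier reports `marginal` rather than forcing a label.

The quasi-steady-state reduction is used for analytic equilibria; full
three-variable integration is retained for trajectories, and the tests
require the two to agree on equilibrium locations (the residual lag
|S - rho A / lambda| scales as 1/lambda and is checked to shrink
accordingly).

# Numerical scheme for the PDE

Time integration is explicit forward Euler on a periodic grid with the
5-point Laplacian, first-order convergent in `dt` (checked by Richardson
comparison). The diffusive stability bound `dt < dx^2 / (4 max(d, big_d))`
is enforced with an error, not a warning. The good's production/decay term
is stiff (`lambda = 100` versus ecological rates of order 1), so it is
advanced by its exact exponential solution within an operator split —
diffusion of S explicit, relaxation `S -> rho A / lambda` exact — leaving
`dt` set by ecology and the CFL bound rather than by `lambda`. Euler
undershoots near extinction fronts are clipped at zero; clip events are
counted and surfaced as a warning, and vanish as `dt` decreases. Well-mixed
ODE trajectories use adaptive `lsoda` via deSolve instead.

Grid metrics matter for this model because the natural interface width is
`~ sqrt(d / (alpha A*))`, about 0.2 length units at the defaults. The 2-D
coarsening experiments therefore use `dx = 0.2` (interfaces of about one
cell; coarser grids pin domain walls), and the 1-D cooperation scenarios
`dx = 0.1`.

# Spatial statistics

## Structure factor (`structure_factor`, `sf_peak`)

`S(q_x, q_y) = |FFT(I - mean I)|^2 / N`, radially averaged into annuli one
fundamental frequency `2 pi / (max(W, H) L)` wide, DC bin dropped. The
normalisation makes Parseval exact: the power-weighted sum of the curve
equals the centred sum of squares of the image (tested to machine
precision). No window is applied by default because simulation output is
periodic; a Hann option exists for closed-boundary or experimental images.

The characteristic wavenumber `q_m` is the *first moment*
`sum(q S) / sum(S)` over the band up to the axis Nyquist `pi / L`. An
argmax estimator is provided and is exact for single-mode fixtures
(stripes), but it is not usable for coarsening spectra: the radially
averaged S(q) of these non-conserved dynamics is monotone decreasing in q,
so the argmax sits in the first annulus at all times and carries no scaling
information. All scaling analyses use the moment estimator.

## Coarsening scaling (`coarsening_fit`, `collapse_curves`)

Model A dynamics predict a characteristic length growing as t^(1/2), hence
`q_m ~ t^(-1/2)` and `S(q_m) ~ q_m^(-2)`; since simulation and experimental
clocks are incommensurate, the primary observable is the slope of
`log S(q_m)` against `log q_m`. `coarsening_fit` drops the first 10% of the
snapshot sequence as transient (with logarithmically spaced snapshots a
10%-of-duration cut would discard most of the data) and requires at least
five usable points. The fitting machinery is validated against a
simulator-independent oracle: block-upsampling one labyrinth pattern by
factor k compresses its spectrum by k and multiplies the normalised S by
k^2, so the series obeys the -2 law exactly by construction
(`make_scaled_series`). `collapse_curves` rescales each curve to
`(q / q_m, S q_m^2 L^2)` and scores collapse quality as the median pairwise
log-space L2 distance on a common grid; rescaling must strictly improve the
score during self-similar coarsening.

For the PDE, scaling snapshots are taken at t = 100-800 (256^2, dx = 0.2):
earlier times are still in the linear-amplification regime, where the
composition amplitude grows exponentially at fixed wavelength and the
S(q_m)-q_m relation has not yet joined the coarsening line. The IBM uses
steps 50-3200 and the Ising model sweeps 5-640 at 256^2 (beyond ~1000
sweeps a 256^2 lattice at beta = 1 approaches full magnetisation and the
spectrum degenerates).

## Assortment (`assortment`, `assortment_profile`)

With the focal strain g coded +1 and the competitor c coded -1, the kernel
of ones with centre `-((2h+1)^2 - 1)` computes, at each cell, the excess of
its neighbourhood over `(2h+1)^2 - 1` copies of itself; operationally the
implementation computes, for each focal cell, the frequency of g among
*occupied* neighbours within radius h (empty sites excluded — lattice
snapshots contain them even though near-confluent experimental images do
not), averages over focal cells, and normalises:

    r_g = (p_local - f_g) / (1 - f_g)

where `f_g` is the global frequency of g among occupied cells in the
edge-trimmed interior (borders within h are discarded). The final
normalisation is a reconstruction from the stated properties — range
[-1, 1], 0 under random mixing, "mean local frequency relative to global
frequency" — and is validated against them, with the kernel computation
required to match an exhaustive sliding-window enumeration exactly on every
test image. Two fixed points of the definition worth noting: an i.i.d.
random image has r = 0 at every radius, and a checkerboard *also* has
r = 0 (same- and opposite-label neighbours balance exactly in every Moore
window); genuine anti-assortment appears for period-2 stripes, where
r(h = 1) = -0.5.

# The cooperation scenarios (`run_cooperation_scenarios`)

Four scenarios: {well-mixed, spatial} x {killing, no killing}, each from a
set of initial cooperator frequencies. Non-spatial runs start from total
density `r / s` split by the initial frequency. Spatial runs are 1-D
(1024 cells, dx = 0.1, dt = 0.002) and start from randomly placed *founder
patches*: the domain is divided into 8-cell patches and exactly
`round(f x n_patches)` of them start as pure cooperator.

The founder-patch initialisation is a deliberate design decision. A start
from uniform coexistence plus infinitesimal noise cannot reproduce invasion
from rarity: pointwise the cooperator's advantage is
`-c + alpha (A - B)`, which at 5% cooperator frequency is negative
*everywhere*, so small-amplitude noise decays globally. Invasion from
rarity is a finite-amplitude phenomenon — it needs patches in which
cooperators are locally the majority, which is exactly what a randomly
seeded population of discrete cells provides and what the experimental
inoculations look like. Founder patches are the continuum analogue at
cell-scale granularity. Once such patches exist, the sequence is: patches
densify toward the cooperator equilibrium (density 19 at the defaults,
versus 1 for cheats), killing at patch borders converts neighbouring
cells' sites, and cooperator domains expand until fixation. At the default
parameters fixation from a 5% start completes within a few hundred time
units; the default horizon is 200.

# What the generators emulate, and what they do not

The synthetic fixtures (`make_pattern`) provide ground-truth statistics:
i.i.d. random labels (r = 0, flat spectrum), stripes (single-mode
spectrum), checkerboard (balanced windows), half-plane splits (complete
segregation), and smoothed-noise labyrinths (one intermediate length
scale). The simulators generate the dynamical inputs. None of these
reproduce features of real colony images: cell-size granularity and
segmentation noise, anisotropic growth, nutrient gradients, or
three-dimensional structure. Passing tests therefore certify the
statistics and dynamics of the *models*, not quantitative agreement with
any particular experimental system; the package's claim about experiments
is limited to the shared universality class (the -2 scaling and its
collapse), which is deliberately insensitive to microscopic detail.

# Problem sizes and determinism

Routine tests run at 16-128 square; the scaling analyses use 256^2 with
three replicate seeds per model, and the null-assortment check ten 500^2
images — sizes at which one fit takes seconds to a couple of minutes on a
single core while leaving the slope estimates' scatter well inside the
+/-0.3 acceptance band. Every stochastic routine draws from a labelled
substream (`make_rng`) of one master seed, compiled kernels included (they
consume R's own RNG), so identical configurations reproduce trajectories
bit for bit; there is no wall-clock seeding anywhere.

# Known limitations

* The IBM supports exactly two strains and symmetric killing; asymmetric
  rates live in the PDE, and more than two effector-immunity types are out
  of scope.
* Forward Euler is first-order; it is adequate for the smooth, stiffness-
  split fields here, but stiff parameter regimes (very large `alpha` or
  `s`) would need smaller `dt` than the CFL bound alone suggests.
* The PDE is deterministic: demographic noise, which would roughen
  interfaces and nucleate patches spontaneously, is not modelled — one
  reason the finite-amplitude initial condition matters.
* Assortment at radius h requires a border of width h to trim;
  profiles on small images are limited to `h <= min(W, H) / 4`.
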