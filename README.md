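# t6phase

Simulators and spatial statistics for **phase separation driven by
contact-dependent killing** in dense bacterial populations, and for its
evolutionary consequence: the protection of public-goods cooperation.

Bacteria armed with a type VI secretion system (T6SS) kill adjacent cells
that lack matching immunity. In a crowded two-strain community this removes
cells only at strain boundaries, so an initially well-mixed population
spontaneously demixes into growing clonal domains — an order–disorder
transition with a *non-conserved* order parameter (Model A), whose
hallmarks are a domain scale growing as t^(1/2) and a structure-factor peak
obeying S(q_m) ∝ q_m^(−2). The package provides, in one toolkit:

* **`run_ibm()`** — an individual-based lattice model: each step 5% of
  cells kill all 8-neighbours of the opposite strain and 5% reproduce into
  an adjacent empty site, with sequential row-major updates.
* **`run_ising()`** — the Ising spin model with the 8-neighbour Hamiltonian
  H = (Σ neighbours) × centre and Glauber-type flips accepted iff
  exp(−β·2H_old) > u: the statistical-mechanics reference for Model A
  coarsening.
* **`integrate_fields()` / `rhs_two_strain()` / `rhs_public_goods()`** — a
  two-strain reaction–diffusion model,
  ∂A/∂t = A(r − s(A+B) − α_AB·B) + d∇²A (and symmetrically for B), with an
  optional diffusible public good ∂S/∂t = ρA − λS + D∇²S produced by strain
  A at growth-rate cost c and benefiting both strains by b·S.
* **`equilibria_two_strain()` / `cooperator_equilibria()`** — closed-form
  equilibria with numerical Jacobian classification: the well-mixed killing
  system is bistable (coexistence at A/B = α_AB/α_BA is a saddle); with a
  public good the cooperator state is stable iff
  α > c(λs − ρb)/(λr − λc), and the interior saddle always leaves
  cooperators the smaller basin.
* **`structure_factor()` / `sf_peak()` / `coarsening_fit()` /
  `collapse_curves()`** — radially averaged S(q), first-moment peak
  extraction, scaling-exponent fits and dynamic-scaling collapse.
* **`assortment()` / `assortment_profile()`** — the kin assortment
  statistic r(h) ∈ [−1, 1] (0 under random mixing), the spatial analogue of
  relatedness, over interaction radii h = 1–36.
* **`perturbation_growth()`** — growth rate of a sinusoidal composition
  mode a·sin(βx): αA* − dβ² with killing, −dβ² without.
* **`run_cooperation_scenarios()`** — the four-way phase diagram
  {well-mixed, spatial} × {killing, no killing} for cooperator invasion.

All stochastic components draw from labelled substreams of one master seed
(`make_rng()`); runs are reproducible bit for bit. A command-line front end
(`inst/cli/t6phase`, or `cli_main()` from R) exposes
`simulate ibm|ising|pde|ode`, `analyze sq|scaling|assortment|equilibria|invasion`
and `fixtures make`, writing CSV outputs plus a checksummed run manifest.

## Worked example

Run the killing lattice at its standard size (500 × 500, equal strain mix),
fit the coarsening scaling, and measure assortment:

```r
library(t6phase)

steps <- c(50, 100, 200, 400, 800, 1600, 3200)
run <- run_ibm(ibm_params(seed = 1), n_steps = 3200, record_at = steps)
tail(run$summary, 1)
#>    step    n_a    n_b n_empty freq_a
#> 1  3200 113772 131434    4794  0.464

fit <- coarsening_fit(run$snapshots, steps)
tidy(fit)
#>   term                 estimate std.error
#> 1 log S(q_m) ~ log q_m   -2.07    0.111
#> 2 log q_m ~ log t        -0.423   0.00547

assortment_profile(run$snapshots[["3200"]], h_max = 5)
#>       h   r_g   r_c freq_g
#> 1     1 0.981 0.981  0.463
#> 2     2 0.958 0.958  0.462
#> 3     3 0.936 0.936  0.461
#> 4     4 0.914 0.914  0.460
#> 5     5 0.892 0.892  0.459
```

Read: the population stays near full occupancy (4,794 empties out of
250,000 sites) while domains coarsen; the S(q_m)–q_m slope of −2.07 ± 0.11
is the Model A signature (−2), with the domain scale growing close to
t^(1/2) (slope of log q_m versus log t near −0.42 here); and after 3,200
updates a cell's neighbourhood is almost entirely clonal (r ≈ 0.98 at
h = 1), compared with r = 0 for a randomly mixed population — the spatial
structure that shields diffusible public goods from cheats. `autoplot()`
methods exist for lattices, S(q) curves, scaling fits and collapses, and
`plot_invasion()` for the cooperation scenarios.

The same analyses run from the shell:

```sh
Rscript inst/cli/t6phase simulate ibm --steps 3200 --record-every 400 --seed 1 --out out/
Rscript inst/cli/t6phase analyze assortment --in out/ibm_step003200.txt --h-max 36 --out out/
```

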