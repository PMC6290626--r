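# porescale

Scaling analysis and Langevin dynamics of charged-polymer translocation
through a nanopore, in monovalent and divalent salt.

When an electric field drives a polyelectrolyte (DNA, RNA) through a
nanopore, the mean translocation time follows
⟨τ⟩ ∼ N^α E^−δ, but the exponents are not universal: as the driving force
grows, the process crosses four regimes — unbiased (UB), weakly driven
(WD), strongly driven with a trumpet-shaped blob ensemble (SD(T)), and
strongly driven isoflux (SD(I)) — with

| regime | α | δ |
|---|---|---|
| UB | 2 + νs·zp(1−γp) | 0 |
| WD | 1 + νs·zp(1−γp) | 1 |
| SD(T) | 1 + νs(1−q) | pz(1−q) |
| SD(I) | 1 + νs | 1 |

where νs is the tethered-chain size exponent, zp the tension-propagation
dynamical exponent, γp the subdiffusion exponent of the translocation
coordinate (⟨Δn²⟩ ∼ t^γp), q = (1−νb)/(1+νb) the density–velocity exponent
of the tension blobs, and pz = z − 2 the velocity–extension–force exponent.
The regimes are demarcated by f1\* ∼ N^−1, f2\* ∼ N^−νsρ and f3\* ∼ N^−νsη.

The package is for polymer/biophysics researchers who want to:

* evaluate the closed-form theory — regime exponents, boundaries,
  demarcation-line slopes, the inter-exponent relations, consistency
  inequalities, piecewise τ(f) / τ(N) curves, and a numerical integration
  of the tension-propagation law (`theory_params()`, `regime_exponents()`,
  `invert_observed()`, `check_inequalities()`, `theory_curve()`,
  `solve_tension_ode()`);
* run the coarse-grained model at reduced scale — a bead-spring
  polyelectrolyte with explicit counterions and (Z:1) salt, WCA excluded
  volume, damped shifted-force Coulomb, an analytic slab-and-pore wall, an
  in-pore driving field, a head-monomer no-return barrier, and a BAOAB
  Langevin thermostat, in a deterministic Rcpp core
  (`sim_params()`, `run_translocation()`, `run_batch()`,
  `sample_tethered_chain()`, `sample_free_chain()`);
* extract exponents from simulated or external n(t) series — pairwise
  log-log slopes at geometric means, least-squares fits, static size
  exponents νs0 and νb0, the variance curve and its diffusion exponent γ,
  plus a synthetic drift-diffusion trajectory generator that validates
  every estimator against planted truth (`pairwise_exponent()`,
  `least_squares_exponent()`, `nu_s0_profile()`, `translocation_variance()`,
  `fit_gamma()`, `generate_synthetic_trajectories()`);
* convert between simulation and experimental units
  (σ ≈ 0.7 bp, tu ≈ 2.13 ps, Eu ≈ 100 mV/nm; `to_simulation_units()`,
  `comparison_table()`).

Everything tabular goes in and out as tibbles; fitted objects have
`tidy()`/`glance()` methods and results have `autoplot()`/`plot_*()`
helpers.

## Worked example

Invert the measured exponents of the monovalent-salt study into the derived
exponent chain:

```r
library(porescale)
obs <- observed_exponents(1)          # alpha_UB = 2.39, delta_SDT = 1.65, ...
inv <- invert_observed(obs$alpha_UB, obs$alpha_SDT, obs$alpha_SDI,
                       obs$delta_SDT, obs$gamma_p)
inv[, c("nu_s_2dp", "q_2dp", "z_p_2dp", "rho_2dp", "eta_2dp")]
#>   nu_s_2dp q_2dp z_p_2dp rho_2dp eta_2dp
#> 1     0.35  0.86    5.06     1.5    1.32
```

νs = 0.35 says the tethered chain is strongly contracted relative to a
self-avoiding walk; zp ≈ 5.06 is the (slow) tension-propagation exponent,
and ρ > η confirms a well-ordered regime diagram (all five consistency
inequalities pass, `check_inequalities()`).

Run a desk-scale batch (16 monomers, monovalent salt, field E = 8) and
summarize it:

```r
p <- sim_params_reduced(Z = 1, E = 8, Nm = 16, seed = 1)
b <- run_batch(p, n_runs = 10, seed0 = 1, equil_time = 25)
mean_tau(b)
#>   mean_tau    stderr n_completed n_failed
#> 1    4.265 0.1103152          10        0
```

Each run transports N = Nm − 5 = 11 monomers (the first five span the pore
at t = 0); τ is the last time any monomer occupied the cis side, here about
4.3 tu at this strong field. A published experiment converts onto the same
axes:

```r
rec <- experiment_records("pBR322 + 100 mM MgCl2", 4400, 145e-6, 8, "divalent")
to_simulation_units(rec)[, c("N", "tau_sim", "E_sim")]
#>      N  tau_sim E_sim
#> 1 6286 68075117  0.08
```

so that 4.4 kbp plasmid at 8 mV/nm sits at N ≈ 6286, τ ≈ 6.8e7 tu,
E = 0.08 — deep in the weakly driven regime.

A command-line wrapper over the same functions is installed at
`inst/cli/porescale.R` (subcommands `simulate`, `batch`, `tethered`,
`freechain`, `analyze`, `theory`, `convert`, `report`; a demo YAML
configuration ships in `inst/extdata/reduced_demo.yaml`).

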