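# alchpath

Metric-based optimization of alchemical free energy calculations in R.

Alchemical free energy calculations couple a system between two chemical
end states through a parameter λ, with the intermediate Hamiltonians — the
*path* — left entirely to the practitioner. The choice of path, of the
spacing of λ points along it, and of how much sampling each point
receives can change the efficiency of the calculation by an order of
magnitude. `alchpath` provides the machinery to make those choices from
data rather than habit:

* **Soft-core coupling** — the Beutler-style pair potential with a shared
  λ-dependent distance function for Lennard-Jones and Coulomb components
  (`softcore_pair_energy()`, analytic `softcore_dVdlambda()`), defaults
  α = 0.5, p = 1.
* **Samplers** — overdamped Langevin, Metropolis, and an exact
  Ornstein-Uhlenbeck propagator for harmonic systems; fixed-λ runs
  (`run_fixed_lambda()`) and an expanded ensemble in which λ performs a
  biased random walk (`run_expanded_ensemble()`).
* **Adaptive weight-histogram bias** — a two-stage adaptive bias
  (`awh_bias()`, `awh_update()`) whose free-energy parameters f_λ converge
  to βG_λ: a robust covering/halving initial stage followed by a
  stochastic-approximation final stage with 1/√N error decay, plus
  on-the-fly metric-based target optimization (`awh_dynamic_target()`).
* **Metrics** — the friction metric
  g(λ) = ∫ ⟨δF(t) δF(0)⟩_λ dt (integrated time-correlation of the
  generalized force F = −∂H/∂λ), the diffusion metric for expanded
  ensembles (conditional-weight-weighted analogue), and the equal-time
  Fisher-Rao metric for comparison; scalar profiles in 1D, 2×2 tensor
  fields on 2D λ grids (`friction_metric()`, `diffusion_metric()`,
  `fisher_rao_metric()`, `metric_field_2d()`).
* **Path tools** — thermodynamic length 𝓛 = ∫√g dλ, the variance
  functional 𝕍 = ∫ g/π dλ with Var ΔG ≈ 2𝕍/τ, optimal targets
  π = √g/𝓛, improvement factors IF = 𝓛²/𝕍_unif, reparameterization to
  constant metric speed, and shortest metric paths across 2D λ grids
  (`path_length()`, `variance_functional()`, `optimal_target()`,
  `improvement_factor()`, `optimize_path_2d()`).
* **Estimators** — thermodynamic integration (`ti_trapezoid()`), Bennett
  acceptance ratio (`bar_pair()`, `bar_chain()`), MBAR (`mbar_solve()`),
  and a repeat-evaluation harness (RMSE against a pooled reference,
  one-sigma bootstrap intervals, empirical improvement factors).
* **I/O and CLI** — GROMACS-style XVG series files, CSV metric/path
  profiles, JSON bias snapshots, YAML run configs, seeded fixture
  generation, and a thin command-line driver (`cli_main()`,
  `inst/cli/alchpath.R`).

Everything is in reduced units (k_B = 1). The built-in systems are
analytically tractable toys — harmonic oscillators, a 2D Lennard-Jones
micro-solvation box with a soft-core-inserted solute, and a two-component
λ toy with a low-metric channel — chosen so that every estimator can be
validated against closed forms or exhaustive enumeration.

## Worked example

Estimate the friction metric of the harmonic toy (k: 1 → 4, exact
ΔG = ln 4 / 2 ≈ 0.6931), derive the optimal target, and compare
estimators:

```r
library(alchpath)
th  <- thermo_params()              # reduced units, beta = 1
sys <- harmonic_system(k_A = 1, k_B = 4)

set <- sampler_settings(timestep = 0.05, n_steps = 40000,
                        sample_interval = 10, seed = 1,
                        move_kind = "exact_ou")
run <- run_fixed_lambda(sys, lambda_grid(21), set, th)

ti_trapezoid(run)
#> dG = 0.690552 +/- 0.00547 (ti)
bar_chain(run, th)
#> dG = 0.689729 +/- 0.00277 (bar)
inp <- mbar_input(run)
mbar_solve(inp$u_kn, inp$N_k, th)$result
#> dG = 0.689058 +/- 0.00374 (mbar)

fm <- friction_metric(run)
round(fm$value[1], 2)               # exact closed form: 2.25
#> [1] 2.19

path <- lambda_path(run$lambda_grid)
improvement_factor(path, fm)        # predicted gain of target optimization
#> [1] 0.7731127
```

All three estimators agree with ln 4 / 2 within their standard errors; the
friction metric at λ = 0 matches the Ornstein-Uhlenbeck closed form
(k_B − k_A)²γ/(4β²k³) = 2.25 within its statistical error; and the
improvement factor predicts that metric-optimized sampling would need
about 23% less time than uniform sampling for the same variance
(`optimal_target(path, fm)` gives the corresponding sampling weights).

The same pipeline runs from the shell:

```sh
Rscript inst/cli/alchpath.R --seed 1 --out fx fixtures
Rscript inst/cli/alchpath.R --out met metric fx/harmonic_dhdl_*.xvg
Rscript inst/cli/alchpath.R --out tgt optimize-target met/friction_metric.csv
```

## Configuration files

`simulate`, `estimate` and `evaluate` read a YAML config:

```yaml
system:            # harmonic | micro_solvation | two_lambda
  kind: harmonic
  k_A: 1
  k_B: 4
thermo:
  temperature: 1
lambda:
  n_points: 21
sampler:
  timestep: 0.05
  n_steps: 40000
  sample_interval: 10
  move_kind: exact_ou
estimator: ti      # ti | bar | mbar
```

Unknown keys are rejected. XVG input follows the GROMACS dialect: `#` and
`@` lines are metadata (`@ s0 legend "..."` names columns), numeric rows
are whitespace-separated with time in the first column.

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "alchpath",
                               load_package = "installed")'
```

The suite validates every operation against independent oracles: hand
evaluations of the soft-core forms, Gaussian/OU closed forms for the
harmonic toy, enumeration of microstate systems for BAR, branch-and-bound
exhaustive search for the 2D path optimizer, and fluctuation-theorem-
consistent Gaussian work samples.

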