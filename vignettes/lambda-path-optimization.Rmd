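---
title: "Metric-based lambda-path optimization: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metric-based lambda-path optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alchpath)
```

## The problem

Alchemical free energy calculations interpolate a Hamiltonian between two
chemical end states, $H(\mathbf{x};\lambda)$ with $H = H_A$ at $\lambda = 0$
and $H = H_B$ at $\lambda = 1$. The intermediate Hamiltonians are a free
choice, which leaves three coupled design decisions: the *path* through
(possibly multidimensional) $\lambda$ space, its *parameterization* (how
$\lambda$ points are spaced), and the *sampling distribution* over those
points. `alchpath` implements the machinery needed to make these choices
quantitatively: metric estimators built from generalized-force time
correlations, path functionals that turn a metric into predicted estimator
variance, target-distribution and shortest-path optimizers, and the
standard free-energy estimators (TI, BAR, MBAR, and an adaptive
expanded-ensemble bias) to evaluate the result. Everything runs in reduced
units ($k_B = 1$, $\beta = 1/T$); all validation systems are desk-scale
toys with closed-form references, not molecular force fields.

## Metrics

The friction metric is the integrated time-autocorrelation of the
generalized force $\mathcal{F}_\mu = -\partial H/\partial\lambda^\mu$ at
fixed $\lambda$:

$$ g_{\mu\nu}(\lambda) = \int_0^\infty \langle \delta\mathcal{F}_\mu(t)\,
   \delta\mathcal{F}_\nu(0)\rangle_\lambda \, dt. $$

For expanded-ensemble simulations, in which $\lambda$ itself performs a
random walk, the analogous diffusion metric weights the force fluctuations
with the conditional weights $w_\lambda(t) = P(\lambda \mid \mathbf{x}(t))$
and normalizes by $\langle w_\lambda^2\rangle$. The Fisher-Rao metric — the
equal-time force covariance — is implemented purely as a comparison: it
ignores time correlations, which is exactly the information the other two
metrics add.

Numerical choices:

* **Correlation windowing.** The integrated correlation uses
  $\Delta t\,(C_0/2 + \sum_{k=1}^{W} C_k)$ with the automatic window
  chosen as the smallest $W \ge 5\,\tau_{\mathrm{int}}(W)$
  (self-consistent integrated autocorrelation time, in samples), capped at
  a tenth of the series length. The cap bounds the variance of the
  estimate; the factor 5 captures $>99\%$ of an exponential tail. Halving
  or doubling the window changes harmonic-toy estimates by well under 15%.
* **Cross terms** are symmetrized, $g_{\mu\nu} \leftarrow
  (\hat g_{\mu\nu} + \hat g_{\nu\mu})/2$, and tensor estimates are
  projected onto the positive semi-definite cone by eigenvalue clipping;
  clipping events are counted in the returned object.
* **Uncertainties** are delete-one-block jackknife errors over ten
  contiguous blocks.
* **Missing points** of the diffusion metric (never-visited grid points)
  are reported as `NA` and filled by log-linear interpolation only on
  request, with an `interpolated` flag.

## Path functionals

For a path $\lambda^\mu(s)$ the thermodynamic length is
$\mathcal{L} = \int_0^1 \sqrt{\dot\lambda^\mu g_{\mu\nu}\dot\lambda^\nu}\,ds$
and the efficiency functional is $\mathbb{V} = \int_0^1 g/\pi\,d\lambda$,
with $\mathrm{Var}\,\overline{\Delta G} \approx 2\mathbb{V}/\tau$ for total
sampling time $\tau$. Discretely, both are built from the same per-segment
lengths $\ell_i = \sqrt{\Delta\lambda^T \bar g\,\Delta\lambda}$ with
$\bar g$ the mean of the endpoint metric values. This shared discretization
is deliberate: it makes the Cauchy-Schwarz chain
$\mathbb{V}(\pi) = \sum_i \ell_i^2/\pi_i \ge (\sum_i \ell_i)^2 =
\mathcal{L}^2$ *exact* in discrete form, with equality at the optimal
per-segment target $\pi_i \propto \ell_i$ — so the property-based tests can
assert the bound and its equality case at machine precision rather than up
to quadrature slop. The theoretical improvement factor is
$\mathrm{IF} = \mathcal{L}^2/\mathbb{V}_{\mathrm{unif}} \in (0, 1]$, and the
empirical counterpart is the squared ratio of measured RMSEs, since the
statistical error decays as $1/\sqrt{\tau}$ after equilibration.

The 2D path optimizer searches the 8-connected grid graph of a tensor
field with edge costs $\sqrt{\Delta\lambda^T\bar g\,\Delta\lambda}$ using
Dijkstra's algorithm (via `igraph`). No monotonicity constraint is imposed
— the improved paths seen in practice are monotone, but nothing in the
formulation requires it, so the search space is all simple paths. An
optional band constraint $|\lambda_1 - \lambda_2| \le d$ (default
configurable, no constraint unless requested) excludes corners where the
two coupling dimensions are very different. The tests validate the search
against an independent branch-and-bound enumeration of all simple paths.

## The expanded-ensemble bias

The adaptive bias maintains free-energy estimates $f_\lambda$ (converging
to $\beta G_\lambda$ up to a constant), a target $\pi_\lambda$, and a
weight histogram. The exact update equations of production adaptive-weight
implementations are not part of this package's sources; `alchpath` uses a
stochastic-approximation surrogate chosen to satisfy the two properties
that define the method's behavior and that the test suite checks directly:

1. a robust initial stage: constant update size
   $\Delta_0 = \beta\,\epsilon_0/n_{\mathrm{points}}$ (from the
   `initial_error` parameter $\epsilon_0$), halved every time the epoch
   histogram *covers* the grid (every point above a fraction — default
   0.2 — of its target share), and
2. a final stage entered when the halving size reaches the
   Robbins-Monro size implied by the accumulated samples, after which
   $\Delta_t = m/N_{\mathrm{eff}}$ (epoch size over effective total) and
   the standard error decays as $1/\sqrt{N}$ (verified: log-log slope
   $-0.5 \pm 0.1$ over 20 seeds).

The update itself is $f \leftarrow f - \Delta\,(\hat h/\pi - 1)$ with
$\hat h$ the normalized epoch histogram. Dividing the histogram mismatch
by $\pi$ keeps the effective stochastic-approximation gain at unity for
every point regardless of how non-uniform the target is; with the plain
difference $\hat h - \pi$ the gain at low-target points would fall below
the $1/\sqrt{N}$ threshold. The gauge $f_1 = 0$ is re-fixed after every
update. The free-energy readout is $(f_{\mathrm{last}} -
f_{\mathrm{first}})/\beta$, either from the current $f$ or (option
`tail_mean`) averaged over the last quarter of the final-stage trace,
which suppresses the update-to-update jitter of $f$; the standard error
comes from block-averaging that trace.

**Dynamic target optimization** sets $\pi_\lambda \propto
\max(\sqrt{\det g(\lambda)},\ \mathrm{floor}\cdot\max\sqrt{\det g})$ from
an on-the-fly diffusion-metric estimate, only after the initial stage and
at most once every `min_target_interval` updates (default 5). The on-the-fly
estimate combines per-epoch chunk estimates with exponential forgetting
(half-life 10 updates), so pre-convergence data decays away. The 5% floor
prevents starvation of end points whose metric is tiny; without it the
discrete target can assign vanishing sampling to points that still carry
statistical weight in the free-energy difference.

## Samplers

Configuration sampling is overdamped (position) Langevin,
$x' = x - (\Delta t/\gamma)\nabla H + \sqrt{2\Delta t/(\beta\gamma)}\,\xi$
— momenta add nothing at toy scale — with two alternatives:

* **`exact_ou`** — for the harmonic family the overdamped dynamics is an
  Ornstein-Uhlenbeck process whose transition density is known exactly,
  so the sampler can use the exact AR(1) propagator
  $x' = e^{-k\Delta t/\gamma} x + \sigma_{\Delta t}\,\xi$. This removes
  Euler discretization bias entirely (the Euler update at feasible
  timesteps biases BAR/MBAR free energies by a few tenths of a percent,
  which matters when the test is "within three standard errors over 20
  seeds") while preserving the exact time-correlation structure the
  friction metric integrates.
* **`metropolis`** — single-particle random-walk Metropolis. The
  Lennard-Jones micro-solvation toy is sampled this way because
  Euler-Langevin with steep $r^{-12}$ walls is unstable at any timestep
  large enough to be affordable; Metropolis is unconditionally stable and
  the metrics remain well-defined with "time" measured in moves.

Expanded-ensemble runs alternate blocks of configuration moves (default 10
per $\lambda$ move) with full-grid Gibbs moves drawn from
$w_\lambda \propto \pi_\lambda e^{f_\lambda - \beta H(x;\lambda)}$. Gibbs
over the full grid matches the behavior of production expanded-ensemble
codes, satisfies detailed balance trivially, and makes the $w_\lambda$
vectors that the diffusion metric needs a free by-product. All stochastic
operations are pure functions of their inputs and the seed.

## The toy systems and what they do (and do not) show

* **Harmonic oscillators** (`harmonic_system`): $n$ independent particles
  with $k(\lambda) = (1-\lambda)k_A + \lambda k_B$. Everything is closed
  form: $\Delta G = n\ln(k_B/k_A)/2\beta$, mean gradient
  $n(k_B-k_A)/2\beta k$, friction metric
  $n(k_B-k_A)^2\gamma/4\beta^2k^3$, Fisher-Rao metric
  $n(k_B-k_A)^2/2\beta^2k^2$. The `n_oscillators` parameter emulates
  extensivity: with more oscillators the energy gap between neighboring
  $\lambda$ ensembles grows, the conditional weights localize, and the
  expanded-ensemble $\lambda$ walk becomes diffusive — the regime in
  which target optimization pays off. The headline variance-reduction
  experiment uses $k: 1 \to 64$ with 4 oscillators and 17 $\lambda$
  points: correlation times vary 64-fold along the path, the measured
  empirical improvement factor is well below 1, and a one-sided paired
  Wilcoxon test over 40 seeds (3 replicas each) confirms the reduction.
* **Micro-solvation toy** (`micro_solvation_system`): 16 LJ particles in
  a periodic 2D box, one solute inserted through the soft-core pair
  potential (state A: ideal gas). It exists to show the *qualitative*
  metric phenomenology of solvation: a soft-core insertion peak in the
  metric at intermediate $\lambda$, a friction profile whose dynamic
  range exceeds the Fisher-Rao profile's (time correlations vary along
  $\lambda$), and a diffusion metric that tracks friction without being
  systematically larger.
* **Two-component toy** (`two_lambda_system`): a tethered particle whose
  soft-core LJ term is switched by $\lambda_{\mathrm{other}}$ and whose
  charge-like term is scaled by a schedule $q(\lambda_c)$ with
  $q'(\lambda_c) \propto 1 + a(2\lambda_c - 1)^2$. Because the
  generalized force conjugate to $\lambda_c$ is $q'(\lambda_c)/r$, its
  fluctuations dip by $(1+a)^2$ at $\lambda_c = 0.5$, producing a
  low-metric channel across the 2D landscape. This is a *synthetic*
  analogue of the channel structure seen in ligand-mutation metric
  landscapes; its functional form is a design choice of this package, not
  fitted to any measured landscape.

Passing tests on these systems validate the estimators, the bias
machinery, and the optimization theory under controlled conditions. They
do not demonstrate force-field realism: there are no bonded terms, no
explicit electrostatics summation, no constraints, and system sizes are
orders of magnitude below molecular practice. Quantities that require
nanosecond-scale solvated MD (absolute hydration free energies, ligand
$\Delta\Delta G$ values) are out of scope by design.

## Soft-core coupling

The pair machinery implements the shared-distance soft-core scheme:
both the LJ and Coulomb components of each end state are evaluated at that
state's modified distance
$r_X = (\alpha\sigma_X^6\lambda_X^p + r^6)^{1/6}$ (with $\lambda_A =
\lambda$, $\lambda_B = 1-\lambda$), which keeps insertion energies finite
at $r = 0$ for $\lambda \in (0,1)$ and avoids the artificial minima that
separate distance functions can create. Defaults are $\alpha = 0.5$ and
$p = 1$, the values recommended in practice. The analytic
$\partial V/\partial\lambda$ (chain rule through $r_A$, $r_B$) reduces to
$V^B - V^A$ at $\alpha = 0$ and is verified against central finite
differences to $10^{-6}$ relative tolerance.

## Worked-example arithmetic

The empirical improvement factor is defined as
$(\mathrm{RMSE}_{\mathrm{opt}}/\mathrm{RMSE}_{\mathrm{ref}})^2$. Published
repeat-study tables that report RMSE pairs alongside IF columns provide a
worked-example check of this definition: the package reproduces every IF
cell that is exactly recoverable from the printed (rounded) RMSEs after
two-decimal rounding. A few printed cells differ in the last digit —
consistent with having been computed from unrounded RMSEs — and are not
asserted.

## Problem sizes and reproducibility

The shipped tests and the acceptance script use fixed, documented problem
sizes chosen so the whole validation suite runs on a single CPU in
minutes: $2\times10^5$-step series for metric oracles (relative standard
error about 5%), 20-40 seeds for repeat studies, 400-update bias runs,
$5\times5$ grids for exhaustive path enumeration. Every stochastic result
in the package is reproducible from (inputs, seed); samplers restore the
caller's RNG state.

## Known limitations

* The variance relation $\mathrm{Var} \approx 2\mathbb{V}/\tau$ assumes a
  converged bias and Markovian $\lambda$ dynamics; during early sampling
  it can misestimate the true error (observed within a factor of ~1.1-3
  on the toys, but not guaranteed).
* On the single-oscillator harmonic toy the diffusion metric exceeds the
  friction metric at the slowest end point (ratio up to ~3): with one
  degree of freedom the conditional weights are broad and the
  $\lambda$ walk is not diffusive, which inflates the weighted
  correlation. The "not systematically larger" comparison is therefore
  asserted on the micro-solvation system, where the diffusive regime
  holds.
* The shortest-path optimizer returns grid-angular paths; smoothing the
  optimum (the true optimal path is not angular) is out of scope.
* BAR/MBAR standard errors assume independent samples; no statistical-
  inefficiency resampling is applied, mirroring common practice for
  these repeat-study designs (the repeat-level RMSE and bootstrap carry
  the real uncertainty).
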