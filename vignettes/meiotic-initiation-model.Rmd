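---
title: "A dynamic model of yeast meiotic initiation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A dynamic model of yeast meiotic initiation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meioticODE)
```

## The model

Budding yeast commits to meiosis (sporulation) through a small signaling
network converging on Ime1, the master transcriptional activator of early
meiotic genes, and Ime2, a kinase encoded by an early gene that serves as
the most downstream readout of the pathway. `meioticODE` implements this
network as six coupled nonlinear ODEs over dimensionless relative protein
levels:

* **Rim11, pUme6, pSok2** are active-form fractions of conserved one-unit
  pools (kinase, DNA-binding partner, repressor). Only phosphorylation and
  dephosphorylation move material between the two forms, so each variable
  lives in $[0, 1]$. PKA is not an explicit variable: its activity is
  carried by the phosphorylation rates of Rim11 and Sok2.
* **Ime1** is synthesized under inhibitory Hill control by pSok2
  ($s_{ime1}\,c_{ime1}/(c_{ime1}+pSok2)$), phosphorylated by Rim11 (mass
  action), and degraded both basally and through an Ime2-activated
  saturating term $d'_{ime1}\,Ime2\cdot Ime1/(c_1+Ime1)$.
* **pIme1** accumulates from Rim11-mediated phosphorylation and decays at a
  first-order rate.
* **Ime2** is produced by pUme6 together with pIme1, amplified by
  cooperative auto-regulation $s'_{ime2}\,Ime2^n/(c_2^n+Ime2^n)$, and
  degraded in a density-dependent manner
  $d_{ime2}\,Ime2/(c_3+Ime2)$.

Three feedback loops structure the dynamics: double-negative feedback
between Ime1 and pSok2 (mutual inhibition, functionally positive), negative
feedback from Ime2 to Ime1 via degradation, and positive auto-regulation of
Ime2. The Hill coefficient $n$ of the auto-regulation defaults to 5; it is
a parameter (`hill_n`) because the cooperativity it encodes — the loop
stands in for several interactions converging on Ime2 — is itself an object
of study, and monostable/bistable behavior switches between $n = 3$ and
$n = 5$.

All rates are per hour; the baseline parameter set is returned by
`default_parameters()`. Simulations start from the mitotic (pre-sporulation)
state: every variable at zero except the repressive pSok2 pool at its
maximum of one.

```{r baseline}
ss <- find_steady_state()
round(ss$state, 2)
```

## Infinite constants and knockouts

Perturbation experiments delete a regulatory term by sending its
half-maximum constant to infinity. The four limit-capable constants
(`c_ime1`, `c_sok2`, `c1`, `c2`) accept the value `Inf`, which the
right-hand side evaluates as the analytic limit: an inhibitory factor
becomes exactly 1, an activation factor exactly 0. This avoids floating
overflow while preserving the intended semantics.

Gene knockouts clamp the deleted protein's variables at zero with zero
derivative *and* zero the corresponding synthesis rates, rather than merely
zeroing initial conditions: a deletion removes the gene product permanently.
For `SOK2` only the phosphorylated (repressive) form appears in the
equations, so clamping `psok2` fully specifies the deletion. This
construction reproduces all knockout phenotypes: zero Ime2 for the four
sporulation-deficient deletions, and damped oscillations with enhanced
Ime2 for the sporulation-proficient `sok2` deletion.

## Numerical choices

* **Integration**: `deSolve` with `lsoda` by default, relative tolerance
  `1e-8`, absolute `1e-10`, with the analytic Jacobian supplied to
  stiff-capable methods. Results are cross-checked in the test suite
  against an explicit Runge-Kutta (`ode45`) and a BDF integrator to a
  `1e-6` max-norm.
* **State clamping**: adaptive solvers can undershoot zero by about the
  absolute tolerance; values above $-10^{-9}$ are clamped to zero before
  evaluating the equations (Hill terms are undefined for negative levels).
  Larger negative inputs are an error.
* **Divergence**: any component exceeding `1e3` flags the trajectory as
  diverged and truncates it. Wild-type levels are $O(1)$; the only
  unbounded regime is deletion of the Ime2-to-Ime1 negative feedback, where
  Ime2 grows without bound at a few units per hour (it crosses the bound
  after roughly 230 h, so divergence checks integrate to 500 h).
* **Steady states**: integrate to 500 h, then polish with damped Newton
  using the analytic Jacobian on the non-clamped coordinates; convergence
  demands a right-hand-side max-norm below `1e-10`. If Newton leaves the
  admissible box the integrator end point is kept.
* **Transient features**: the peak is the global interior maximum refined
  by local quadratic interpolation; width is full width at half maximum
  above the pre-stimulus baseline of zero (the source analyses speak of
  "peak width" without defining it; FWHM is the standard choice). Local
  maxima are filtered by topographic prominence (default `1e-3` of the
  profile range) so that sub-resolution ripples in the final creep toward
  steady state do not count as oscillations. The default 24-h grid uses
  961 points (0.025 h), which resolves the ~6 h Ime1 peak; halving the
  spacing moves the reported peak time by less than 0.05 h.

## Equilibria, stability and bistability

Equilibria are found by multi-start damped Newton iteration. Seeds combine
closed-form quasi-steady values for Rim11, pUme6, pSok2 and pIme1 with a
coarse grid over Ime1 ($\{0.01, 0.05, 0.2, 0.5, 1\}$) and 12 log-spaced
Ime2 values up to 50 — the high-Ime2 branch sits well above 1. Duplicates
are merged at a `1e-6` max-norm; stability comes from the eigenvalues of
the analytic Jacobian (margin `1e-8` on the leading real part).

Branches along a parameter use natural-parameter sweeps in both directions
with warm starts plus fresh multi-starts at every grid point, rather than
pseudo-arclength continuation: the six-dimensional system is cheap enough
that multi-start robustly finds disconnected branches without tangent
bookkeeping. Grids are logarithmic for half-maximum constants (varied over
orders of magnitude) and linear for rates. Fold points bounding a bistable
interval are located by bisection on the *stable*-equilibrium count to a
parameter tolerance of `1e-3`.

The stable-count definition matters. At `hill_n = 3` there is a narrow
window of `c2` with three equilibria, but the low-Ime2 equilibrium is
unstable there (a focus that has shed its stability), so at most one
*stable* state exists and `bistable_interval()` correctly reports no
bistability — consistent with the monostable phenotype of low
cooperativity. Genuine bistability, two attracting states separated by a
saddle, appears at `hill_n = 5` for `c2` roughly in $[0.5, 0.7]$ and over
a strictly wider interval at `hill_n = 7`.

A related subtlety: along `c_ime1`, `c_sok2` and the coupled PKA scale, the
intermediate segment of the branch is an unstable focus surrounded by a
limit cycle (trajectories there oscillate with slowly decaying or sustained
amplitude). The package classifies equilibria only; it does not continue
limit cycles (no Hopf machinery), which is a known limitation. Scan ranges
wide enough to show both stable segments are therefore used in the tests:
`c_ime1` in $[10^{-3}, 10]$, `c_sok2` in $[10^{-5}, 1]$, PKA scale in
$[10^{-3}, 2]$.

```{r bistable, eval = FALSE}
bistable_interval(param_name = "c2", range = c(0.1, 2), hill_n = 5)
#> $lower ~ 0.505, $upper ~ 0.676
```

## Global sensitivity (MPSA)

`run_mpsa()` implements multi-parametric sensitivity analysis: all 19
kinetic constants are sampled by Latin hypercube, each uniform on
$[\theta/10,\ 10\,\theta]$ around its baseline $\theta$ (linear scale, as
the method prescribes a uniform distribution over the range; a log-uniform
option exists but is off by default). Each sampled model is integrated from
the mitotic state and scored per variable by the sum of squared errors
against the baseline time course; samples below the mean objective are
"acceptable", the rest "unacceptable"; the sensitivity of a parameter for a
variable is the Kolmogorov–Smirnov distance between its values in the two
classes, bounded in $[0, 1]$.

Two decisions were open and resolved as follows. First, the objective's
time grid is unspecified in the source analysis; the package uses the full
per-variable time course on 0–24 h with 97 points, one classification per
variable, because sensitivities are reported per variable. Exact bar
heights therefore depend on this choice and only the qualitative rankings
are treated as reproducible. Second, divergent samples are classed
unacceptable (with an infinite objective, the threshold mean taken over
finite objectives) rather than dropped, preserving class sizes.

The reference design uses 5,000 samples; the test suite runs 300–1,000 to
keep runtimes modest, which preserves the headline rankings (Ime2 is
dominated by `s2_ime2` and `d_ime2`; Rim11 by dephosphorylation over
phosphorylation; pUme6 the reverse) in at least 9 of 10 replicate seeds at
n = 1000.

## The synthetic validation screen

The original validation correlates simulated steady-state Ime2 across wild
type and the five single-gene deletions with sporulation/pre-sporulation
ratios from a published genome-wide deletion screen. That screen is
external data and is deliberately not bundled; `read_screen()` loads a
two-column TSV so the real comparison is one call for users who have it.

For self-contained testing, `synth_screen()` emulates the screen: one
positive ratio per genotype, linked to simulated Ime2 by
$\mathrm{ratio} = (a\,\mathrm{Ime2} + b)\,e^{\varepsilon}$ with
$\varepsilon \sim N(0, \sigma^2)$. The link is affine with multiplicative
lognormal noise because ratios are positive, fold-type quantities; defaults
$a = 1$, $b = 0.1$, $\sigma = 0.2$ give a clearly positive baseline for the
zero-Ime2 genotypes and noise large enough to be visible but not to destroy
rank order. With $\sigma = 0$ the Pearson correlation is exactly 1 by
construction; at $\sigma = 0.2$ the median correlation across 200 seeds
exceeds 0.8, dominated by the contrast between the four zero-Ime2
genotypes and the two expressing ones. What passing these tests shows is
that the *pipeline* recovers a monotone signal under realistic noise — not
that the model matches the real screen, which requires the external data
(reported there: r = 0.85, p = 0.033).

## Problem sizes used in the checks

Steady states integrate 500 h before polishing; divergence checks use
500 h; initial-condition independence uses 100 random admissible starts;
bistable-interval bisection refines to `1e-3` in the parameter; branch
scans use 15–25 grid points; MPSA checks use 60–1,000 samples with the
sampled runs integrated at relative tolerance `1e-6`; the synthetic-screen
recovery uses 200 seeds. These sizes are the package's own defaults for a
thorough-but-quick desk check; the full 5,000-sample MPSA design remains
the default of `run_mpsa()`.

## Known limitations

* No limit-cycle continuation or Hopf detection: oscillatory regimes are
  visible in time courses (and flagged by `transient_features()`), but
  branch diagrams only classify equilibria.
* No stochastic simulation; the model is deterministic by construction.
* Upstream regulators (PKA, Cln3/Cdc28, Msn2/4, Snf1, Ndt80) are folded
  into rates and feedback terms, so the model cannot resolve perturbations
  that act on them separately from the terms that carry them.
* Double or higher-order knockouts are expressible but have no reference
  phenotypes; only single deletions are validated.
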