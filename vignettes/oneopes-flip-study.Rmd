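---
title: "Mapping a gated base-flip equilibrium with a OneOPES-style replica ladder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a gated base-flip equilibrium with a OneOPES-style replica ladder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(flipsampler)
```

## The problem

A purine base flipping between a "stacked-in" and a "bulged-out" orientation
is a textbook rare event: the two states are separated by tens of kJ/mol, and
the flip is *gated* by a slow, orthogonal rearrangement of the hydration
shell. A biased simulation that pushes only along a flip coordinate stalls,
because the hidden coordinate must also cross. The protocol implemented here
combines a trained linear collective variable (CV), an adaptive kernel bias
with a hard energy cap, auxiliary low-barrier biases on the hidden degrees of
freedom, a multithermal ramp, and replica exchange — and then recovers
unbiased free-energy differences by reweighting.

All internal units are kJ/mol, nm, ps and K with
`kB = 0.0083144621 kJ/mol/K`; interfaces quoting kcal/mol convert at 4.184.

## The synthetic system

`make_flip_model()` builds the analytic stand-in

$$U(x, y) = a\,(x^2-1)^2 + b\,x + \tfrac{k_y}{2}\,\bigl(y - y_0(x)\bigr)^2
  + \varepsilon_L\, g(x), \qquad y_0(x) = y_\mathrm{mid} + y_\mathrm{amp}\tanh 2x,$$

with the flip coordinate $x$ (stacked near $-1$, bulged near $+1$) and a
hydration-like coordinate $y$ whose preferred value shifts by
$2\,y_\mathrm{amp}$ across the flip. The smooth indicator
$g(x) = (1+\tanh g_k x)/2$ selects the bulged basin, so a ligand term
$\varepsilon_L \ge 0$ destabilizes it — emulating a binder that holds the
stacked state. Key choices:

- **Tilt solved, not set.** The tilt $b$ is found by root-finding so that the
  *quadrature* free-energy gap between the basins (trapezoid integration of
  $e^{-\beta U}$ on each side of the separatrix, the maximum of the 1D
  potential of mean force) equals the requested target. Every simulated
  estimate in this package is therefore judged against an exact oracle, not
  against another simulation.
- **Defaults are the study conditions.** The apo gap defaults to
  −10.9 kJ/mol (−2.6 kcal/mol) and the ligand term to 12.6 kJ/mol, which
  shifts the gap to ≈ −23.4 kJ/mol (−5.6 kcal/mol); barrier parameter
  $a = 20$ kJ/mol. The hydration mean runs from ≈ 9 (stacked) to ≈ 15
  (bulged) in arbitrary hydration units, mirroring the coordination-number
  ranges such a CV takes on a real hairpin.
- **The gate.** $k_y$ = `coupling` × kT(300 K)/nm² with `coupling = 0.2` by
  default, and the $y$ mass is 5× the $x$ mass: a lagging $y$ raises the
  effective flip barrier by up to $\tfrac{k_y}{2}(2 y_\mathrm{amp})^2 \approx
  9$ kJ/mol and relaxes slowly. The magnitude of this hidden barrier is a
  free model parameter (no experimental anchor exists for it); 0.2 makes the
  gate felt but not pathological.
- **Features.** Ten contact-like distances $d_i = m_i + s_i \tanh 2x +
  \mathcal N(0, \sigma_f^2)$ with seeded one-off $m_i, s_i$ and
  $\sigma_f = 0.05$ nm, so HLDA has a recoverable discriminant direction
  (it is $\propto s$).

`run_langevin()` integrates BAOAB with a counter-based RNG keyed by
(seed, replica, stream): every noise value is a pure function of its counter,
replicas are reproducible independently of scheduling, and the pure-R
reference integrator reproduces the compiled path bitwise. `sample_basin()`
confines dynamics with a reflecting wall at the separatrix to draw labeled
training ensembles.

## HLDA

`train_hlda()` uses the closed form $w \propto (\Sigma_A^{-1} +
\Sigma_B^{-1})(\mu_A - \mu_B)$ with ridge-regularized covariances (default
$10^{-6}\,\mathrm{tr}\Sigma/d$), unit-norm output, and the sign fixed so
class A ("stacked") sits at the lower CV value. This maximizes the Rayleigh
quotient whose within-class scatter is the *matrix* harmonic mean
$(\Sigma_A^{-1}+\Sigma_B^{-1})^{-1}$; the tests verify it against a
10⁴-direction brute-force scan of that quotient. Note that the superficially
similar objective with a scalar harmonic mean of projected variances is a
different (and not closed-form-solvable) criterion — on strongly anisotropic
classes the two maximizers differ by tens of degrees, so the distinction
matters and is pinned by a test.

On the toy feature map the trained combination collapses to
$A + B\tanh 2x$, which is the deterministic form the engine biases
(`hlda_as_toy_cv()`). Coefficients apply to distances in nm; the built-in
`premir21_hlda()` records the published ten-contact CV and this unit
convention explicitly, and `export_plumed_cv()` emits it as DISTANCE +
COMBINE lines for external engines.

## The OPES-Explore layer

Each layer estimates the *sampled* distribution with unit-weight Gaussian
kernels (deposited every `pace` steps, bandwidth $\sigma_0
n^{-1/5}$, merged within one bandwidth) and applies

$$V(s) = (\gamma-1)\,kT\,\log\Bigl((1-\varepsilon)\,\frac{\tilde p(s)}{Z} +
\varepsilon\Bigr), \qquad Z = \sup_s \tilde p(s),\quad
\varepsilon = e^{-\beta\Delta E/(\gamma-1)}.$$

With this normalization $\sup V = 0$ and $\inf V \ge -\Delta E$ *exactly, at
every step and for every kernel set* — the barrier parameter is a hard cap,
which the tests enforce on a thousand randomized kernel sets. (The common
formulation without the $(1-\varepsilon)$ mixing exceeds its nominal cap by
$(\gamma-1)kT\log(1+\varepsilon)$, several kJ/mol at these settings.) The
bias factor defaults to $\gamma = \beta\Delta E$, clamped above 1 so that
$\Delta E \to 0$ gives $V \to 0$. The engine evaluates the bias on a cached
2001-point grid with linear interpolation; the R-level `opes_bias()` is
exact (golden-section-refined supremum) and is what tests and reweighting
use. $\sigma_0$ defaults to the CV fluctuation observed before the first
deposition.

The multithermal layer is an expanded ensemble over inverse temperatures,
$V(U) = -\beta_0^{-1}\log \frac1J\sum_j e^{-(\beta_j-\beta_0)U +
\beta_0\lambda_j}$, with shifts $\lambda_j$ adapted on the fly from running
log-sum-exp estimates of each ensemble's free energy (`adapt_shifts()` is the
same estimator exposed on histories; it is idempotent at convergence and
recovers the harmonic closed form $\tfrac{kT}2\ln(T_2/T_1)$ per mode in the
tests). Five grid points per replica span 300 K to that replica's ceiling.

## The ladder

`build_default_ladder()` reproduces the published arrangement: replica 0
carries only the main HLDA layer (ΔE = 20 kJ/mol) and is the convergence
stream; replicas 1–7 cumulatively add the hydration CV and torsion-like CVs
as low-barrier layers (ΔE = 3 kJ/mol) and are progressively heated to
ceilings 302, 304, 306, 308, 310, 314, 320 K. Configurations (never bias
states) swap in even/odd alternating neighbor attempts every 2000 steps under
the Metropolis rule on the total bias difference. The published deposition
paces (20000/40000 steps) remain the defaults of `LadderConfig`; the
desk-scale study overrides them to 500/1000 because its trajectories are
10⁴× shorter than the 400 ns originals — the bias should still see thousands
of depositions.

## Reweighting and ΔG

`reweight_weights()` implements the static-final-bias estimator
$w_t \propto e^{V_\mathrm{final}(s_t)/kT}$ (the engine recomputes the final
bias at every recorded frame), the simplest estimator consistent with
reweighting an accumulated bias; the first 20% of each run is discarded as
the bias-filling transient. `basin_delta_g()` reports the population
estimator $-kT\ln(P_A/P_B)$ *and* the minima-depth difference (both appear
in outputs since either convention is used in the literature), a
growing-prefix ΔG(t) series, and a 20-block bootstrap error; the separatrix
defaults to the FES maximum between the two lowest minima.
`convergence_report()` declares a plateau when consecutive window means agree
within tolerance (default 0.5 kT). Block bootstraps underestimate errors when
round trips are scarce — the convergence gate, not the error bar, is the
honest instrument there.

## The study pipeline and problem sizes

`run_study()` chains the stages per condition — basin sampling (2000 samples
each), HLDA training on apo (the holo condition reuses the apo-trained CV,
assuming the ligand keeps its binding mode in both states), the 8-replica
ladder, reweighting onto (HLDA, hydration), ΔG with convergence report, and
the structural analytics on a feature-embedded pseudo-structure trajectory.
The default step budget is 8×10⁶ steps per replica (dt = 0.002 ps, friction
10 ps⁻¹): the holo gap (≈ 9.4 kT) exceeds the 20 kJ/mol bias cap, so its
population estimator needs the extra round trips; the compiled core covers
this in ≈ 80 s per condition on one CPU. Halving the budget visibly degrades
the holo estimate while apo stays converged — the convergence flag in the
report, not silence, is the designed failure mode.

What the toy validates: CV training, bias correctness and boundedness,
exchange statistics, estimator consistency against exact quadrature truths,
and the qualitative ligand phenomenology (stiffened landscape: lower RMSF,
weaker cross-correlations, smaller leading eigenvalue). What it cannot show:
force-field realism, explicit solvent, or the absolute kcal/mol values of a
real hairpin — those live at cluster scale.

The 1D double-well validation problem (quadrature truth 2 kT) uses a barrier
of 8 kJ/mol with a 10 kJ/mol bias cap: tall enough that unbiased dynamics is
metastable, low enough that a 2×10⁶-step biased run accumulates the ~2000
round trips a 0.2 kT recovery check statistically requires — single-replica
static-final-bias estimates carry a seed-to-seed spread of ≈ 0.15 kT there,
and ≈ 0.25–0.35 kT on taller (12 kJ/mol) wells at the same budget.

## Trajectory analytics

Superposition is least-squares Kabsch (proper rotation, determinant +1);
RMSF/cross-correlation/principal modes superpose every frame onto the first
by default. Cross-correlation takes *one representative site per residue* as
input — the classic formula names Cα atoms, which do not exist in RNA, so the
site choice (e.g. C4′ for nucleotides) is the caller's and is recorded in
attributes rather than guessed. gromos (Daura) clustering removes the
highest-neighbor-count frame and its neighbors iteratively, ties broken by
lowest frame index, clusters relabeled by size. Zero-variance sites in
correlation maps are flagged `NA` instead of propagating NaN. Contact
frequencies count a residue pair as in contact when any inter-site distance
is below 0.4 nm (the 4 Å convention).

## Numerical choices and limitations

- Quadrature truths use the exact 1D reduction of the 2D model (the harmonic
  $y$ integrates out analytically); the 2D trapezoid route agrees and is
  exercised in tests.
- Kernel compression merges within 1.0 σ; a full grid rebuild every 500
  depositions bounds floating-point drift of the incremental updates.
- `basin_delta_g` flags an empty basin side as an infinite (not thrown) ΔG.
- The exchange scheme assumes a shared thermostat temperature; heterogeneous
  thermostats are rejected, heating lives in the multithermal layer.
- The static-final-bias estimator carries a slow transient: early post-burn-in
  frames were sampled under a shallower bias than the final one. For deep
  asymmetries this biases ΔG toward zero until enough round trips accumulate;
  runs at the default budget keep this within ≈ 1 σ of the bootstrap error
  for apo, and within ≈ 2–3 kJ/mol in the worst holo seeds.
- No MBAR/WHAM multi-ensemble combination (replica 0 alone feeds the
  estimator) and no kinetics.
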