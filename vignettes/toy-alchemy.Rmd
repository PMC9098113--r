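---
title: "Methods: alchemical RBFE estimators on analytically solvable systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: alchemical RBFE estimators on analytically solvable systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbfekit)
```

## The problem

Relative binding free energy (RBFE) calculations rank congeneric ligands of
one receptor by the difference `ΔΔG_bind = ΔG_complex − ΔG_solution`
between the two alchemical legs of a thermodynamic cycle. Two estimator
families dominate practice: windowed free energy perturbation (FEP), which
samples a ladder of fixed intermediate λ states and combines adjacent
windows with the Bennett acceptance ratio (BAR), and multisite λ dynamics
(MSλD), which treats the coupling variables at one or more substitution
sites as dynamical coordinates on a simplex and reads relative free
energies from end-state residence populations.

The numerical machinery of these workflows — bias optimization, binning,
reweighting, the BAR solver, convergence diagnostics, cycle composition,
charge routing, cost accounting — is where implementations diverge and
bugs hide, yet it does not require a molecular mechanics engine to
exercise. This package therefore replaces the physical system with the
smallest model in which every quantity has a closed form, and implements
the full estimator stack against it.

## The toy model

Each substituent *i* at site *s* is a one-dimensional harmonic well

\[ U_{s,i}(x) = E_{0,s,i} + \tfrac{1}{2} k_{s,i} (x - x_{0,s,i})^2 , \]

with one coordinate per site. The "solution" and "complex" phases define
separate wells per substituent; the complex phase differs by
substituent-specific offsets, which is the minimal representation of
binding selectivity (`ΔΔG_bind ≠ 0`). The configurational integral is
Gaussian, so relative free energies are exact:

\[ \Delta A_i = E_{0,i} - E_{0,\mathrm{ref}} +
   \tfrac{kT}{2}\ln (k_i / k_{\mathrm{ref}}), \]

with `k_B = 0.0019872 kcal mol⁻¹ K⁻¹` and a default temperature of 298 K.
`analytic_free_energy()` implements this and is cross-checked against
numerical quadrature of `exp(−βU)` to below 10⁻⁶ kcal/mol in the tests.
Note that the minimum position `x0` never enters `ΔA` — shifting a
harmonic well is free — which provides a free internal consistency check:
estimators must get the same answer however far the wells are displaced,
even though displacement controls how hard the sampling problem is.

The fixture generator (`generate_fixture()`) draws force constants,
minima and solution offsets from seeded distributions and then adds the
*requested* binding offsets in the complex phase, so the truth table is
exact by construction for any draw. What the generator emulates is the
estimator-facing structure of real campaigns: multi-substituent λ
trajectories with known end-state populations, per-window forward/reverse
energy differences with known ΔG, and perturbation networks with charged
and neutral compounds. What it does not emulate: rugged high-dimensional
landscapes, slow conformational degrees of freedom orthogonal to λ,
explicit solvent and electrostatics, finite-size charge artifacts.
Passing tests here certify estimator correctness, not force-field accuracy
on proteins.

## Sampling engine

Both coordinates and λ auxiliaries are propagated by overdamped Langevin
(Euler–Maruyama, unit friction):
`x ← x − ∇U dt + √(2 kT dt) ξ`. A thermostatted inertial integrator would
add nothing at toy scale. Step sizes are exposed (`dt`, `dt_x`,
`dt_theta`, defaults 0.05) and sit well inside the stability region of the
stiffest default well; the residual O(dt) discretization bias on a
harmonic variance is `k·dt/2` (2.5% at the defaults), far below the
stochastic tolerances used anywhere in the package. The equipartition and
χ² Boltzmann-histogram tests pin this down.

MSλD uses the implicit-constraint convention of the λ-dynamics
literature: per site,

\[ \lambda_i = \frac{e^{c \sin \theta_i}}{\sum_j e^{c \sin \theta_j}},
   \qquad c = 5.5, \]

with unconstrained auxiliaries θ. The simplex constraint (`λ ∈ [0,1]`,
`Σλ = 1`) holds by construction on every emitted frame (to 10⁻⁹;
max-shifted exponentials keep it at machine precision). The bounded
exponent keeps the auxiliary landscape ergodic, and `e^{2c} ≫ 99` makes
the `λ ≥ 0.99` end states reachable. The biased potential is
`U − Σ b_i λ_i`, so a larger bias raises that substituent's occupancy;
`population_ddg()` removes exactly this convention when reweighting. The
λ-space measure induced by the map is symmetric under permutation of
substituents, so it cancels from end-state population *ratios*; the
residual within-bin coupling above the 0.99 cutoff is far below the
stochastic tolerances.

FEP windows interpolate the two wells linearly in λ (the mixture of
harmonics is itself harmonic, so windows sample exactly known Gaussians),
while the offset terms follow the staged schedule: the outgoing
substituent's offset is decoupled over λ ∈ [0, 0.5]
(factor `max(0, 1 − 2λ)`) and the incoming one coupled over [0.5, 1]
(factor `max(0, 2λ − 1)`). A soft-core pair kernel
(`softcore_energy()`: `r_eff² = r² + α(1 − λ)`, energy scaled by λ) is
provided and tested against its endpoint/finiteness contract — it is the
standard device against end-point singularities — but the harmonic wells
are bounded everywhere, so the window mixing itself needs no soft-core
regularization.

## Adaptive landscape flattening

`run_alf()` runs a two-stage schedule of serial biased simulations —
by default 40 short runs of 1,500 steps to find the landscape, then 20
long runs of 30,000 steps to refine it, mirroring the many-short /
fewer-long shape of production ALF protocols — updating after each run by
the population-matching increment `Δb_i = −kT ln(p̂_i / p̂_ref)` with an
additive pseudocount of 1 on the raw end-state counts (the minimal
regularizer that survives zero-visit iterations; pseudocounts are confined
to ALF and never enter production estimates). The reference bias is
pinned to zero at every site. Because the converged update fluctuates
around the true free energy difference with zero mean, the final bias is
the average of the last half of the long-stage trace, which damps the
per-iteration count noise by roughly the square root of the window length.
A final validation run must visit every substituent (else a
non-convergence error names the offender) and satisfy the flatness
criterion, a max/min pseudocounted population ratio ≤ 10 (configurable;
well-flattened toy runs sit near 1–2).

Linear per-substituent biases are the only bias functional implemented;
quadratic or cross-site coupling terms used by some production ALF codes
are out of scope here.

## Estimators

**Binning.** A frame belongs to a substituent combination iff
`λ ≥ cutoff` at *every* site (default 0.99; the constructor rejects
cutoffs ≤ 0.5, which would allow double assignment); all other frames are
counted as unassigned, never redistributed.

**Population free energies.** Binned counts are Boltzmann-reweighted to
zero bias, `Ñ_i = N_i e^{−β b_i}`, and
`ΔΔG_i = −kT ln(Ñ_i/Ñ_ref)`. Adding a constant to all biases cancels
exactly. Zero counts yield `+Inf` with a flag rather than a silent
pseudocount — regularization would bias the estimate; a zero reference
count is an error. The binned-count convention (rather than per-frame
weights) is used throughout and documented here as a package choice.

**BAR.** The self-consistency condition is solved by bisection
(`uniroot` on a bracketed, monotone function) to 10⁻⁸ kcal/mol, with the
standard asymptotic variance from the Fermi-weight moments. Degenerate
overlap (all Fermi weights at machine zero on either side) produces a
warning and a flagged estimate instead of a number that looks healthy.
The test suite checks BAR against an independently coded damped
fixed-point iteration of the same condition to 10⁻⁶ on frozen samples,
plus the analytic constant-offset case and antisymmetry under direction
exchange.

**Convergence.** `convergence_series()` recomputes the leg estimate from
the first (forward) and last (reverse) fraction of every window's samples;
at `f = 1` both equal the full estimate identically. The run is flagged
converged when forward and reverse agree within a half-width band
(default 0.5 kcal/mol, the conventional "reliable estimation" bar) for
all fractions ≥ 0.5. Fractions leaving fewer than two samples are
skipped with a warning.

**Replicates and ranking.** Uncertainties everywhere are sample standard
deviations over independent replicas (5 by default for MSλD, 3 for FEP
benchmark protocols); a single replica yields a flagged, undefined SD.
Spearman correlation delegates to `stats::cor` with average-rank ties and
flags constant input as undefined.

## Cycles, routing and budgets

Perturbation networks are validated at construction: an edge must change
at least one site or protonation state, and may change net charge only by
±1 through a single (de)protonation. Legs combine as
`ΔΔG = ΔG_complex − ΔG_solution`; paths sum with quadrature
uncertainties (legs are independent simulations). Net-charge-changing
routes insert the neutral protonation-state form of each charged endpoint,
so every emitted edge satisfies the invariant; missing neutral
intermediates are reported by name. Cycle closure takes one independent
cycle per non-tree edge of a spanning forest and passes when
`|Σ| ≤ 2σ` (with σ = 0, the sum must vanish outright, as it does for
edges built from one analytic truth table). No finite-size/net-charge
corrections are applied to charged edges — at toy scale there is no
lattice electrostatics to correct for.

Budget accounting is deliberately dumb arithmetic, because conventions are
where published cost figures go wrong: `fep_budget()` counts
edges × directions × phases × replicas simulations and reports
collection-only and total (with equilibration) times separately — the
collection-only convention is the one that reproduces the standard
"12 simulations / 240 ns per edge, 168 / 3360 ns for 14 edges" figures for
the 20-window, 1 ns-collection protocol. `msld_budget()` computes ALF and
production totals from an explicit plan and records whether replicas are
counted. `pic50_to_dg()` is `RT ln 10` per pIC50 unit (≈ 1.36 kcal/mol at
298 K).

## Topology operations

The multiple-topology model keeps all substituents attached to a common
core with no energy terms spanning two substituents at one site; the
exclusion list enumerates every cross-substituent atom pair. The common
core is found by exact search for the **maximum common connected induced
labeled subgraph**: connected vertex subsets of the smallest input graph
(each ≤ 30 atoms; larger inputs are refused) are enumerated once and
matched into every other graph preserving labels, edges and non-edges.
The induced variant was chosen over edge-subgraph matching because it is
symmetric in the inputs and therefore order-independent. Ties between
equal-size cores break deterministically: smallest sorted label multiset,
then smallest atom-id mapping. Graphs are undirected with element labels
only — no bond orders, coordinates or atom typing.

Charge renormalization brings every non-exempt substituent at a site to
the site's target net charge — the arithmetic mean of the non-exempt
substituents' original nets — distributing each substituent's correction
uniformly over its atoms. Uniform distribution minimizes the largest
per-atom perturbation and makes the operation idempotent. Substituents
flagged as the (de)protonated partner of a charge perturbation are exempt
and keep their integer charge offset. After renormalization the total
charge of *every* combinatorial compound must be the same integer (to a
tolerance, default 10⁻⁶ e), or a consistency error names the offending
combination. Real charge-renormalization algorithms may distribute
corrections non-uniformly; the uniform rule is this package's documented
choice, and no published per-atom RMSD is treated as a target.

## Problem sizes and reproducibility

The shipped defaults are sized so the full test suite runs in well under a
minute and the acceptance script in seconds on one CPU: ALF
40 × 1,500 + 20 × 30,000 steps per phase, five production replicas of
50,000 steps, 20-window FEP with 500 + 2,000 steps per window, and
10⁵–10⁶-step runs for the sampler-physics checks. These are the package's
verification conditions, not recommendations for molecular systems. Every
stochastic routine takes an explicit integer seed and draws exclusively
through R's generator (including the compiled samplers), so identical
seeds give byte-identical artifacts.

## Known limitations

- One coordinate per site and harmonic wells: no orthogonal slow modes,
  so ALF convergence here is easier than on real ligands.
- Linear per-substituent biases only; no biasing-potential replica
  exchange.
- MBAR, thermodynamic integration and WHAM are out of scope (BAR only).
- The population estimator's cutoff bin retains a small within-bin
  coupling bias that vanishes as the cutoff → 1; at 0.99 it is far below
  the replica scatter at the shipped run lengths.
- The perturbation-network planner builds a reference-rooted spanning
  tree with neutral intermediates; optimal network design (LOMAP-style
  scoring) is not attempted.
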