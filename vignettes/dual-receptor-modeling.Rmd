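---
title: "Modeling dual IGF1R/InsR signaling: model, calibration and perturbation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling dual IGF1R/InsR signaling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualRTK)
```

## The biological question

Insulin (Ins) and insulin-like growth factor 1 (IGF1) act through two
structurally very similar receptor tyrosine kinases, InsR and IGF1R. Both
receptors funnel into the same two proliferation/survival cascades —
Ras/Raf/MEK/MAPK and PI3K/PDK1/Akt/mTORC1/RPS6K — which makes it hard to
inhibit IGF1R signaling pharmacologically without disturbing insulin
signaling and glucose metabolism. dualRTK implements a mechanistic
dual-receptor model whose purpose is to locate points in the shared
downstream network where the responses to the two ligands *differ*, so that
those differences can be probed experimentally.

## The model

The network is a mass-action reaction system over 16 molecular pools: the
two ligands, the two receptors, and twelve downstream proteins (IRS, SOS,
Ras, Raf, MEK, MAPK, PI3K, PDK1, Akt, TSC2, mTORC1, RPS6K), each represented
by an inactive and an active/phosphorylated state. Activation events are
single-step: an active upstream species acts catalytically on the inactive
form of its target (`flux = k * [target_inactive] * [activator]`), and every
active form has a first-order deactivation. This deliberately coarse level of
detail (no scaffolds, no double phosphorylation, no receptor isoforms or
IGF1R/InsR hybrids) is enough to generate testable, directional hypotheses.

Each receptor arm has eight specific rate constants: reversible ligand
binding (`kon`, `koff`), receptor auto-phosphorylation and surface
dephosphorylation, internalization of the phosphorylated receptor, recycling
back to the surface (the internalized, receptor-bound ligand is degraded in
that step), and activation of IRS and of SOS by the phosphorylated surface
receptor. The two arms then share one downstream network (34 shared rate
constants), reflecting that one cell responds to both ligands with the same
downstream machinery. Counting the 16 initial pool sizes, the model has 66
parameters: 16 abundances plus 34 + 8 + 8 rate constants. These counts are
enforced at build time:

```{r}
m <- build_reference_model()
m
```

Three shared parameters are central to the analyses:

* `k7` — activation of SOS by phosphorylated IRS (the IRS-to-MAPK shortcut),
* `kf203` — negative feedback of active RPS6K on phosphorylated IRS,
* `kf208` — negative feedback of active Akt on phosphorylated IRS.

Besides the canonical cascade edges, the shared network carries a small set
of literature-motivated crosstalk edges (MAPK feedback on SOS and IRS,
Ras–PI3K coupling in both directions, Akt feedback on Raf, deactivation of
active mTORC1 by unphosphorylated TSC2, RPS6K activation by PDK1, shared
free-ligand clearance, and shared internalized-receptor dephosphorylation).
Every edge is an ordinary row of the reaction table, so any of them can be
removed or re-parameterized by editing the CSV serialization
(`write_model_csv()` / `model_from_reactions()`).

### Units and conservation

Time is measured in minutes and abundances in molecules per cell (mpc);
unary rate constants are 1/min, binary ones 1/(mpc·min). Ligand doses in nM
convert to mpc linearly via `dose_to_mpc()`; the default factor 6.022e4
mpc/nM corresponds to an effective extracellular volume of 1e-13 L per cell.
Every protein pool is conserved exactly by the reaction stoichiometry —
`validate_model()` proves this symbolically and `check_conservation()`
verifies it numerically on every trajectory (drift is typically below 1e-10
relative). The only non-conserved pools are the two ligands, which decay by
free-ligand clearance and by degradation of receptor-bound ligand during
receptor recycling; this makes all responses transient over the 48 h horizon,
emulating a single stimulation bolus rather than a perfused system.

### Numerical integration

`simulate_model()` starts from the serum-starved fixed point (all
phospho/active states zero — the zero state is an exact equilibrium of the
mass-action system, so no pre-equilibration burn-in is needed) and integrates
with deSolve's stiff-capable solvers. The right-hand side is evaluated by a
compiled C routine working off precompiled flux-factor indices and sparse
stoichiometry triplets; `compile_rhs()` provides the equivalent portable R
closure, which the test-suite cross-checks against a brute-force
flux-accumulation oracle at 1e-12 relative tolerance and against an
independent integrator (`radau` vs `lsoda`) along full 48 h trajectories.
Default tolerances are `rtol = 1e-8` and `atol = 1e-10 * max(abundance)`;
the absolute tolerance is deliberately far below the negative-excursion
abort threshold (`-1e-9 * max(abundance)`), so solver undershoots of the
zero boundary stay within the clip-to-zero band instead of triggering the
blowup guard.

## The reference parameter set

The exact calibrated parameter values behind the original study are not
redistributed here; the package instead ships a synthetic **reference
parameter set** (`reference_params()`, stored as
`inst/extdata/reference_params.json`). It was constructed by hand-tuning the
model to the qualitative early-response training behavior — all four
phospho-observables rising within 5–30 min of a 10 nM stimulus, IGF1
producing a somewhat stronger response than insulin, and signals relaxing
over hours as ligand is consumed — and then verifying, not adjusting, the
behavioral properties below. Abundances are in the 3e4–2e5 mpc range; rate
constants sit well inside the default fitting bounds (1e-6–1e2 for unary,
1e-9–1e-1 for binary constants; abundances 1e3–1e6 mpc).

Two mechanistic features of the reference set matter for the analyses:

* **IRS occupancy asymmetry.** Under 10 nM IGF1, phosphorylated IRS occupies
  most of the IRS pool (~70%), whereas under 10 nM insulin it occupies ~25%.
  Relief of either IRS feedback loop therefore raises pIRS much more under
  insulin (free IRS is plentiful) than under IGF1 (the pool is nearly
  depleted) — this is the mechanism behind the differential Akt response to
  RPS6K feedback silencing, and it simultaneously keeps pMAPK essentially
  unchanged under PI3K-branch inhibitors in IGF1-stimulated cells.
* **A near-linear MAPK branch.** The Ras/Raf/MEK/MAPK stages run at modest
  occupancy (~15–20%), so relative changes in SOS drive propagate without
  strong saturation compression. The IRS→SOS route (`k7`) carries a small
  share of the total SOS drive at reference, a share about three-fold higher
  under IGF1 than under insulin; scaling `k7` up therefore boosts pMAPK more
  under IGF1.

## Inhibitor emulation

Kinase inhibitors are emulated as rate-constant reductions, not as new
species: the PI3K inhibitor (`"LY"`) multiplies the PI3K→PDK1 activation
constant by 0.1 (a 90% reduction), and the dual PI3K/mTORC1 inhibitor
(`"BEZ"`) additionally reduces the mTORC1→RPS6K constant by 90%. Under the
reference set at 10 nM IGF1 and a 30 min readout, both inhibitors leave
receptor and MAPK phosphorylation within 1% of control while reducing pAkt
to ~37% and pRPS6K to ~87% (LY) or ~13% (BEZ) of control — the dual
inhibitor suppresses RPS6K essentially completely, while 90% PI3K inhibition
alone still lets residual mTORC1 activity phosphorylate RPS6K.

```{r}
p <- reference_params(m)
cond <- rtk_condition("IGF1", 10, output_times = c(0, 30))
ctrl <- observables_at(simulate_model(m, p, cond), 30)
ly   <- observables_at(simulate_model(m, apply_inhibition(p, "LY"), cond), 30)
bez  <- observables_at(simulate_model(m, apply_inhibition(p, "BEZ"), cond), 30)
round(rbind(control = ctrl, LY = ly / ctrl, BEZ = bez / ctrl), 3)
```

The 30 min readout for inhibitor and dose-response panels is a package
choice: it is the latest of the early-response time points used for fitting.

## Calibration

### Loss

RPPA intensities come in arbitrary, antibody-specific units, so the loss
profiles one free multiplicative scale per observable: for observable $o$
with simulated values $y$ and measured values $d$ weighted by $w = 1/sem^2$,
the scale $c_o = \sum w y d / \sum w y^2$ minimizes
$\sum_i w_i (c_o y_i - d_i)^2$ in closed form, and the loss is the sum of
those minimized weighted residuals over the four observables. Profiling
(rather than sampling) the scales keeps the sampled dimension at the model's
own parameters. Only the early time points (5, 10, 30 min) enter the loss;
later points are validation-only overlays. Every sem is floored at 5% of the
observable's maximum value: besides guarding the zero-sem baseline records,
the floor tames the heavy-tailed weights that replicate-estimated sems
produce at three replicates (the inverse square of a 2-d.f. chi-distributed
sem has no finite mean, so unfloored weights let single records dominate the
fit). Failed integrations map to an infinite loss — a rejected move — rather
than an error.

### Parallel tempering

`pt_mcmc()` runs Metropolis chains in log10-parameter space under uniform
box priors, with Gaussian proposals (σ = 0.1 log10 units by default, scaled
during burn-in toward 20–40% acceptance and frozen afterwards so the
post-burn-in chain is a proper Markov chain). The default energy is half the
loss — the Gaussian negative log-likelihood — so the T = 1 chain samples the
corresponding Bayesian posterior. Chains at temperatures {1, 3.16, 10, 31.6}
attempt adjacent swaps every 10 steps with the standard replica-exchange
acceptance rule; high-temperature chains explore globally and feed good
states down the ladder. The sampler is verified against analytic oracles: a
single chain on a quadratic energy reproduces the analytic Gaussian
posterior (mean, s.d. and a χ² histogram test), and an effectively infinite
temperature flattens the posterior to the prior (KS test against uniform).
The minimum-energy sample over all chains is the **best fit**; ties break to
the earliest (chain, step) pair.

### The recovery benchmark

Because no experimental dataset ships with the package, calibration is
exercised end-to-end on synthetic data: 3 replicates, lognormal noise with
σ = 0.1 on the log scale, both 10 nM conditions, with six parameters freed
(`kint_igf1`, `kon_ins`, `kirs_ins`, `kr_mapk`, `k_akt`, `kr_s6k`) and the
rest held at truth. The six were chosen for distinct kinetic signatures —
receptor internalization and binding shape the pReceptor time course,
`kirs_ins` sets the insulin arm's downstream amplitude relative to IGF1 (the
profiled scales are shared across conditions, so cross-condition ratios are
informative), and the three downstream constants shape the pMAPK, pAkt and
pRPS6K profiles. Their priors are per-parameter boxes two decades either
side of truth, in the spirit of literature-derived ranges; the global
8-decade boxes contain ridge directions (e.g. receptor-arm gain trading off
against downstream gain under a free scale) on which no finite chain
length yields calibrated marginals. A 4-chain × 5000-step run recovers each
freed parameter to ~0.1–0.3 log10 units at the best fit, with truth inside
the central 90% of the T = 1 marginals.

## Virtual-cell ensembles

Cell-to-cell variability is represented by varying only the 14 protein
abundances while keeping the fitted rate constants fixed. `lhs_sample()`
draws a Latin hypercube with **log10-uniform** marginals (abundances span
orders of magnitude; the linear-vs-log choice is a package decision) —
exactly one sample per equal-probability stratum per dimension — and
`ensemble_bands()` simulates every virtual cell under one condition and
returns 5/15/85/95 empirical percentile curves (linear interpolation between
order statistics) per observable. The two ligand amounts are excluded from
the default ranges because the stimulation condition sets them; a custom
range matrix can include them. The full-size ensemble is N = 10,000; tests
and the acceptance script run N = 200, which is ample for band-nesting and
stratification properties.

## Perturbation scanning and sensitivity analysis

`scan_parameter()` re-simulates the model with a single rate constant *set*
to each value of an absolute grid — `{0} ∪ logspace(-6, 4, 21)` by default,
realizing a "zero to infinity" sweep — and reports
`log2((obs + ε)/(obs_ref + ε))` for pMAPK and pAkt at 5/10/30 min under
either ligand, with ε = 1 mpc guarding `log2(0)`. A grid value equal to the
unperturbed value runs through the identical code path and yields exactly
zero. Abundances are excluded from the default scan set but can be named
explicitly. The scan reproduces the package's three headline directional
predictions with the reference set:

```{r}
l2 <- function(pid, value, obs) sapply(c("IGF1", "Ins"), function(lig)
  scan_parameter(m, p, pid, grid = value, ligand = lig,
                 times = 30, observables = obs)$entries$log2fc)
round(rbind(kf203_off_pAkt = l2("kf203", 0, "pAkt"),
            kf208_off_pAkt = l2("kf208", 0, "pAkt"),
            k7_x10_pMAPK   = l2("k7", 10 * p$values[["k7"]], "pMAPK")), 4)
```

Silencing the RPS6K→IRS feedback (`kf203 = 0`) raises Akt phosphorylation at
30 min under both ligands, and more under insulin than under IGF1; silencing
the Akt→IRS feedback (`kf208 = 0`) up-regulates pAkt differentially; and a
ten-fold increase of IRS-mediated SOS activation (`k7`) raises pMAPK more
under IGF1. All three single out IRS regulation as the point where the two
receptor systems can be distinguished downstream.

`sensitivity_2x()` complements the scans with a local analysis: each rate
constant is doubled and halved, and the ratio of perturbed to unperturbed
response is reported at 5 min together with the trapezoidal AUC ratio over
0–30 min, for all four observables. The control direction (×1) returns
exactly 1, and the two opposite manipulations land on opposite sides of 1
wherever the effect is numerically resolved.

## Synthetic RPPA data

`generate_rppa()` emulates the training data's structure: per-observable
nuisance scales drawn log-uniformly from [0.5, 2] (arbitrary intensity
units), multiplicative lognormal replicate noise (σ = 0.1 by default, the
natural choice for strictly positive intensities), three replicates, and the
time grid {0, 5, 10, 30 min, 6, 24, 48 h}. Baseline (t = 0) records receive
a small positive floor (1e-3 of the observable's maximum) so scale profiling
never divides by zero. What the generator does **not** emulate — spatial
array artifacts, antibody cross-reactivity, batch effects, or any model
misspecification — bounds what passing tests show: they demonstrate the
estimation machinery is correct and well-calibrated when the model family is
right, not that the model captures real MCF7 cells.

## Problem sizes and determinism

All stochastic stages (LHS, noise generation, MCMC) are reproducible from
explicit seeds, and simulation is deterministic, so repeated runs are
byte-identical. The shipped test-suite and the acceptance script use
scaled-down problem sizes chosen to exercise every property at high power:
N = 200 virtual cells (vs 10,000 in production use), 4 × 5000 MCMC steps for
the recovery benchmark, 20,000–50,000 steps for the sampler's analytic
self-tests, and 100 random states for the RHS oracle comparison.

## Known limitations

* The reaction table is a reconstruction with the published structural
  counts, not the original edge list; nine shared crosstalk edges are
  flagged reference choices and individually removable.
* The reference parameter set is synthetic; quantitative outputs (e.g. the
  exact fold-changes above) characterize this packaged set, not any cell
  line.
* Single-step activation kinetics understate MAPK ultrasensitivity; the
  dose-response of pMAPK at low doses is the least trustworthy regime.
* Receptor isoforms, IGF1R/InsR hybrid receptors and IGF2 are out of scope.
* The sampler's marginals are calibrated only where the posterior is
  unimodal in the prior box; ridge directions of the full 64-parameter
  problem require longer ladders and chains than the packaged defaults.
* Receptor internalization (`kint`) is only weakly identified from the four
  phospho-observables in the 5–30 min window (pReceptor counts surface and
  internalized states alike): under some noise realizations the likelihood
  admits a distinct optimum with internalization shifted by nearly a decade.
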