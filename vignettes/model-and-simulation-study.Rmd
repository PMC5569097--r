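---
title: "A probabilistic cellular automaton of amoeboid-mesenchymal migration plasticity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A probabilistic cellular automaton of amoeboid-mesenchymal migration plasticity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(switchmig)
```

## The model

Invading tumor cells use two interconvertible migration modes. Mesenchymal
(M) cells move slowly, adhere to the extracellular matrix (ECM) and degrade
it proteolytically, creating paths; amoeboid (A) cells move fast, adhere
weakly, and squeeze through existing pores without degradation. `switchmig`
implements a probabilistic cellular automaton that asks when the ability to
switch between these modes — migration plasticity — lets a cell population
invade farther than any fixed mixture of the two modes.

The domain is a rectangular lattice of `S1 x S2` sites, periodic along the
vertical `r1` axis and reflecting along the horizontal `r2` axis. Each site
carries a pair of states: an occupancy (empty, or one cell with phenotype A
or M — volume exclusion permits at most one cell per site) and an ECM
resistance `mu` in [0, 1], a lumped scalar for matrix density, stiffness and
porosity as a barrier to movement.

Time advances by random sequential updates. One Monte Carlo step (MCS), the
time unit, is `n` single-cell updates for a population of `n` cells, each
picking a cell uniformly at random with replacement, so every cell is
updated once per MCS on average. The selected cell experiences three rules
in order:

1. **Phenotype switch.** An A-cell becomes M with probability
   `alpha * mu`; an M-cell becomes A with probability `beta * (1 - mu)`.
   High resistance therefore recruits the degrading mode and free space the
   fast mode. All rate constants lie in [0, 1] and are interpreted directly
   as per-update probabilities.
2. **ECM degradation.** If the cell is (now) mesenchymal, the resistance at
   its own site decays multiplicatively, `mu -> (1 - delta) * mu`, with
   `delta = 0.1` by default — degradation is partial, never complete, and
   `mu = 0` is a fixed point. Only the cell's current site is affected.
3. **Migration.** The cell attempts a move with probability
   `lambda_X(mu) = c_X / (1 + exp(15 (mu - 0.5)))`, `c_A = 1` for amoeboid
   and `c_M <= c_A` for mesenchymal cells: movement is nearly free at low
   resistance, falls steeply around `mu = 0.5` and is almost blocked at
   high resistance. The target is one of the four von Neumann neighbors,
   drawn with weights `exp(kappa)` (up-gradient), `exp(-kappa)`
   (down-gradient) and 1 (lateral); `kappa >= 0` is the chemotactic
   responsiveness and `kappa = 0` gives an unbiased random walk. The move
   executes only if the target is on-lattice and empty; otherwise it is
   aborted (exclusion process).

The chemotactic signal is the static linear field `G(r1, r2) = r2 / S2`
pulling cells toward the right edge, independent of the ECM. Because `G` is
linear with slope `1/S2`, the exponential direction weights are
dimensionless and lattice-size independent.

### The ECM fields

Two generators produce initial resistance fields. The homogeneous generator
sets a constant level. The heterogeneous generator superimposes a coherent
sinusoidal structure (spatial periods 25 lattice units vertically, 50
horizontally) on per-site uniform noise:

```
mu(r1, r2) = 1 - theta/2
           + (theta/2) sin(2 pi r1 / 25 + 3 pi/2) sin(pi r2 / 25 + pi/2)
           - (1 - theta) xi(r1, r2),     xi ~ iid Uniform(0, 1)
```

The heterogeneity parameter `theta` interpolates from completely random
(`theta = 0`) to completely coherent (`theta = 1`) structure; the spatial
mean is approximately 0.5 for every `theta`. The noise `xi` is drawn once
per site and then frozen: a single shared scalar would collapse `theta = 0`
to a flat field, which is not what a "completely random" matrix means. All
values lie in [0, 1] analytically (extremes at sinusoid ±1 and
`xi` in {0, 1}), so the generator asserts rather than clips.

### Initial conditions and observables

Runs start with `n` cells (default 50) on distinct random sites of the left
column `r2 = 1` — half M and half A for switching populations, a fixed
fraction `gamma` of M-cells for non-switching ones (`alpha = beta = 0`).
`round(gamma * n)` uses round-half-up so `gamma` in {0, 0.3, 0.7, 1} with
`n = 50` gives exactly 0, 15, 35, 50 M-cells. Runs last 200 MCS by default
on a 100 x 300 lattice: 300 columns exceed the maximal possible advance in
200 MCS, so the reflecting right boundary is never reached.

Per cell we record the migration distance `d` from the initial position;
per run the population mean `d_p`, the maximum `d_max`, and the within-run
spread. The default metric is Euclidean with the `r1` displacement reduced
to its minimal image on the torus; an axial metric `|r2 - r2_0|` (projection
on the gradient axis) is provided because the trajectory-style analyses mark
distances along that axis, and which of the two the original analyses used
is not decidable from the text. Qualitative orderings agree under both.
Replicate variability is summarized by the between-run coefficient of
variation of `d_p`; the within-run spread is reported separately.

## The simulation-study harness

`run_scenario()` compares a switching arm, scanned over switch ratios
`alpha/beta` in {1/10, ..., 1, 2, ..., 10}, with a non-switching arm scanned
over `gamma` in {0, 0.3, 0.7, 1}, at 50 replicates per grid point by
default. A ratio `r <= 1` is realized as `(alpha, beta) = (r, 1)` and
`r > 1` as `(1, 1/r)`, so both constants stay in (0, 1]. The headline
statistic is `delta_d_p`: the best switching arm minus the best
non-switching arm in replicate-mean `d_p` (positive = plasticity pays).

Derived experiments: `critical_resistance_scan()` locates the homogeneous
resistance level at which the pure-A advantage flips to pure-M (bracketing
the sign change of the arm difference, reported as the bracket midpoint);
`phase_diagram()` maps `delta_d_p` over `theta` times `c_M/c_A` (20
replicates per grid point by default — a grid-size compromise, each point
being a full two-arm scan); `kappa_sensitivity()` traces `delta_d_p`
against the chemotactic responsiveness and reports a Spearman trend;
`cooperativity_experiment()` compares a population of `n = 500` with `n`
single-cell repetitions, for switching and non-switching settings, 100
repeats per arm.

Since the sources do not state the non-switching composition of the
cooperativity comparison, the package uses the frozen 50:50 A:M mixture,
and composition-matches the single-cell arms (of the `n` single runs,
`round(gamma n)` start mesenchymal): this isolates cooperation — amoeboid
cells exploiting mesenchymal paths — from mere composition differences.

### Reproducibility

Every replicate is a pure function of (parameters, ECM descriptor, seed):
replicate `r` of a scenario seeds one RNG stream with `base_seed + r`, and
all stochastic draws — the noise field `xi`, cell placement, phenotype
assignment, cell selection, rule Bernoullis, direction draws — consume that
single stream in a fixed order. Arms and grid points share replicate seeds
(common random numbers). The compiled update loop draws from R's own RNG,
so `set.seed()` governs everything; reruns are bit-identical.

## Worked example

```{r example, eval = FALSE}
spec <- scenario_spec(ecm = ecm_heterogeneous(0.5), kappa = 1,
                      c_ratio = 0.25, replicates = 50, base_seed = 1)
res <- run_scenario(spec)
res$comparison
```

Under a highly structured ECM (`theta = 0.5`), strong chemotaxis
(`kappa = 1`) and a slow mesenchymal mode (`c_M/c_A = 0.25`), the switching
arm peaks near the balanced ratio `alpha/beta = 1` and exceeds every fixed
mixture by a wide margin (`delta_d_p` of roughly 15 lattice units); with a
fast mesenchymal mode (`c_M/c_A = 0.75`) or a homogeneous field the
advantage disappears. Raising homogeneous resistance through 0.5 flips the
best fixed mixture from pure A to pure M, mirroring the sigmoid midpoint of
the migration rate.

## Numerical and design choices

* **Rule composition.** The three rules apply sequentially (switch,
  degrade, move) within one update, with each rate in [0, 1] read as a
  per-attempt probability. The switch decision sees the resistance before
  degradation; the move rate sees it after — the value a cell experiences
  at the moment of each action. An alternative, mutually exclusive
  composition is conceivable; sequential application keeps the three
  processes' frequencies proportional to their rates.
* **Neighborhood.** Von Neumann (4 neighbors); diagonal moves would
  complicate the distance metric without support in the model description.
* **Degradation form.** Multiplicative `(1 - delta) mu`; a subtractive
  variant `max(0, mu - delta)` is exported for sensitivity checks.
* **Boundary handling in the direction draw.** Off-lattice targets keep
  their weight and the attempt is aborted at execution, which slightly
  lowers the effective mobility in the boundary columns rather than
  renormalizing toward the interior.
* **Crossover reporting.** The critical-resistance scan reports the
  midpoint of the two adjacent levels bracketing the sign change, with "no
  crossover" as a regular outcome, not an error.
* **Problem sizes.** Default testing sizes follow the study design (50
  cells, 200 MCS, 50 replicates; 20 for phase-diagram points). The
  cooperativity comparison in the regression suite runs at population size
  100 with 100 repeats; its qualitative conclusions were additionally
  verified once at the full 500-cell scale.

## What the synthetic fields do and do not emulate

The heterogeneous generator produces stationary random fields with a single
coherent length scale plus white noise. Real tumor ECM has fibrous
anisotropy, multi-scale correlations, and remodels in time; the chemotactic
field here is static and ECM-independent, and there is no proliferation,
death, adhesion, haptotaxis or durotaxis. Passing tests therefore show that
the implementation reproduces the model's behavior under these idealized
conditions — not that the conclusions transfer to any particular tissue.

## Known limitations

* **Absolute switch-rate dependence.** The switch ratio `alpha/beta` fixes
  the stationary phenotype mix, but the absolute scale of `(alpha, beta)`
  sets how fast cells adapt to local resistance changes. With per-attempt
  switch probabilities, `d_p` increases noticeably with that scale at a
  fixed ratio (adaptation lag): ratio-sufficiency holds only in the
  fast-switching limit, and exact invariance between, say,
  `(0.2, 0.2)` and `(1, 1)` should not be expected from this
  implementation.
* **Cooperativity in frozen mixtures.** The population-vs-single advantage
  in maximal migration distance is strong for switching populations but
  near zero for non-switching mixtures, where the volume-exclusion cost of
  crowding offsets the benefit of shared degraded paths.
* The macroscopic (drift-diffusion) description of the automaton is out of
  scope; so are image-derived ECM maps and time-varying gradients.
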