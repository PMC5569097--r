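# switchmig

A probabilistic cellular automaton of tumor cell invasion for studying
**amoeboid–mesenchymal migration plasticity**: under what microenvironmental
conditions does the ability of cells to switch between a fast,
non-degrading amoeboid (A) mode and a slow, matrix-degrading mesenchymal
(M) mode let a population invade farther than any fixed mixture of the two
modes? The package is aimed at computational biologists who want a small,
fully reproducible lattice model of cell–ECM interaction with a complete
simulation-study harness on top.

## The model

Cells live on an `S1 × S2` lattice (periodic in `r1`, reflecting in `r2`),
at most one cell per site (exclusion process). Each site also carries an
ECM resistance `μ ∈ [0, 1]`. Random sequential updates apply three rules to
the selected cell; `n` updates form one Monte Carlo step (MCS):

1. **Switch** — A→M with probability `αμ`, M→A with probability `β(1−μ)`:
   high resistance recruits the degrading mode, free space the fast mode.
2. **Degrade** — an M-cell reduces its own site's resistance,
   `μ → (1−δ)μ`, default `δ = 0.1`.
3. **Move** — with probability `λ_X(μ) = c_X / (1 + e^{15(μ−0.5)})`
   (`c_A = 1`, `c_M ≤ c_A`), to a von Neumann neighbor drawn with weights
   `e^{±κ}` along a static linear chemotactic gradient `G(r1, r2) = r2/S2`
   and 1 laterally; blocked or off-lattice moves are aborted.

Heterogeneous ECM fields superimpose a coherent sinusoid on per-site
uniform noise, interpolated by a heterogeneity parameter `θ` (0 = pure
noise, 1 = fully coherent; spatial mean ≈ 0.5 for all `θ`). Observables are
per-cell migration distances from the initial left-column placement and
their population summaries `d_p` (mean), `d_max` (maximum), and
`Δd_p` — the best switching arm minus the best non-switching arm across
parameter scans.

## Worked example

Compare switching and non-switching populations under a highly structured
ECM (`θ = 0.5`), strong chemotaxis (`κ = 1`) and a slow mesenchymal mode
(`c_M/c_A = 0.25`) — 50 cells, 200 MCS, 50 replicates per grid point:

```r
library(switchmig)
spec <- scenario_spec(ecm = ecm_heterogeneous(0.5), kappa = 1,
                      c_ratio = 0.25, replicates = 50, base_seed = 1)
res <- run_scenario(spec)
res$comparison
#> $delta_d_p
#> [1] 15.75918
#>
#> $best_switching_setting
#> [1] "0.9"
#>
#> $best_nonswitching_setting
#> [1] "1"
#>
#> $best_switching_d_p
#> [1] 35.00294
#>
#> $best_nonswitching_d_p
#> [1] 19.24377
```

The best non-switching mixture (pure M, `γ = 1`) reaches a mean migration
distance of about 19 lattice units, while the switching population peaks
near the balanced switch ratio `α/β ≈ 1` at about 35: under these
conditions phenotypic plasticity buys roughly 16 lattice units of extra
invasion depth (`Δd_p > 0`). Re-running with `c_ratio = 0.75` or a
homogeneous field makes the advantage vanish — plasticity pays only in
structured, resistive environments with directed migration.

Other experiment recipes: `critical_resistance_scan()` (where does the
pure-A advantage flip to pure-M as homogeneous resistance rises?),
`phase_diagram()` (`Δd_p` over `θ × c_M/c_A`), `kappa_sensitivity()`, and
`cooperativity_experiment()` (population vs single-cell maxima). A thin
command-line front end is installed at `inst/scripts/switchmig`
(verbs `simulate`, `scan`, `phase-diagram`, `cooperativity`,
`critical-scan`, `kappa-scan`, `fixtures`, `validate-config`).

See `vignettes/model-and-simulation-study.Rmd` for the full model
description, parameter meanings, design choices and known limitations.

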