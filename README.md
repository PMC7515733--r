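# transitr

Quantify **transition cells**, **intermediate cell states** and
**transition genes** from single-cell expression matrices — and generate
the ground truth to validate the inference with.

Hard clustering assigns every cell to exactly one state, which erases the
most interesting cells in a differentiating or transforming tissue: the
ones *between* states. transitr takes a genes × cells matrix and

1. builds a cell–cell **consensus matrix** `M` (mean of binary
   co-membership matrices over an ensemble of k-means/PCA clusterings),
2. estimates the number of states from the largest eigengap of the
   symmetric normalized graph Laplacian of `M`,
3. soft-clusters by **symmetric NMF**, `min_{H≥0} ‖M − HHᵀ‖²_F`, turning
   each row of `H` into a probability vector `P_i·` over clusters,
4. scores each cell's plasticity with the entropy-based **CPI**,
   `CPI_i = −(1/log k) Σ_j P_ij log P_ij`, and calls cells above a
   threshold (Otsu by default) **transition cells (TC)**,
5. lays out clusters and cells in 2-D by a **probabilistic regularized
   embedding** (attraction to cluster centers, pairwise repulsion; solved
   in closed form),
6. infers **transition trajectories** — cluster paths supported by the TC
   between them — with occurrence probabilities, CPI-ordered cells and
   segment-scaled pseudotime, and
7. extracts **cluster markers** via a membership-coupled NMF of the
   expression submatrix and **transition genes** by Spearman correlation
   along the ordered cells (|ρ| ≥ 0.64 by default).

Two generative models ship as first-class citizens:

* `run_emt_simulation()` — a multiscale agent-based model of the
  epithelial–mesenchymal transition (EMT): each cell integrates an
  18-species regulatory circuit (SNAIL/miR-34, ZEB/miR-200, OVOL2/GRHL2,
  autocrine TGF-β/SMAD, E-cadherin and Vimentin readouts) with
  multiplicative noise, divides with inheritance noise and a finite
  division budget, and dies on a clock. The default circuit has exactly
  four stable states (E, I1, I2, M); everything off-attractor is a
  ground-truth transition cell.
* `simulate_population()` / `simulate_population_sde()` — a linear
  population model of EMT through N intermediate states with three
  dimensionless rates (reverse direct rate α, chain rate γ, reverse chain
  factor β), plus three emergent metrics: adaptation sensitivity
  `AS = (max_t M − M(∞))/max_t M`, noise attenuation
  `NA = std(M̃)/mean(M̃)` and transition efficiency `TE = M(∞)`.

## Worked example

Simulate one division cycle of the EMT population and run the full
analysis on the snapshot:

```r
library(transitr)

net <- emt_network()
att <- steady_states(net, n_grid = 300, seed = 1)
att
#> <emt_attractors> 4 stable states: E, I1, I2, M
#>    ECAD  VIM SNAIL  ZEB TGFB
#> E  3.35 0.05  0.07 0.00 0.00
#> I1 1.66 0.63  2.90 0.03 0.00
#> I2 0.72 1.87  2.90 2.27 0.10
#> M  0.57 2.29  3.18 2.36 2.63

sim <- run_emt_simulation(emt_sim_config(n_cycles = 1, seed = 7), net, att)
glance(sim)
#>    time n_cells     E    I1    I2     M    TC
#> 1   700     303    70    78    61    53    41

ta <- quantify_transitions(sim$snapshots[[1]]$expression, seed = 11)
ta
#> <transition_analysis> 303 cells, 18 genes, k = 4, 104 transition cells
#> <trajectory_set> 3 trajectories from C4
#>   C4-C3-C2-C1: 100% of cells
#>   C4-C3-C2: 75.6% of cells
#>   C4-C3: 44.6% of cells
```

The eigengap recovers the four planted states, the hard labels match the
ground-truth phenotypes exactly (adjusted Rand index 1.0 on settled
cells), and the top trajectory traverses the full E–I1–I2–M axis. Per-cell
results are a tibble (`tidy(ta)`): cluster, CPI, TC flag, embedding
coordinates, membership probabilities and pseudotime;
`autoplot(ta)` draws the embedding colored by CPI, and `write_results(ta,
dir)` emits the TSV/JSON bundle.

The population model's trade-offs, on the reduced γ grid at N = 2
intermediates:

```r
sweep_population_metrics(gamma = c(5, 20, 80), n_ics = 2, seed = 1)
#>   alpha  beta gamma n_ics      as    na    te
#> 1     8  0.01     5     2 0.0109  0.458 0.199
#> 2     8  0.01    20     2 0.0133  0.448 0.463
#> 3     8  0.01    80     2 0.00122 0.365 0.764
```

Raising the chain rate γ attenuates noise (`na` falls) and boosts
transition efficiency (`te` rises), while adaptation sensitivity peaks at
an interior γ and then declines — efficiency and adaptation cannot be
maximized by γ alone. Increasing the number of intermediate states N (at
fixed γ) does the opposite: it buys adaptation and noise attenuation at
the cost of efficiency.

Command-line wrappers for the three entry points live in `inst/cli/`
(`run_pipeline.R`, `simulate_emt.R`, `population_sweep.R`), each a thin
shell over the functions above.

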