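# paircomm

Two-type spatial microbial communities — biofilms, monolayer colonies,
synthetic cross-feeding consortia — organize themselves through short-range
molecular exchange: each cell's growth depends on who sits within the few
microns its metabolites travel. `paircomm` is an R package for scientists
who want to predict community-level steady states (species composition,
spatial clustering, community productivity, collapse) from measurable
quantities at lower levels, without simulating every molecule.

It stacks three connected layers:

1. **Biophysics → local rules.** From the diffusion coefficient `D`, uptake
   rate `r_u` and leakage rate `r_l` of each exchanged molecule (plus cell
   geometry and density), compute the interaction range `R`, the
   neighborhood size `r` (`∝ R²` in monolayers, `∝ R³` in 3D biofilms) and
   the maximum growth rate `μ̂` of each cell type — including the case where
   rates differ between producer and consumer.
2. **Local rules → community.** A pair approximation on a *directed* regular
   graph (the two types may have different neighborhood sizes `r_A ≤ r_B`)
   yields closed-form steady states:

   ```
   P(A)  = [ μ̂_A (r_A−2)/r_A + (μ̂_A/r_A − μ̂_B/r_B) ] /
           [ μ̂_A (r_A−2)/r_A + μ̂_B (r_B−2)/r_B ]          (spatial)
   P(A)  = μ̂_A / (μ̂_A + μ̂_B)                               (well-mixed)
   P(B|A)/P(B) = (r_A−2)/(r_A−1)                            (local structure)
   ```

   plus the community productivity (mean birth rate) and the interval of
   growth-rate ratios outside which a spatially structured community
   collapses even though its well-mixed counterpart would coexist.
3. **Validation by simulation.** A fast stochastic cellular automaton
   (Rcpp) implements the same birth–replacement process on a periodic
   lattice with per-type extended Moore ranges, with spatial observables
   and a clustered-versus-randomized productivity experiment on snapshots.

Density-dependent and mutual-inhibition growth models are included, and
arbitrary growth functions are solved numerically.

## Worked example

The cross-feeding community of two *E. coli* auxotrophs (a proline
non-producer trading with a tryptophan non-producer) is parameterized by
`r_A = 10`, `r_B = 130` and growth-rate ratio `0.22 / 0.78`:

```r
library(paircomm)

rules <- local_rules(10, 130, 0.22, 0.78)
productivity(rules)
#> Pair-approximation equilibrium
#>   P(A) = 0.2034  P(B|A) = 0.7081  P(A|B) = 0.2018
#>   productivity: spatial 0.1571, well-mixed 0.1716 (ratio 0.915)
```

The slow, short-range type settles at a global frequency of 0.20 — slightly
below the 0.22 a well-mixed model predicts — while spatial clustering costs
the community 8% of its well-mixed productivity (ratio 0.92). The matching
lattice simulation (interaction ranges 1 and 5, i.e. 8 and 120 neighbors):

```r
cfg <- ca_config(d_A = 1, d_B = 5, mu_hat_A = 0.22, mu_hat_B = 0.78,
                 d_R = 1, seed = 100, n_events = 100000)
ens <- ca_ensemble(cfg, n_replicates = 20)
ens$summary[ens$summary$observable == "P_A", ]
#>   observable    mean          sd  ci_lower  ci_upper
#> 1        P_A 0.18898 0.003420465 0.1874809 0.1904791
```

The simulated equilibrium (0.189, CI ±0.002) sits just below the
pair-approximation value, as expected when the closure slightly
underestimates clustering. Spatial observables work on any snapshot:

```r
run <- ca_run(ca_config(d_A = 1, d_B = 1, mu_hat_A = 1, mu_hat_B = 1,
                        seed = 3, n_events = 100000))
clustered_vs_randomized(run$final_grid, run$config, seed = 5)
#> [1] 0.8858096  (attributes omitted)
```

i.e. the equilibrated community grows ~11% slower than the same cells
randomly arranged — the cost of being surrounded by your own offspring.

A command-line front end is installed with the package
(`system.file("exec/paircomm", package = "paircomm")`) with subcommands
`local-rules`, `equilibrium`, `trajectory`, `simulate`, `stats`,
`randomize-experiment` and `pipeline`, all driven by a YAML configuration
(see `?load_config`) and emitting TSV.

The methods vignette
(`vignettes/pair-approximation-methods.Rmd`) documents the model
assumptions, the moment-closure derivation, and every numerical choice.

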