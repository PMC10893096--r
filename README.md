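# commfba

Personalized gut microbial community modeling with individual-based flux
balance analysis.

## The problem

Compositional 16S surveys tell you *who* is in a gut microbiome but not
*what the community does metabolically* — and two cohorts (say, Parkinson's
disease patients and matched controls) can differ more in predicted
metabolite output than in taxon lists. `commfba` implements the full chain
from a zOTU count table to group-level differences in simulated metabolite
production:

1. **Sequence mapping** — each zOTU representative 16S sequence is aligned
   (ends-free global alignment: match +1, mismatch −1, gap −2, free terminal
   gaps) against the 16S sequences of a genome-scale metabolic model
   collection and assigned to its closest neighbor at ≥ 97% identity.
2. **Community building** — per sample, taxa sharing a model are pooled,
   members below 2% relative abundance are dropped, the rest renormalized.
3. **Diet constraints** — per-participant nutrient intakes (g/day) become
   millimolar inputs, `mM = g / MW / V · 1000`, blended 99%/1% with a
   Western-style reference diet so every model's trace requirements are met.
4. **Spatial community FBA** — every bacterium is an individual agent on a
   60 × 60 grid (one agent per cell, 400 founders by default). Each hour,
   each agent solves the linear program

   maximize c·v subject to S·v = 0, lb ≤ v ≤ ub

   with its uptake bounds capped by the metabolites locally available,
   grows as `biomass · (1 + μ·Δt)`, exchanges metabolites with its grid
   cell (negative exchange flux = uptake), divides at twice the founder
   biomass, moves, and metabolites diffuse. After 12 h × 10 replicates the
   end-point concentrations (mM) are collected.
5. **Statistics** — alpha diversity (observed, Shannon, inverse Simpson),
   Bray–Curtis and weighted/unweighted UniFrac with ANOSIM and
   PERMANOVA/Adonis (9999 permutations), Spearman/FDR diet–clinical
   correlations, and per-metabolite Wilcoxon + Gaussian GLM group
   comparisons with Benjamini–Hochberg correction.

A first-class synthetic-data module generates every input with known ground
truth (toy models with analytic growth yields and cross-feeding chains,
group-structured negative-binomial counts with planted differential taxa,
16S-like sequences at controlled divergence, phylogenies, diets), so the
whole pipeline runs and is validated at desk scale with no downloads.

## Worked example

A two-species cross-feeding chain: `sp01` eats the diet nutrient and
secretes a byproduct which is `sp02`'s only substrate.

```r
library(commfba)

toy <- make_toy_models(2, "cross_feeding")   # uptake 10, yield 0.1
solve_fba(toy$models$sp01)$fluxes
#> EX_nut01_e    trans01  biomass01  EX_by01_e
#>        -10         10          1          5

arena <- init_arena(
  community = c(sp01 = 0.6, sp02 = 0.4),
  models    = toy$models,
  diet      = c(nut01_e = 50),               # mM
  n_init    = 400, shape = c(60, 60), seed = 42)
sim <- run_simulation(arena, hours = 12, replicates = 10)
sim
#> <simulation_result> 10 replicates x 12 h, 3 metabolites, mean occupancy 1.000
round(colMeans(sim$end_concentrations), 2)
#> nut01_e  by01_e  by02_e
#>    0.31   22.92    0.96
flux_attribution(sim)
#>   species metabolite produced_mmol consumed_mmol production_pct
#> 1    sp01    nut01_e    0.00000000    0.49694697             NA
#> 2    sp01     by01_e    0.24847348    0.00000000            100
#> 3    sp02     by01_e    0.00000000    0.01927002              0
#> 4    sp02     by02_e    0.00963501    0.00000000            100
```

Reading the numbers: the grid fills completely within 12 h (occupancy 1.0);
`sp01` consumes 0.497 mmol of the 0.5 mmol nutrient pool (50 mM × 0.01 L)
and secretes half of it (stoichiometry 5 per 10) as `by01`, of which `sp02`
consumes 0.019 mmol to grow — so the cross-feeder is alive exactly because
its producer is present. End concentrations are total mmol divided by the
0.01 L arena volume.

The full synthetic cohort runs through one call:

```r
res <- run_pipeline(scaled_config(planted_species = "sp03", planted_lfc = 2,
                                  mean_grams = 300, seed = 7))
head(res$endpoints)   # per-metabolite Wilcoxon/GLM group comparison
```

or from a shell, `Rscript scripts/run_pipeline.R --out results/ --seed 7`.

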