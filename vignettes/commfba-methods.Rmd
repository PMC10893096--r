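---
title: "Methods: individual-based community flux balance analysis from 16S data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: individual-based community flux balance analysis from 16S data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(commfba)
```

# Overview

`commfba` reconstructs a personalized gut microbial community for each
participant of a two-group cohort and asks whether the *predicted metabolic
output* of those communities differs between groups. The chain is: map 16S
zOTU sequences to a collection of genome-scale metabolic models, build
per-sample communities, translate each participant's diet into millimolar
metabolite inputs, simulate every community as individual bacteria on a
spatial grid where each individual solves flux balance analysis (FBA)
against its local environment, and compare end-point metabolite
concentrations (and classical community-ecology statistics) between groups.

This vignette documents the model and its assumptions, every tunable
parameter that matters, the synthetic-data generator, and the numerical and
design decisions taken where the procedure was genuinely open.

# Flux balance analysis

A metabolic model is a stoichiometric matrix $S$ (metabolites × reactions)
with flux bounds $lb \le v \le ub$ (mmol/gDW/h) and a biomass objective
reaction. FBA solves

$$\max_v \; c^\top v \quad \text{s.t.} \quad S v = 0,\; lb \le v \le ub,$$

where $c$ selects the biomass reaction; the optimum $\mu$ is the specific
growth rate (1/h). Exchange reactions move a single extracellular
metabolite across the system boundary; **negative flux is uptake, positive
is secretion** (the AGORA/VMH convention), enforced throughout.

Implementation notes:

* The solver is a dense bounded-variable two-phase primal simplex
  (C++/Armadillo), refactorizing every iteration and pivoting by Bland's
  rule — the $b = 0$ FBA system is maximally degenerate and Bland's rule
  guarantees termination. Primal feasibility tolerance is $10^{-9}$
  (configurable). All bounds must be finite; the SBML reader clamps
  "infinite" bounds at $\pm 10^6$.
* LP degeneracy: many flux vectors attain the optimum. The package reports
  one optimizer; tests assert only the objective value, steady state
  ($\max |Sv| \le 10^{-9}$) and bound feasibility, never a particular flux
  vector.
* Infeasible problems return a status rather than raising: inside the
  simulator an infeasible agent simply does not grow that step.
* The canonical model format is a small JSON dialect
  (`{id, metabolites[], reactions[{id, stoich{}, lb, ub}], objective}`)
  written and read by the package itself; SBML Level 3 + FBC reading is a
  thin xml2 adapter covering the subset needed for curated collections.
  Exchange reactions are auto-detected as reactions touching exactly one
  *extracellular* (compartment `"e"`) metabolite; intracellular
  single-metabolite sinks (e.g. a biomass drain) are deliberately excluded.

# Sequence mapping

zOTU representatives are aligned to each model's 16S reference with an
ends-free ("overlap") global alignment: match $+1$, mismatch $-1$, gap $-2$
per position, terminal gaps free. Identity is matching columns divided by
aligned columns (terminal-gap columns excluded). Ambiguity codes, including
N, never match — a conservative, testable rule. A query maps to its
maximum-identity reference when identity $\ge 0.97$ (the standard
species-level 16S cutoff); ties break to the lexicographically smaller
reference id so results are deterministic.

*Degenerate-input note.* With free terminal gaps, the score-optimal
alignment of two **unrelated** sequences is a short perfectly matching
overlap — a few columns at 100% identity. `map_sequences()` therefore
requires the alignment to cover at least half of the shorter sequence
(`min_coverage = 0.5`) before the identity threshold is applied. Without
this, every random reference would "match" at identity 1.0 on a 2-column
alignment.

Per-sample communities pool the counts of zOTUs sharing a model, drop
members below 2% relative abundance, and renormalize. Reads mapping to no
model are excluded *before* the cutoff by default (`unmapped =
"exclude_first"`; the other order is available because the protocol is
silent on it), and the mapped-read fraction is reported so the discarded
information is visible.

# Diet construction

Nutrient intakes in g/day convert to concentrations as
$\mathrm{mM} = \mathrm{g} / \mathrm{MW} / V \times 1000$. The conversion
conflates an intake with a concentration unless a reference volume is
explicit; the package exposes it (`volume`, default 1 L) and reproduces the
plain arithmetic exactly at the default. Nutrients sharing an exchange
metabolite are summed; unmapped nutrients are skipped with a message (or
raise under `strict = TRUE`).

Each personal diet is blended with a reference diet as a per-metabolite
convex combination over the union of metabolites (absent entries are 0),
default 99% personal / 1% reference. The 1% Western-style admixture exists
to satisfy model-specific trace growth requirements. The shipped reference
(`inst/extdata/western_diet_synthetic.csv`) is a *synthetic* editable table
with the composition shape of a Western diet, not a copy of any curated
resource. Diet concentrations seed the arena's environment uniformly
(BacArena-style semantics); capping per-agent uptake bounds directly at
−mM is the other textual reading of "constraining the lower bounds of the
inflow reactions" and is intentionally *not* the default, because the
spatial simulator already enforces local availability each step.

# The arena simulator

The arena is a rows × cols grid (default 60 × 60 = 3600 cells, the
protocol's stated environment size) holding at most one agent per cell —
this makes grid occupancy equal to population / 3600. Each agent carries a
model reference and a biomass (gDW); each cell holds per-metabolite
amounts (mmol), initialized as diet mM × cell volume with cell volume =
arena volume / cells (default arena volume 0.01 L; end-point mM is
volume-invariant because concentrations are reported per total volume).

One step of length Δt (default 1 h, so 12 h = 12 steps):

1. agent order is shuffled (seeded);
2. each agent caps every exchange uptake bound at
   −min(model bound, local amount / (biomass · Δt));
3. solves FBA; infeasible ⇒ μ = 0, the agent persists (no death rule — the
   protocol reports all founders surviving);
4. biomass ← biomass · (1 + μ·Δt) (explicit Euler);
5. the cell receives flux · biomass · Δt for every exchange (uptake
   negative, secretion positive);
6. an agent at ≥ 2·b₀ divides into a uniformly random free 8-neighbor cell
   (skipped when none is free), halving biomass;
7. each agent moves to a random free 8-neighbor cell with probability
   `p_move` (default 1);
8. every metabolite field takes one explicit Laplacian sweep with zero-flux
   boundaries; the stability constraint D·Δt/h² ≤ 0.25 is validated
   (default 0.1).

Founders: `round(abundance · n_init)` per species, minimum one founder per
community member, placed at distinct uniform cells; default `n_init = 400`
with a warning outside the protocol's 300–500 range. Initial biomass b₀ is
10⁻⁶ gDW per agent.

Mass bookkeeping is exact by construction: the uptake cap guarantees
non-negative amounts (solver-tolerance overshoots of order 10⁻¹⁵ are
clamped and accounted), per-step environmental change equals
Σ flux·biomass·Δt, and the neighbor-difference form of the diffusion sweep
conserves totals to rounding. These are asserted as invariants in the test
suite rather than stated here as results.

Stochasticity is deliberate and seeded: agents earlier in the shuffled
order see more substrate; replicates are independent seeded runs from the
same initial arena. Fixed seed, solver and thread count (the simulator is
single-threaded and uses R's RNG) give bit-identical trajectories.

Per-agent FBA results are cached per species keyed on the effective
exchange bounds, which makes substrate-replete phases (where every agent of
a species solves the same LP) essentially free.

# Ecology and endpoint statistics

* **Rarefaction** subsamples each sample without replacement to a common
  depth (vegan's `rrarefy` behind the module surface); samples below depth
  are dropped with a warning. The pipeline's default depth is the 0.1
  quantile of library sizes, mirroring the protocol's "90% of samples have
  more reads" rule. Default order is rarefy → 20% prevalence filter; the
  protocol's wording is ambiguous, so the order is a documented choice.
* **Alpha diversity**: observed richness, Shannon (natural log), inverse
  Simpson.
* **Bray–Curtis** $d = \sum|x-y| / \sum(x+y)$; **UniFrac** from a single
  post-order edge sweep: unweighted = unique / covered branch length;
  weighted = $\sum_i b_i |A_i - B_i|$, normalized by
  $\sum_i b_i (A_i + B_i)$ (the normalized variant is the default).
* **ANOSIM** uses Clarke's statistic
  $R = (\bar r_B - \bar r_W)/(n(n-1)/4)$ on mid-ranked distances — the
  protocol names the method, not the formula, so the 1993 convention is
  adopted. **PERMANOVA** partitions squared distances
  ($SS_W = \sum_g \frac{1}{n_g}\sum_{i<j\in g} d_{ij}^2$, pseudo-F, $R^2$).
  Both use label permutations with the +1/+1 rule
  ($p = (1 + \#\{stat^* \ge stat\})/(perm+1)$), so p is never 0 and never
  below $1/(perm+1)$; the protocol default is 9999 permutations.
* **Endpoints**: per-sample replicate means (median via flag), restricted
  to metabolites present in every sample's output, tested per metabolite
  with the Wilcoxon rank-sum test (exact when both n ≤ 8 without ties,
  else normal approximation with tie and continuity correction) and a
  Gaussian-identity GLM (the protocol says "generalized linear models"
  without a family; with no covariates this is the pooled t-test, and
  covariate hooks exist but default to none). Benjamini–Hochberg is applied
  per test family across metabolites. All tests are two-sided.
* A reported "significance p < 0.5" in the source material is treated as a
  typo for 0.05; 0.05 is the default and configurable.

# The synthetic cohort

The generator produces every input with known ground truth:

* **Toy models** with an uptake → transport → biomass backbone: uptake
  bound 10 mmol/gDW/h, yield 0.1 gDW/mmol, hence analytic μ = 1/h;
  optional byproduct secretion (5 mmol per unit biomass flux, i.e. half
  the substrate carbon). Motifs: `independent` (private nutrients),
  `chain`/`cross_feeding` (species i consumes species i−1's byproduct —
  obligate syntrophy with known structure).
* **Counts**: negative-binomial (dispersion 0.5, variance μ + 0.5μ²) around
  log-normal taxon weights and log-normal library sizes (sdlog 0.25 around
  a 20,000-read mean); planted taxa have expected counts differing by
  exactly 2^lfc between groups. A balanced-weights option exists for
  experiments that need a symmetric background.
* **Sequences**: one random 420-bp reference per model (V4–V5 amplicon
  scale; cosmetic); each query substitutes exactly `round(divergence · L)`
  random sites of its source reference, so realized divergence is exact and
  a 2%-divergent query always has identity 0.98 > 0.97 while a
  10%-divergent one always has 0.90 < 0.97.
* **Diets**: log-normal gram intakes with multiplicative group shifts and
  an optional Gaussian-copula clinical variable at a target Spearman rho.
* **Trees**: random rooted bifurcating topologies with exponential branch
  lengths.

The scaled default cohort is 2 × 10 samples, 60 taxa, 6 models — the full
pipeline then runs in seconds. What the generator does *not* emulate:
sequencing error profiles and chimeras, real phylogenetic signal in
abundances, curated model scale (hundreds of reactions), compositional
hosts effects, or covariate structure (medication, age). Passing tests
therefore demonstrate correctness of the machinery and recoverability of
planted effects under controlled conditions — not biological conclusions
about real cohorts.

# Validation experiment sizes

The heavier property checks fix these problem sizes:

* solver vs. brute-force vertex enumeration: 50 random networks with ≤ 6
  reactions (vertex enumeration is exponential, so networks stay tiny);
* mass/yield conservation: 400 agents, 60 × 60 grid, 12 steps;
* permutation calibration: 1000 null tables (2 × 6 samples, 20 taxa) at 999
  permutations, rejection rate compared against the binomial band
  [0.03, 0.07] at α = 0.05; exhaustive label enumeration at n = 6;
* UniFrac vs. a naive per-branch oracle: 100 random 8-leaf trees;
* end-to-end recovery: 100 pipeline runs with a planted producer
  (`planted_lfc = 2` on one species' zOTUs) and 100 null runs, on a 20 × 20
  arena with 100 founders and 300 g/day nutrient pools.

Two choices in the last experiment deserve their rationale. First, the
arena is scaled down with the cohort so that hundreds of full pipeline runs
stay cheap; the full 3600-cell arena remains the package default. Second,
nutrient pools are macronutrient-scale (300 g/day) so that 12 h of growth
stays substrate-replete: in that regime each species' cumulative byproduct
is proportional to its founder biomass, i.e. to its relative abundance, and
a planted abundance shift is expressed in the end-point concentrations.
With small pools the community exhausts the substrate and every run
converges to the same stoichiometric ceiling, erasing the compositional
signal — a useful reminder that *simulated end-points only reflect
community structure while resources are not limiting*.

# Known limitations

* One agent per cell couples carrying capacity to the grid size; occupancy
  saturates quickly for fast-growing toys, after which biomass still grows
  within agents (no per-agent biomass ceiling is imposed).
* The Euler biomass update overestimates growth for μ·Δt near 1; with the
  default Δt = 1 h and toy μ ≤ 1/h this is a bounded, documented bias, and
  Δt is configurable.
* Diffusion is a single explicit sweep per step, not a PDE solution; no
  pH, oxygen, chemotaxis, host exchange, or dilution/outflow term (the
  environment only accumulates what agents exchange).
* BLAST-style local identity differs from the ends-free global identity
  used here; the scoring scheme is configurable but the definitional choice
  matters near the 97% boundary.
* PERMANOVA is implemented for a single grouping factor (the design the
  pipeline needs), not general formulas; use vegan::adonis2 for anything
  richer.
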