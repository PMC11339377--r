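---
title: "Methods: counterfactual reserve design on synthetic forest landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: counterfactual reserve design on synthetic forest landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The question

Protected-area estates worldwide are biased toward land that is high,
remote and economically marginal — "high and far" — which is also the land
least likely to be converted whether or not it is protected.  `cfreserve`
quantifies what that bias costs, for a forest-interior top carnivore and
for forest carbon, by running seven counterfactual designs of a reserve
network through one consistent model chain:

1. **Prioritisation.** A simulated-annealing site-selection model in the
   MARXAN idiom ranks 10 × 10 km-style planning units by selection
   frequency.  *Proactive* designs treat the probability of imminent
   forest loss as a conservation feature to be captured (and cost units by
   area); *expedient* designs cost units by that same risk, steering
   selection into safe, cheap, remote terrain.
2. **Loss projection.** Outside effectively protected cells, the loss
   probability `p` converts expectations: landscape resistance becomes
   `r' = r + p · r_plantation` (the expected increase from conversion to
   plantation/regrowth) and above-ground biomass carbon becomes
   `c' = c · (1 − p)` (the expected retained stock).  Protected cells keep
   baseline values.
3. **Connectivity.** A resistant-kernel surface sums, over a fixed lattice
   of source points, a linear kernel `max(0, 1 − cost/bandwidth)` of the
   least accumulated cost through the resistance surface.  Core habitat is
   the area above a fixed density threshold, summarised with
   FRAGSTATS-style patch metrics (percentage of landscape, patch count,
   largest patch index, area-weighted mean patch size, correlation
   length).
4. **Genetics.** A spatially explicit individual-based simulation on fixed
   habitat points — cost-distance-limited mating and dispersal, Mendelian
   inheritance, non-overlapping generations, no mutation — tracks
   population size, observed heterozygosity and total allelic richness
   over hundreds of generations.

The seven scenarios are: S1 the baseline landscape with no loss applied;
S2/S3 proactive designs (redistributing vs retaining the existing
estate); S4/S5 the matching expedient designs; S6 the existing estate
alone, assumed fully effective; S7 business-as-usual, where modelled loss
applies everywhere including inside existing protected areas.

# The synthetic landscape generator

The real analysis rests on proprietary-scale geodata (a machine-learnt
loss-risk raster, pantropical biomass, a protected-area database, a
land-cover map).  The generator replaces these with seeded synthetic
layers that reproduce the *statistical* premises the comparison needs,
each of which is asserted by tests:

* elevation is spectrally filtered (`1/f²`) Gaussian noise — one
  `roughness` amplitude parameter in metres, autocorrelated at all scales;
* land cover allocates the target forest share by thresholding a latent
  score that mixes elevation and autocorrelated noise (remaining forest
  sits upslope, as clearance proceeds from accessible lowlands), then
  stratifies five forest classes by elevation quantile over two to three
  non-forest classes;
* protected areas grow as a handful of contiguous blobs seeded on
  high-elevation forest — the "high and far" bias: mean elevation inside
  the estate exceeds outside in ≥95% of seeds;
* loss risk is a logistic in standardised elevation, distance to the
  deforestation frontier and protection status, with negative slopes:
  risk is highest in low, frontier, unprotected forest and zero off
  forest;
* carbon is class-mean AGB with lognormal cell noise (lowland forest
  richest), zero off forest; resistance is a pure per-class lookup with
  forest cheapest.

What the generator does **not** emulate: coastline and real geography,
spatial error structure of remote-sensing products, temporal dynamics of
the loss process (a single transition is modelled), or leakage of
displaced deforestation (assumed absent, as in the source analysis).
Passing tests therefore demonstrate internal correctness and the
qualitative orderings under these premises, not predictions for any real
landscape.

Default calibration, chosen once from the real system's proportions: 55%
forest cover; a protected estate of 8% of cells, which locks 12–15% of
planning units (the production analysis locked 944 of 7675 ≈ 12%); a risk
surface with mean ≈ 0.25 on forest, yielding a business-as-usual expected
carbon loss of ≈ 20–25% (the production projection loses ≈ 19%).

# Scale choices

Everything runs at two scales.  The *production* scale of the original
tool chain (1 M annealing iterations × 10 k runs, 125 000 / 250 000
cost-unit bandwidths on a ~1000 km island, 200 generations × many
replicates) is configurable but not the default.  The *desk* scale used
by the package defaults, tests and the acceptance script is:

* 64 × 64 cells of 500 m (a 32 × 32 km landscape), 4 × 4-cell planning
  units (16 km²);
* eligibility thresholds expressed as the same *fraction* of unit area as
  the production rule (16 km² of 100 km², i.e. 16%), because a fixed
  16 km² floor is meaningless when the whole unit is 16 km²;
* a kernel bandwidth of 12 500 cost units for the pipeline default:
  dispersal spans about an eighth of the map edge at least cost, the same
  ratio the canonical 125 kcu bandwidth has to its study area.  The
  canonical bandwidths remain the `kernel_params()` default for users
  working at full extent;
* annealing 2000 iterations × 20 runs per scenario; genetic simulation
  15 loci, 50 generations, 5 replicates.  The drift-calibration test runs
  the full 30 loci × 200 generations × 30 replicates at N = 50.

# Numerical and design decisions

**Shortfall penalty.**  The original tool's penalty bookkeeping is not
published to reproducible precision.  The objective here is
`Σ cost + BLM · boundary + Σ_f SPF_f · (shortfall_f / target_f) · G_f`,
where `G_f` is the cost of a greedy (best amount-per-cost) completion
meeting feature *f* alone, computed once per problem.  This surrogate has
identical zeros (penalty vanishes iff all targets are met), scales like
the cost of repairing the shortfall, and is exactly testable.

**Boundary term.**  Edges to the landscape exterior count as exposed
perimeter (the default edge treatment of the original tool), which
penalises stringy edge-hugging designs.  Two selected neighbours
contribute nothing; a selected/unselected edge contributes its length.

**Annealing.**  Proposals toggle one uniformly random non-locked unit;
the initial temperature defaults to the mean |Δobjective| of 100
presampled moves, with geometric cooling spanning four decades over the
run; the best-seen state is returned, and incremental bookkeeping is
verified against full recomputation to 1e-9 relative tolerance.  On 8–12
unit problems, best-of-20 runs matches exhaustive search in ≥95 of 100
seeded trials.

**Selection frequency and design assembly.**  Locked units enter first;
free units fill by descending frequency, ties broken by ascending id;
the design size is `round(area_fraction × n_units)` (the production
figures 0.17 × 7675 → 1305 follow; published unit counts vary between
7675 and 7657 in different places, so the size is always derived from
the data, never hard-coded).

**Core threshold.**  The kernel density threshold is the 10th percentile
of *positive* baseline densities (over a raster dominated by zeros a low
percentile would be trivially 0), and the *same absolute* threshold cuts
every scenario's map — otherwise each map would trivially keep ~90% of
its own support and scenarios would be incomparable.  The cut is strict
(`>`), so a constant surface yields no core (degenerate, documented).

**Cost distance.**  Step cost between adjacent cells is
`distance_factor × (r_a + r_b)/2 × cell_size` with √2 on diagonals, on an
8-neighbour lattice (harmonising patch connectivity and movement at 8).
Dijkstra runs on an igraph lattice graph and is verified against a
Bellman–Ford relaxation oracle on all small grids.

**Carbon update.**  The loss sentence can be (mis)read two ways; the
default is the expected-loss form `c' = c · (1 − p)` — retained stock
falls with risk — because the literal alternative (`c' = c · p`) rewards
high-risk cells and contradicts every reported ordering.  The literal
form is available as `loss_model = "literal"` so the choice is explicit
and auditable, never silent.

**Mating system.**  Each breeding female's litter is Poisson(4); each
offspring draws its sire independently among males reachable within the
dispersal threshold, weighted by the same linear kernel (multiple
paternity).  This choice is pinned by the module's quantitative anchor:
in the panmictic limit the population must reproduce Wright–Fisher decay
`H_t = H_0 (1 − 1/(2N))^t`, and the measured calibration at N = 50 over
200 generations sits well within Monte-Carlo error (single-sire-per-female
mating inflates the variance in male reproductive success and decays
markedly faster than 1/(2N)).  Offspring settle, in random order, at the
nearest unoccupied point by cost distance within the threshold; the rest
die; generations do not overlap.

**Subdivision and allelic richness.**  At *equal total size*, two fully
isolated halves lose heterozygosity roughly twice as fast as one
connected population, but their *union* of distinct alleles is retained
at least as well (different demes fix different alleles) — verified
against an independent Wright–Fisher oracle.  Tests therefore assert the
directional Ho effect only; the allelic-richness declines reported by the
full pipeline arise from reduced population size after habitat loss, not
from subdivision per se.

**Degenerate inputs.**  Misaligned layers, unknown land-cover codes,
all-zero normalisation, empty source sets, single-class validation data
and reserve sizes below the locked set are rejected with errors;
extinction is an absorbing, non-erroring simulation state; an all-forest
landscape gets a finite frontier distance (the grid diagonal).

# Reproducibility

Every stochastic stage takes an explicit integer seed; the pipeline fans
a master seed out to fixed per-stage offsets (landscape: the landscape
config's seed; annealer for scenario *s*: `seed + 100 + s`; genetics:
`seed + 200 + s`), so stages can be rerun independently and the whole
report is bit-reproducible.  All artifacts are plain text: ESRI ASCII
grids for rasters, CSV for tables, the MARXAN dat dialect for problem
interchange, YAML for configuration.

# Known limitations

* The desk-scale landscape is ~1/1000 the area of the real system;
  absolute metric values (e.g. percentage of landscape connected) are not
  comparable to published ones — only within-run scenario contrasts are.
* Selection-frequency ranking at 20 runs is noisier than at 10 000; the
  acceptance checks use orderings and sign tests across landscape seeds
  rather than single-run values.
* With few genetic replicates the per-scenario medians of a 50-generation
  simulation are noisy, and heavily degraded scenarios can go extinct at
  desk scale; the drift anchor, not the scenario medians, is the
  module's quantitative guarantee.
* The loss process is a single expected transition; no multi-step
  dynamics, no leakage, no climate interaction.
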