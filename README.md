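# cfreserve

Counterfactual protected-area network design with connectivity and
genetic simulation.

## The problem

Protected areas are disproportionately sited on land that is high,
remote and economically marginal — land that would likely survive
unprotected anyway.  `cfreserve` is for conservation modellers who want
to quantify what that bias costs.  It compares, on seeded synthetic
forest landscapes, seven counterfactual designs of a reserve network for
a dispersal-limited forest carnivore and for forest carbon:

| id | design |
|----|--------|
| S1 | baseline landscape, no forest loss applied |
| S2 | proactive new reserves (high loss risk prioritised), estate redistributed from scratch |
| S3 | proactive new reserves, existing estate retained |
| S4 | expedient new reserves (low loss risk prioritised), estate redistributed |
| S5 | expedient new reserves, existing estate retained |
| S6 | existing estate only, assumed 100% effective |
| S7 | business-as-usual: modelled loss applies everywhere, estate included |

## The model chain

Reserve selection is simulated annealing over planning units in the
MARXAN idiom, minimising

```
Σ_selected cost_u  +  BLM · boundary(selected)  +  Σ_f SPF_f · (shortfall_f / target_f) · G_f
```

with per-feature targets of 30% of each feature total (resistant-kernel
connectivity, above-ground biomass, and — in proactive mode — loss
risk), SPF = 2, BLM = 0.0015, and `G_f` the greedy completion cost of
feature *f*.  Units are ranked by selection frequency across runs and
the top `round(0.17 · n_units)` form the design.

Forest loss with probability `p` then updates unprotected cells:
resistance `r' = r + p·r_plantation`, carbon `c' = c·(1−p)`.  Connectivity
is a resistant-kernel density `K(x) = Σ_s max(0, 1 − cost_s(x)/bandwidth)`
over least-cost distances, thresholded into core habitat and summarised
with FRAGSTATS-style metrics (PLAND, NP, LPI, area-weighted mean patch
size, correlation length / GYRATE_AM).  A CDPOP-style individual-based
simulation (cost-distance-limited mating and dispersal, Mendelian
inheritance, no mutation, non-overlapping generations) tracks N,
observed heterozygosity and allelic richness.  In the panmictic limit the
simulation reproduces Wright–Fisher decay `H_t = H_0 (1 − 1/(2N))^t`.

See `vignettes/counterfactual-reserve-design.Rmd` for assumptions,
parameter defaults and numerical decisions.

## Worked example

```r
library(cfreserve)

cfg <- pipeline_config(landscape = synthetic_config(seed = 1), seed = 1)
report <- run_pipeline(cfg)
print(report)
```

```
 scenario                              label bandwidth pland np   lpi awmps_km2
        1                           Baseline     12500 78.03  2 75.22     743.6
        2 Proactive conservation redistribut     12500 55.08  7 47.36     421.0
        3 Proactive conservation maintaining     12500 50.90  7 42.87     375.7
        4 Expedient conservation redistribut     12500 49.78  7 43.26     389.0
        5 Expedient conservation maintaining     12500 50.27  7 42.70     377.4
        6             Existing PAs effective     12500 47.80  7 40.97     364.2
        7                  Business-as-usual     12500 46.68  7 40.23     359.2
 correlation_length_km carbon_gt Ho_median alleles_median N_median
                10.979  0.011195  0.376667             42       42
                 8.718  0.009128  0.189744             27       24
                 8.700  0.008896  0.000000              0        0
                 8.890  0.008767  0.163333             26       20
                 8.810  0.008823  0.008333             16        8
                 8.822  0.008539  0.000000             15        9
                 8.846  0.008498  0.000000              0        0
```

Reading the table: the baseline keeps 78% of the landscape connected and
0.0112 Gt of carbon; every loss scenario falls below it.  The proactive
redistribute design (S2) retains the most connectivity (55.1%), carbon
and genetic diversity of any alternative; the expedient designs (S4, S5)
cluster near business-as-usual — protecting land that was never at risk
buys little.  Population medians come from 5 short genetic replicates and
are noisy; heavily degraded scenarios can go extinct at this desk scale.

```r
relative_change(report, "pland", 2)          # S2 vs business-as-usual: +18%
relative_change(report, "carbon_gt", 2, digits = 1)   # +7.4% carbon
```

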