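# matchdem

Phenological mismatch and demography of cavity-nesting solitary bees.

Solitary bees provision each brood cell with pollen collected during a
short nesting window. If the nesting period drifts away from the
flowering period of the bee's main floral resources — the match/mismatch
hypothesis — per-nest recruitment (brood cells per nest) and ultimately
the population growth rate should fall, and more steeply for diet
specialists than for generalists. `matchdem` implements the complete
analysis pipeline for testing these predictions from three field tables
(weekly floral surveys, trap-nest records, pollen samples) or from a
built-in synthetic-data generator that emulates a nine-season, two-site
trap-nest study of five bee species spanning a specialization gradient.

## The estimators

* **Weighted mean date (WMD).** The phenological centre of nesting or
  flowering in a season is the abundance-weighted mean day,
  `WMD = Σ dᵢ·(aᵢ/Σa)`, with days counted from 1 July (austral season
  anchor; configurable).
* **Mismatch.** Nest-level: `|end day of nest construction − flowering
  WMD|` of the bee's main floral resources, the minimal set of plant
  taxa jointly holding ≥ 85% of the pollen found across the species'
  examined nests. Population-level: `|nesting WMD − flowering WMD|`.
* **Generalization.** Shannon diversity `H = −Σ pᵢ ln pᵢ` of the summed
  per-nest pollen proportions of each plant taxon.
* **Recruitment models.** Linear mixed models (random intercept per
  season year, ML estimation) with mismatch as predictor and either
  brood cells (`linear`) or `ln` brood cells (`exponential`) as
  response, compared by AIC; standardized slopes for cross-species
  comparison; Spearman rank correlation at the population level.
* **Demography.** `λ_t = N_{t+1}/N_t` over the yearly totals of brood
  cells, summarized by `λ̄ = mean(ln λ_t)` (`λ̄ > 0`: growth), with a
  95% percentile bootstrap CI from 1000 season-stratified nest
  resamples. Species whose cells cannot be counted directly get counts
  imputed from the occupied cavity length via a per-species OLS
  calibration.

## Worked example

```r
library(matchdem)

weighted_mean_date(c(60, 67, 74), c(10, 60, 30))
#> [1] 68.4

sim  <- simulate_scenario(default_scenario(), seed = 42)
phen <- analyze_phenology(sim$flowers, sim$nests, sim$pollen)
print(phen$resources[["bee_sp1"]])
#> Main floral resources of bee_sp1 (>= 85% of pollen):
#> cactus_a
#>    0.946
#> cumulative share: 0.946

generalization_scores(sim$pollen, sim$nests)
#>   bee_taxon shannon_h n_nests
#> 1   bee_sp1 0.3114556      20
#> 2   bee_sp2 0.6375539      51
#> 3   bee_sp3 1.0660738      18
#> 4   bee_sp4 1.6741419       8
#> 5   bee_sp5 2.0180432      14

nf <- impute_brood_cells(sim$nests, fit_imputation_models(sim$nests))
d  <- merge(phen$per_nest[, c("nest_id", "bee_taxon", "season_year",
                              "mismatch_days")],
            nf[, c("nest_id", "brood_cells")], by = "nest_id")
fit_species_models(d)[, c("bee_taxon", "form", "slope", "std_slope")]
#>   bee_taxon        form        slope  std_slope
#> 1   bee_sp1 exponential -0.065306679 -0.8438787
#> 2   bee_sp2 exponential -0.048898696 -0.8219383
#> 3   bee_sp3 exponential -0.030131490 -0.6959090
#> 4   bee_sp4 exponential -0.023703636 -0.4723570
#> 5   bee_sp5 exponential  0.009523753  0.2670295

species_demography(nf[nf$bee_taxon == "bee_sp1", ], n_boot = 1000, seed = 42)
#> bee_sp1: lambda_bar = 0.0836 [0.0247, 0.1580]
#>   (95% percentile bootstrap, 1000 resamples, 8 transitions)
```

Reading: the WMD of 10/60/30 flowers on days 60/67/74 is day 68.4.
Species `bee_sp1`–`bee_sp5` are generated along a specialization
gradient (Shannon H from 0.31 to 2.02); the exponential model wins the
AIC comparison for every species, and its standardized slope weakens
monotonically from the strict specialist (−0.84) to the broad generalist
(+0.27, indistinguishable from zero at its SE) — the diagnostic pattern
the pipeline is built to detect. The demography summary shows the
specialist's mean log growth rate with its bootstrap interval.

The same stages run end to end, with CSV stage outputs and a JSON run
manifest, via `run_pipeline(out_dir = "run1", seed = 42)`, or from the
shell through the thin wrapper:

```sh
Rscript inst/scripts/matchdem.R run --config inst/extdata/default_scenario.yaml \
    --seed 42 --out run1
```

Field data are ingested by pointing `run_pipeline(inputs = list(...))`
at CSV tables in the canonical schema (a column-name `dialect` and an
ISO-date column are accepted; see `?read_floral_surveys`).

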