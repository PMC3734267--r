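# sivva

Comparative species vulnerability assessment in R: expert-elicited index
scoring with Monte-Carlo uncertainty, bathtub sea-level-rise exposure on
gridded elevation, and mixed-model comparison of ecological traits between
paired listed (threatened/endangered) and non-listed taxa.

## The problem

Conservation triage needs a defensible answer to "which taxa are most
vulnerable, and why?". One established approach couples a standardized
expert-scored index — SIVVA, with four modules: vulnerability, adaptive
capacity, conservation value, information availability — with literature
trait surveys and GIS exposure metrics, comparing each federally listed
subspecies against a closely related non-listed subspecies of the same
parent species so that phylogeny is controlled. This package implements
that full analysis chain as tested, reusable functions, plus synthetic-data
generators so every stage can be exercised and calibrated without any
external data.

The core quantities:

- **Module summary score** for criterion scores `s_i ∈ {0} ∪ [1,6]` and
  weights `w_i ≥ 0`:

  `S = Σ w_i s_i / Σ 6 w_i`, sums over scored criteria (`s_i ≥ 1`);
  a score of 0 means "insufficient information" and drops out of both
  numerator and denominator.

- **Uncertainty interval**: each assessor-flagged criterion is perturbed by
  δ ~ Uniform{−1, 0, +1} (clipped to [1,6]) in each of `n_sims` Monte-Carlo
  draws; the 95% percentile interval of the recomputed scores is reported,
  and two taxa differ on a module when their intervals are disjoint.

- **Bathtub inundation**: a cell floods iff elevation ≤ rise; exposure is
  the percent of a taxon's range cells flooded, and distance to coast is
  the Euclidean distance from the range centroid to the nearest coast cell
  (analysed on the natural-log scale).

- **Trait contrasts**: independent literature observations are scaled to
  proportions of the pair × trait maximum, transformed with the adjusted
  logit `ln((p+ε)/(1−p+ε))` (ε = minimum non-zero proportion), and compared
  between statuses with a linear mixed model (trait nested within status;
  pair and taxon × trait random intercepts) under Tukey-style familywise
  adjustment. Within single pairs, tiny samples get an exactly enumerated
  Wilcoxon rank-sum test.

## Worked example

```r
library(sivva)

# weighted module score: scores (6,2,4), weights (2,1,1)
module_score(c(6, 2, 4), weight = c(2, 1, 1))
#> [1] 0.75

# exact rank-sum test, 3 vs 3 with complete separation
exact_rank_sum(c(7.1, 8.4, 9.0), c(1.2, 2.5, 3.3), sided = "one")
#>   statistic n1 n2 p_value sided                               method
#> 1         9  3  3    0.05   one Wilcoxon rank sum, exact enumeration

# full synthetic study: 12 taxon-pairs, 2 assessors, coastal landscape
cfg <- sim_config(seed = 1)
report <- run_pipeline(sim_scoresheets(cfg), sim_traits(cfg),
                       sim_landscape(cfg), pipeline_config(seed = 1))
report
#> <sivva_report>
#>   taxa: 24; modules scored with 1000 MC draws (alpha = 0.05)
#>   pairwise module differences flagged: 45 of 48
#>   a priori status tests rejected (BH q = 0.05): slr, fragmentation, temperature, precipitation
#>   trait contrasts significant at 0.05: dispersal, home_range

report$trait_contrasts
#>           trait   estimate        se  statistic   p_adjusted
#> 1     dispersal -1.3612902 0.1599902 -8.5085856 0.000000e+00
#> 2    home_range  1.1979365 0.1623937  7.3767424 6.489254e-13
#> 3 litter_clutch  0.1464222 0.1638125  0.8938401 8.438733e-01
#> 4      survival  0.1876147 0.1572380  1.1931893 6.535462e-01
```

Reading the output: the generator plants a higher criterion-score baseline
for listed taxa, a 2× home-range ratio and a 0.5× dispersal ratio, and
places listed ranges nearer the coast. The report recovers exactly that —
nearly every pair differs on every module, all four a priori status tests
reject after FDR correction, and only the home-range (positive, listed
larger) and dispersal (negative, listed shorter) contrasts are significant
on the adjusted-logit scale. `report$table2` gives the per-taxon
categorical summary (sea-level-rise, fragmentation, temperature,
precipitation bands), `report$exposure` the per-taxon inundation and
coast-distance metrics, and `write_report(report, dir)` writes every table
as CSV.

A thin command-line wrapper over the same functions lives at
`inst/cli/sivva.R` (`simulate`, `score`, `inundate`, `report`
subcommands).

## Package layout

- `R/scoresheet.R`, `R/module_score.R` — scoresheet validation/IO, module
  scoring, Monte-Carlo intervals, weight permutation, assessor combination
- `R/grid.R`, `R/inundation.R` — ESRI ASCII grids, bathtub masks, exposure
  and coast-distance metrics, categorical scales
- `R/traits.R`, `R/stats.R` — trait normalisation, exact rank-sum
  enumeration, correlations, BH-FDR, mixed-model LRTs and contrasts
- `R/simulate.R` — scoresheet, trait, and landscape generators
- `R/pipeline.R`, `R/plots.R` — end-to-end orchestration, report tables,
  ggplot builders
- `vignettes/vulnerability-assessment.Rmd` — the methods vignette: model
  assumptions, parameter meanings, calibration evidence, limitations
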