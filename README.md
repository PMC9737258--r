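# hmazone

Concentric-zone analysis of self-assembled multicellular aggregates.

When a heterogeneous mix of tumour cells is cultured in a non-adhesive
microwell, the cells self-assemble into a single aggregate and sort by
intercellular affinity: strongly cohesive populations end up in the core,
weakly cohesive ones at the periphery. In glioblastoma, a population's
radial position is an empirical correlate of temozolomide (TMZ) response
and of patient outcome — which makes the self-assembly pattern a fast,
marker-free probe of tumour heterogeneity. `hmazone` is for labs using
microwell aggregation assays who want that probe quantified reproducibly
from fluorescence stacks, and for anyone who wants the full analysis chain
testable without a microscope.

The package implements the whole pipeline:

* **Zonation** — partition a 500-µm well into five concentric zones of
  equal radial width and compute, per channel, the thresholded pixel area
  and occupancy fraction f₁…f₅ per zone (Otsu or fixed threshold,
  per z slice, summed over z).
* **Radial scoring and ranking** — summarise a profile as the
  area-weighted mean zone index *s* = Σₖ k·fₖ ∈ [1, 5] (1 = fully
  internal, 5 = fully external), classify test populations against the
  U251 (internal, *s* = 1.44) and U87 (external, *s* = 2.44) references,
  rank populations 1…n and split at the median rank into internal and
  external subgroups.
* **Phenotype metrics and concordance** — TMZ resistance as normalised
  log-dose AUC of viability, proliferation as the log-linear growth rate,
  invasion as relative area change 0–72 h; each ranked with the same
  semantics and compared to the spatial ranking by Spearman rho and
  subgroup agreement.
* **Survival** — Kaplan–Meier product-limit curves with Greenwood errors
  and the two-group log-rank test, implemented from the formulas and
  cross-checked against the `survival` package in the tests.
* **Synthetic data** — seeded generators for microwell image stacks
  (per-zone occupancy or core–shell placement models), coupled phenotype
  tables, and two-group survival cohorts, so every stage is testable
  end-to-end.

## Worked example

Simulate one heterotypic well — the two reference lines plus one unknown
population with a strong shell bias — then quantify, score and classify:

```r
library(hmazone)

pops <- tibble::tibble(
  label     = c("U251", "U87", "GC01"),
  channel   = c("red", "green", "blue"),
  n_cells   = 2000,
  placement = list(zone_placement(c(0.57, 0.42, 0.01, 0, 0)),
                   zone_placement(c(0.05, 0.48, 0.45, 0.02, 0)),
                   core_shell_placement(0.4, shell_bias = 0.9))
)
geom    <- well_geometry(center_xy = c(y = 249.5, x = 249.5))
stack   <- simulate_aggregate_image(pops, geometry = geom, seed = 7)
profile <- quantify_zones(stack, geometry = geom)
profile$label <- pops$label[match(profile$channel, pops$channel)]

scores <- radial_score(profile[, c("label", "zone", "fraction")])
scores
#> # A tibble: 3 × 2
#>   label score
#>   <chr> <dbl>
#> 1 GC01   3.98
#> 2 U251   1.43
#> 3 U87    2.44

classify_configuration(scores, "U251", "U87")
#> # A tibble: 1 × 3
#>   label score call
#>   <chr> <dbl> <fct>
#> 1 GC01   3.98 external
```

The recovered reference scores (1.43, 2.44) match the scores of the
published occupancy profiles they were generated from (1.44, 2.44), and
the shell-biased test population is called external. An external-type call
is the unfavourable one; on a simulated cohort with hazard ratio 3:

```r
rec <- simulate_survival(hazard_ratio = 3, baseline_median = 24,
                         n_per_group = 30, seed = 7)
glance(km_estimate(rec))
#> # A tibble: 2 × 4
#>   group        n events median_survival
#>   <chr>    <int>  <int>           <dbl>
#> 1 external    30     24            7.05
#> 2 internal    30     26           31.7
logrank_test(rec)
#> <logrank_test> log-rank test: chi-square = 23.79 on 1 df, p = 1.077e-06
```

Median survival drops from 31.7 to 7.1 months for the external group and
the log-rank test rejects decisively. `autoplot(km_estimate(rec))` draws
the curves; `run_pipeline(out_dir, seed = 1)` executes the whole chain
(simulate → zonate → score → phenotype → correlate → survive) and writes
every table plus a JSON summary, byte-identically for a given seed.

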