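# comorbnet

Comorbidity network analysis of ICD-10-coded claims cohorts.

`comorbnet` is for epidemiologists who want to ask, of a longitudinal
claims database, *"which diseases precede this one?"* — and get back a
screened, matched, graph-shaped answer. It implements the full case-control
design used to map the comorbidity network of Legg–Calvé–Perthes disease
(LCPD, idiopathic avascular necrosis of the pediatric femoral head), but
every element — index codes, washout, age limit, matching ratio, clinical
grouping — is configuration, so the same pipeline applies to any index
disease.

The stages, each exposed as plain R functions:

1. **Cohort** — incident cases of the index disease (first index-coded
   visit after a code-free washout window, age at diagnosis ≤ limit),
   after excluding demographically incomplete patients.
2. **Incidence** — annual rates per 100,000 by sex with a washout year, and
   an exact conditional test of the male:female rate difference.
3. **Matching** — 1:3 propensity-score matching (logistic model of case
   status on age, sex and period before diagnosis), greedy nearest-neighbor
   without replacement, exact on sex; controls get pseudo-index dates so
   their comorbidity lookback windows equal their case's.
4. **Association** — per three-character ICD-10 category ("cluster"),
   presence-based 2×2 tables with the Haldane–Anscombe-corrected odds
   ratio

   $$\widehat{OR} = \frac{(a+\tfrac12)(d+\tfrac12)}{(b+\tfrac12)(c+\tfrac12)}$$

   (the ½ added to every cell, unconditionally) and two-sided exact Fisher
   p-values; screening at p < 0.05; clinical regrouping with statistics
   recomputed on union exposure; pairwise cluster-cluster links.
5. **Network** — index node plus significant clusters/groups, edges
   weighted by odds ratio, degree-sized nodes colored by ICD-10 chapter;
   exported as GraphML, GEXF and CSV.

A seeded synthetic claims generator (`sim_config()`/`generate_claims()`)
with configurable prevalences and *planted* case-control odds ratios stands
in for the (non-redistributable) national claims source, so every stage is
testable end to end. `run_pipeline()` chains everything from one config and
writes a reproducible manifest.

## Worked example

Generate a synthetic cohort at the packaged demonstration scale (20,000
patients, three planted comorbidities with odds ratios 2, 5 and 10, about
167 expected incident cases), run the pipeline, and look at the network:

```r
library(comorbnet)

claims <- tempfile(fileext = ".csv")
write_claims(generate_claims(demo_config(seed = 1)), claims)

res <- run_pipeline(pipeline_config(
  claims, out_dir = tempfile(), cohort = demo_cohort_spec(),
  seed = 1, verbose = FALSE
))

format_results(res$associations)[, c("cluster", "cases_fmt", "controls_fmt",
                                     "p_fmt", "or_fmt")]
#> # A tibble: 9 × 5
#>   cluster cases_fmt  controls_fmt p_fmt  or_fmt
#>   <chr>   <chr>      <chr>        <chr>  <chr>
#> 1 A09     41 (22.9)  104 (19.4)   0.334  1.24
#> 2 D64     12 (6.7)   22 (4.1)     0.159  1.71
#> 3 H66     28 (15.6)  76 (14.2)    0.625  1.13
#> 4 J06     59 (33.0)  183 (34.1)   0.855  0.95
#> 5 L20     15 (8.4)   48 (8.9)     0.880  0.95
#> 6 M67     32 (17.9)  23 (4.3)     <0.001 4.82
#> 7 Q65     45 (25.1)  13 (2.4)     <0.001 13.14
#> 8 S83     5 (2.8)    20 (3.7)     0.646  0.80
#> 9 Z00     166 (92.7) 508 (94.6)   0.361  0.72
```

This cohort has 179 incident cases and 537 matched controls. The two
strongly planted clusters are flagged with estimates near their targets
(M67: 4.82 for a planted 5; Q65: 13.14 for a planted 10 — single-cohort
estimates of large odds ratios are noisy), while the weak D64 effect
(planted 2, estimated 1.71) misses the 0.05 cutoff in this particular
cohort — an odds ratio of 2 on a 5%-prevalence code is underpowered at
~170 cases; across 200 replicates the mean estimates recover all three
targets within 10% (see the acceptance tests).
The null codes, including the ubiquitous general-examination code Z00,
stay out. The network links the index node to the significant clusters,
which here are also mutually associated:

```r
res$network$nodes
#> # A tibble: 3 × 3
#>   label chapter degree
#>   <chr> <chr>    <int>
#> 1 LCPD  index        2
#> 2 M67   M            2
#> 3 Q65   Q            2
res$matched$balance
#> # A tibble: 3 × 4
#>   covariate mean_cases mean_controls     smd
#>   <chr>          <dbl>         <dbl>   <dbl>
#> 1 age            5.94          5.98  -0.0100
#> 2 sex_male       0.754         0.754  0
#> 3 period         3.85          3.85   0
```

Sex proportions are identical by the exact-on-sex matching contract, and
the control lookback window equals the case's period before diagnosis by
construction (SMD exactly 0 for both).

The published study tables ship with the package for worked examples:

```r
tab <- lcpd_reported_associations()
row <- tab[tab$cluster == "Q65", ]           # 4/167 cases, 0/501 controls
haldane_anscombe_or(4, 163, 0, 501)
#> [1] 27.6055
fisher_exact_two_sided(4, 163, 0, 501)
#> [1] 0.003801493
```

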