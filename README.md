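# panssmapper

Topological stratification of early-psychosis patients from PANSS symptom
profiles, with replication, outcome prediction and metabolite analysis.

## What it does and for whom

Early-psychosis cohorts are heterogeneous; clinically meaningful subtypes
are hidden in the 30-item Positive and Negative Syndrome Scale (PANSS)
vectors (P1–P7, N1–N7, G1–G16, each scored 1–7). `panssmapper` is for
researchers who want to:

1. **Stratify** a cohort with the Mapper algorithm from topological data
   analysis: normalized Pearson correlation distance
   d(x, y) = √(2·(1 − r(x, y))), a two-dimensional principal-component
   lens, an overlapping hypercube cover (`resolution` intervals per
   dimension, adjacent-interval overlap 1 − 1/`gain`; defaults 60 and 7),
   single-linkage clustering of each cover element's preimage with a
   first-gap dendrogram cut, and the nerve graph — nodes are preimage
   clusters, edges join nodes sharing a patient.
2. **Extract groups** from the graph: small components excluded, the
   largest component split into k parts (modularity cut by default, exact
   edge-betweenness or manual cuts optional), groups named by symptom
   content (B = highest positive factor, then C, then A), patients
   assigned by node-majority vote with ties left unassigned, plus a
   boundary-sensitivity report.
3. **Characterize groups**: Wallwork five-factor scores (item sums),
   per-item group-vs-rest Kolmogorov–Smirnov tests with Bonferroni
   correction, chi-square / t / ANOVA outcome comparisons.
4. **Replicate and predict**: nearest-centroid assignment of a second
   cohort; L2-penalized logistic regression (inverse-penalty strength,
   default 1) predicting good vs. poor functional outcome (GAF > 65
   vs. ≤ 65) from items or group membership, with accuracy, precision,
   recall, precision–recall curves and average precision against the
   prevalence baseline; k-means comparators (k = 3, k-means++) and
   adjusted-Rand partition comparison.
5. **Analyse metabolites**: per-group Pearson correlation networks
   (edges at p < 0.05), cross-group edge classification, and linear-model
   group contrasts adjusted for age and sex.

Because the motivating clinical cohorts are not deposited, the package
includes a synthetic-cohort generator (`default_params()`,
`generate_cohort()`) that plants three symptom profiles, group-linked
outcomes (good-outcome ordering A > C > B) and group-linked metabolites
(glutathione peroxidase rising A < B < C: 23.3/25.5/28.1 µmol/min/gHb;
2-aminobutyrate falling 21.4/17.9/16.8 µM; group-specific correlation
blocks), so the whole pipeline is testable end to end.

## Worked example

```r
library(panssmapper)

sim    <- generate_cohort(default_params(n_patients = 100), seed = 1)
x      <- panss_matrix(sim$cohort)
graph  <- build_mapper_graph(x)           # resolution 60, gain 7
graph
#> Mapper graph: 2927 nodes, 92526 edges over 100 patients

groups <- stratify_groups(graph, x)
table(groups$group)
#>          A          B          C unassigned
#>         22         31         43          4

keep <- groups$group != "unassigned"
compare_partitions(groups$group[keep], sim$labels$group[keep])$ari
#> 0.965
```

The recovered group sizes (22/31/43 with 4 unassigned) track the planted
mixing proportions, and the adjusted Rand index of 0.965 says the
recovered partition nearly coincides with the planted one. Replication
and outcome prediction in an independent synthetic cohort:

```r
sim2 <- generate_cohort(default_params(n_patients = 100), seed = 2,
                        id_prefix = "v")
x2   <- panss_matrix(sim2$cohort)
rep2 <- assign_by_centroid(x2, group_centroids(x, groups))
compare_partitions(rep2$group, sim2$labels$group)$matched_fraction
#> 0.95

pr <- run_prediction_experiment(x,  sim$cohort$gaf,  groups,
                                x2, sim2$cohort$gaf, rep2,
                                predict_config(seed = 1))
pr$reports$group_onehot$train_test
#> Prediction report (n = 100): accuracy 0.710, precision 0.640,
#>   recall 0.444, PR-AUC 0.519 (baseline 0.360)
pr$reports$panss_items$train_test
#> Prediction report (n = 100): accuracy 0.560, precision 0.395,
#>   recall 0.417, PR-AUC 0.406 (baseline 0.360)
```

Nearest-centroid replication reassigns 95% of the second cohort to its
generative group, and group membership out-predicts the 30 raw items for
the group-driven outcome (PR-AUC 0.519 vs. 0.406 over a 0.360 prevalence
baseline) — the stratification carries the outcome signal in three
degrees of freedom.

`run_pipeline(default_config())` runs everything (including the
metabolite stage) and serializes each stage's output; a command-line
wrapper with subcommands `simulate`, `mapper`, `stratify`,
`characterize`, `replicate`, `predict`, `metabolome` and `run-all` lives
at `inst/cli/panssmapper.R`. The methods vignette
(`vignettes/methods.Rmd`) documents the model, conventions, parameter
choices and limitations.

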