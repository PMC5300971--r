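# nkstrat

Unsupervised stratification of patient cohorts by NK-cell maturation
profile, from five-marker flow cytometry (CD56, CD16, NKG2A, NKG2C, CD57).

The package is aimed at computational immunologists who want a scripted,
reproducible version of a workflow that is usually spread across FlowJo,
a model-based clustering tool and a heatmap viewer: gate NK cells, cluster
each sample's events with a finite mixture model, merge cluster centroids
across samples into named NK populations, build a patients × populations
frequency matrix, discover patient groups, and compare them with
nonparametric statistics. Because studies of this kind rarely deposit
event-level data, the package also ships a synthetic-cohort generator that
reproduces the statistical structure of a primary-HIV-infection cohort
(three patient groups with distinct maturation profiles and matching
clinical metadata), so the entire chain is testable end to end.

## The method

For each sample, gated NK events `x_1..x_n` (5-dimensional, transformed
scale) are modeled as a `K`-component mixture

    f(x) = sum_k w_k N(x; mu_k, Sigma_k),   sum_k w_k = 1,

fitted by EM with k-means++ restarts (a Student-t family with fixed
degrees of freedom is available). `K` is chosen once cohort-wide by
scanning `BIC = 2 log L - p log n` (larger is better) and
`ICL = BIC - 2 * assignment entropy`; the default `K = 27` follows the
motivating study. The pooled centroids are rescaled per marker so the
pooled 5th/95th percentiles map to -3/+3, clustered hierarchically
(Euclidean distance, average linkage), cut into 19 metaclusters, filtered
for rare representation, and annotated into 13 named NK populations by
interval rules on the rescaled signatures (e.g. CD56bright: CD56 >= 1.5,
CD16 < 0, NKG2A >= 0). Population frequencies (% of total gated NK events)
feed a second hierarchical clustering that stratifies patients into groups
X (CD56dim NKG2A+-dominated), Y (CD56dim CD57+-dominated) and Z (CD56dim
NKG2A-NKG2C-CD57--dominated). Groups are compared with the tie-corrected
Kruskal-Wallis test,

    H = [ 12 / (N(N+1)) * sum_g R_g^2 / n_g - 3(N+1) ] / (1 - sum(t^3 - t)/(N^3 - N)),

followed by Dunn's pairwise post-hoc z tests (Bonferroni-adjusted, stars at
0.05/0.01/0.001), plus Spearman correlation and simple linear regression
for continuous associations.

## Worked example

```r
library(nkstrat)

cohort <- simulate_cohort(cohort_config(events_per_sample = 2000, seed = 1))
t0 <- cohort$samples[grepl("_T0$|^HD", names(cohort$samples))]
pl <- run_nk_pipeline(t0, K = 27, n_tree_groups = 19,
                      opts = mixture_opts(n_init = 1, seed = 1))
pl
#> <nk_pipeline>
#>   clusters: 729 rows from 27 samples (2 failed)
#>   metaclusters: 19 (13 retained)
#>   populations analyzed: 11
#> <nk_grouping> 3 groups: X (n=12), Y (n=10), Z (n=4)
```

Two of the 29 per-sample mixture fits failed (component collapse) and were
collected rather than aborting the run; 19 metaclusters were cut, 13
survived the rare-representation filter, and the planted-rare
CD56neg CD16+CD57+ population was excluded by the cohort-wide 0.5% rule.
The recovered groups carry the planted signatures:

```r
round(pl$grouping$group_medians[, c("CD56dim NKG2A+", "CD56dim CD57+",
                                    "CD56dim NKG2C+CD57+",
                                    "CD56dim NKG2A-NKG2C-CD57-")], 1)
#>    CD56dim NKG2A+ CD56dim CD57+ CD56dim NKG2C+CD57+ CD56dim NKG2A-NKG2C-CD57-
#> G1           31.2           3.3                 3.1                      12.3
#> G2           13.5          26.1                15.1                      13.2
#> G3           16.2           6.2                 0.7                      44.6
```

Group G1 (labeled X) is dominated by CD56dim NKG2A+ cells (median 31.2% of
NK, planted center 34%), G2 (Y) by the mature CD57+ pools, G3 (Z) by
triple-negative cells (44.6%, planted 42.6%). Viral suppression at month 3
recomputes exactly from the planted metadata:

```r
suppression_table(cohort$metadata, pl$grouping)
#>   group n_suppressed  n      pct
#> 1     X            5 12 41.66667
#> 2     Y            7 10 70.00000
#> 3     Z            1  4 25.00000
```

Group Y — the mature-NK group — reaches 70% suppression (7/10), against
25% (1/4) for the immature group Z. The Mature-category aggregate per
recovered group:

```r
mat <- maturation_summary(pl$freq_analyzed)
a <- pl$grouping$assignments
round(tapply(mat$Mature[match(a$sample_id, mat$sample_id)], a$label, median), 1)
#>    X    Y    Z
#>  7.0 39.6  7.1
```

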