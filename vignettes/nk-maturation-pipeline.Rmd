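---
title: "Stratifying cohorts by NK-cell maturation profile: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratifying cohorts by NK-cell maturation profile: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nkstrat)
```

## The analysis problem

Natural killer (NK) cells mature along a well-described axis: CD56bright
progenitors acquire CD16, lose NKG2A, and eventually express the senescence
marker CD57; NKG2C marks adaptive expansions driven by CMV. A five-marker
panel (CD56, CD16, NKG2A, NKG2C, CD57) therefore encodes the maturation
state of the NK compartment. In primary HIV infection the composition of
this compartment differs strongly between patients, and patients whose NK
cells are skewed toward the mature CD57+ pool have been observed to control
viremia better under early combination antiretroviral therapy.

`nkstrat` implements the unsupervised analysis chain that turns per-sample
cytometry event files into such a patient stratification:

1. **NK pre-gating** — keep viable, dump-negative (CD3-CD14-CD19-) events
   in the CD56+CD16+, CD56+CD16- or CD56-CD16+ quadrants.
2. **Per-sample mixture clustering** — a seeded EM fit of a finite Gaussian
   (optionally Student-t) mixture with a fixed component count `K`
   (default 27), selected once cohort-wide by BIC/ICL scans.
3. **Metaclustering** — pool all cluster centroids, rescale each marker so
   its pooled 5th/95th percentiles land on -3/+3, cluster them
   hierarchically (Euclidean distance, average linkage), cut the tree into
   `n_tree_groups` (default 19) metaclusters, drop rarely-represented ones
   (fewer than 3 member clusters), and annotate the rest as named NK
   populations from their mean signatures.
4. **Frequency matrix** — percentages of total gated NK events per
   population and sample; populations whose cohort-wide mean is below 0.5%
   are excluded from analysis.
5. **Stratification and comparison** — hierarchical clustering of the
   patient rows at inclusion into three groups (X: CD56dim NKG2A+-dominated,
   Y: CD56dim CD57+-dominated, Z: CD56dim triple-negative-dominated),
   compared with tie-corrected Kruskal-Wallis and Dunn's post-hoc tests.

Because no event-level data are publicly available for the motivating
study, the package ships a first-class synthetic-cohort generator that
emulates the study's structure; every stage is validated against the
quantities the generator plants.

## The synthetic cohort: what it emulates

`simulate_cohort()` draws, for each of three patient groups, per-patient
population-frequency vectors and event files:

* **Phenotypes.** `build_default_phenotypes()` defines 13 populations: two
  CD56bright progenitor variants, seven CD56dim variants spanning the
  NKG2A/NKG2C/CD57 combinations, and four CD56neg/CD16low dysfunctional
  variants. Expression levels map to a fixed transformed-intensity grid
  (neg = 0, low = 1, dim = 2.5, bright/high = 4) with a per-marker
  event-level standard deviation of 0.3, so adjacent levels are at least
  3 standard deviations apart and every pair of phenotypes is separable on
  at least one marker. The grid emulates data after a variance-stabilizing
  (arcsinh-like) transform; the generator draws directly on that scale.
* **Group centers.** The per-group median frequencies are the study's
  printed group medians: group X centers on 34% CD56dim NKG2A+, group Y on
  21% CD56dim CD57+ and 17.8% CD56dim NKG2C+CD57+ (39% Mature in total),
  group Z on 42.6% CD56dim triple-negative. Populations without a printed
  median absorb the remaining mass so each center vector sums to 100%. The
  CD56neg CD16+CD57+ population is planted below 0.5% everywhere so the
  rare-population filter always has work to do.
* **Cohort layout.** 14 X + 10 Y + 4 Z patients, two timepoints (T0 before
  therapy, M3 after three months), plus one healthy donor file. The study
  enrolled 30 patients, but its grouping covers the 28 whose samples
  computed; the generator models those 28 directly.
* **Inter-patient noise.** Logistic-normal: each center is multiplied by
  `exp(0.25 z)` and renormalized to the 100% simplex. A log-scale standard
  deviation of 0.25 (~25% coefficient of variation) is a typical
  inter-individual spread for cytometry population frequencies; it keeps
  the groups statistically separable without being trivially so.
* **M3 kinetics.** At M3 the summed CD57+ compartment is shifted by
  +6.6 / +1.4 / +7.7 percentage points for X / Y / Z (the printed T0-to-M3
  deltas), with the mass taken proportionally from the immature CD56dim
  triple-negative and NKG2A+ pools.
* **Metadata.** Clinical scalars (HIV-RNA, HIV-DNA, CD4, CD8, IL-6, IP-10,
  pDC/mDC frequencies, CD38/CD86/PDL-1) are drawn log-normally around
  group-specific medians with the study's ranges; group Y gets the lowest
  viral load, inflammation and activation. Assay floors are honored: HIV-RNA
  is floored at 20 copies/mL and undetectable IL-6 is imputed at
  0.46 pg/mL (half the minimal detectable value). Per group, a planted
  number of patients (6/14, 7/10, 1/4) is suppressed (< 50 copies/mL) at
  M3. IL-6/IP-10/activation centers are not printed in the study and are
  chosen as plausible acute-infection values; only their ordering across
  groups matters to the pipeline.
* **Contaminants.** A 2% fraction of dump-positive (CD3+, CD14+ or CD19+)
  CD16-bright events exercises the gate.

What the generator does **not** emulate: spectral spillover and
compensation residues, doublets, acquisition drift, heavy-tailed or skewed
event clouds, and correlations between populations beyond the simplex
constraint. Passing recovery tests therefore show that the chain of
estimators is consistent under its own model, not that it is robust to all
real-data artifacts.

## Numerical and design choices

* **Mixture model.** Full-covariance Gaussians on transformed data, EM with
  k-means++ initialization, `n_init` restarts (best final log-likelihood
  wins), and a per-iteration covariance ridge of `1e-6 * trace(S)/d`. The
  heavier-tailed Student-t family (fixed 4 degrees of freedom) is available
  behind `mixture_opts(family = "student")`. Box-Cox estimation is not
  re-implemented: the transform is handled upstream and the downstream
  stages depend on centroids, not on the exact likelihood family.
* **Fit failure** is declared when every restart ends with a non-finite
  likelihood, a component weight below `1/(10n)`, or a covariance condition
  number above 1e12. Cohort runs collect failures per sample id and
  continue; at realistic sizes (K = 27 on ~2,000 gated events) an
  occasional sample fails by component collapse, which downstream stages
  tolerate by design.
* **BIC convention.** `BIC = 2 loglik - p log n`, larger is better;
  `ICL = BIC - 2 * assignment entropy`. Both conventions exist in the
  literature, so the sign is stated here and in the documentation.
* **Rescaling.** The percentile anchor map is
  `x -> -3 + 6 (x - p5)/(p95 - p5)` with inclusive linear-interpolation
  percentiles; values outside [-3, 3] are kept (not clipped). No additional
  row normalization is applied: any further per-cluster normalization would
  distort the marker semantics the annotation rules rely on. A
  unit-row-norm switch was considered and rejected for that reason.
* **Tree cutting.** The interactive heatmap cut of the original workflow is
  replaced by an explicit `n_groups` parameter (default 19) — the only
  honest deterministic surrogate for a subjective step. Several
  metaclusters may receive the same population name; they are pooled when
  frequencies are computed, which makes the pipeline insensitive to
  moderate over-cutting.
* **Annotation cutoffs.** On the rescaled scale: negative below -1, low in
  [-1, 0), dim/medium in [0, 1.5), high/bright at or above 1.5 — thirds of
  the anchored range, all overridable. One known soft spot: when very few
  pooled centroids are CD16-negative, the CD16 anchor shifts and the two
  CD56bright variants (CD16- vs CD16low) can merge under one name. Both are
  Progenitors, so category-level results are unaffected.
* **Auto-gating.** The midpoint-between-modes rule finds the deepest
  kernel-density valley between the two highest modes, ignoring peaks below
  0.5% of the maximum density, requiring at least 4 bandwidths between
  modes and a valley below 20% of the lower mode; anything less clearly
  bimodal falls back to a fixed quantile (logged). Without the prominence
  guard, isolated events on sparse channels create micro-peaks that put
  cutoffs inside the main mode.
* **Rare filter.** `min_members = 3` operationalizes "only a few clusters";
  excluded metaclusters keep their events in the total-NK denominator,
  because populations are reported as percentages of all NK cells.
* **Rare-population exclusion** uses the cohort-wide mean (not a
  per-patient criterion) with a strict `< 0.5%` comparison.
* **Stratification** clusters raw percentages (no z-scoring; a
  `standardize` switch exists) of the T0 rows only; M3 samples are scored
  against the T0-derived groups. Group-to-label mapping is by signature
  medians and falls back to neutral G1..Gn labels with a warning when two
  labels claim the same group.
* **Maturation categories.** Progenitors = CD56bright variants; Effectors =
  CD56dim NKG2A+ (with or without NKG2C); Intermediate = CD56dim
  triple-negative and NKG2C+ single-positive; Mature = all CD56dim CD57+
  variants; Dysfunctional = the CD56neg/CD16low variants. The study never
  prints its category membership (its group-Z "Effectors 0" is even
  inconsistent with its own per-population medians), so this map is a
  documented reconstruction and fully overridable via `category_map`.
* **Rank statistics.** Mid-ranks everywhere; Kruskal-Wallis uses the tie
  correction `1 - sum(t^3 - t)/(N^3 - N)`; Dunn's z uses the matching tie
  term, two-sided normal p-values, Bonferroni over all pairs within each
  variable (the behavior of the graphing software the study used).
  Only large-sample approximations are provided; with groups of 4 patients
  the p-values are approximate, which the report does not hide.
* **Indexing.** In-memory event selectors are 1-based (R convention);
  interchange files (gate audit logs) store 0-based indices.

## Problem sizes

The validation suite runs at deliberately modest sizes chosen to exercise
every stage: cohorts of 57 samples at 2,000 events each, K = 27, with the
full recovery study repeated over 10 seeds (a few minutes on one CPU);
oracle-equivalence checks for the EM run at n <= 300, K <= 3, where a naive
reference implementation is feasible. Real cytometry files are two orders
of magnitude larger in events; the per-sample fit scales linearly in
events and quadratically in markers, and nothing in the pipeline assumes
the validation sizes.

## Known limitations

* Exact numerical compatibility with the original t-mixture/Box-Cox
  clustering tool is out of scope; the pipeline reproduces the workflow's
  structure (fixed cohort-wide K, exported centroids, MeV-style
  metaclustering), not its likelihood surface.
* Per-sample K selection is not attempted — K is fixed cohort-wide after
  one scan, as in the original design.
* The annotation rules are interval predicates on rescaled signatures;
  exotic marker distributions that move the percentile anchors far from the
  level grid would require re-tuned cutoffs (all rule parameters are
  exposed).
* The synthetic generator's event model is a diagonal Gaussian mixture;
  its event-level variances are free parameters of this package, not
  published values.
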