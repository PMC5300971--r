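test_that("default phenotype set has 13 uniquely named, separable signatures", {
  phen <- build_default_phenotypes()
  expect_length(phen, 13L)
  expect_false(anyDuplicated(names(phen)) > 0)

  bright <- phen[["CD56bright"]]
  expect_equal(unname(bright$levels["CD56"]), "bright")
  expect_true(bright$levels["CD16"] %in% c("neg", "low"))
  expect_equal(unname(bright$levels["NKG2A"]), "high")

  tn <- phen[["CD56dim NKG2A-NKG2C-CD57-"]]
  expect_equal(unname(tn$levels["CD16"]), "high")

  # every pair separated by >= 3 sd on at least one marker
  mu <- phenotype_means(phen)
  sds <- phen[[1]]$sds
  for (i in seq_len(nrow(mu) - 1)) {
    for (j in (i + 1):nrow(mu)) {
      gap <- abs(mu[i, ] - mu[j, ]) / sds
      expect_gte(max(gap), 3)
    }
  }
  expect_silent(nkstrat:::check_phenotype_monotonicity(phen))
})

test_that("noiseless class means are perfectly separable by nearest centroid", {
  phen <- build_default_phenotypes()
  mu <- phenotype_means(phen)
  d2 <- as.matrix(dist(mu))
  diag(d2) <- Inf
  # nearest other centroid is farther than 0 for every phenotype
  expect_true(all(apply(d2, 1, min) > 0))
  # nearest-true-centroid classification of the noiseless means is identity
  expect_equal(apply(as.matrix(dist(mu)), 1, which.min), seq_len(nrow(mu)),
               ignore_attr = TRUE)
})

test_that("patient frequency draws stay on the 100% simplex", {
  prof <- default_group_profiles()$Y
  # zero spread: renormalized center, exactly
  prof0 <- prof
  prof0$freq_spread <- 0
  f0 <- withr::with_seed(1, sample_patient_frequencies(prof0))
  expect_equal(unname(f0), unname(100 * prof$freq_center / sum(prof$freq_center)))
  # any draw sums to 100
  withr::with_seed(2, {
    for (i in 1:25) {
      expect_equal(sum(sample_patient_frequencies(prof)), 100, tolerance = 1e-9)
      expect_true(all(sample_patient_frequencies(prof) >= 0))
    }
  })
})

test_that("frequency-draw medians sit on the planted centers", {
  prof <- default_group_profiles()$Y
  draws <- withr::with_seed(3, {
    replicate(10000, sample_patient_frequencies(prof)["CD56dim CD57+"])
  })
  expect_lt(abs(median(draws) - prof$freq_center[["CD56dim CD57+"]]), 2)
})

test_that("simulate_sample plants multinomial phenotype mixtures", {
  phen <- build_default_phenotypes()
  panel <- nk_panel()
  # empty case keeps the schema
  f <- stats::setNames(numeric(13), names(phen))
  f[c("CD56bright", "CD56dim CD57+")] <- c(60, 40)
  em0 <- withr::with_seed(1, simulate_sample(f, phen, panel, 0))
  expect_equal(nrow(em0), 0L)
  expect_equal(colnames(em0), panel_channels(panel))

  # 60/40 proportions within 3 binomial sd
  n <- 10000
  em <- withr::with_seed(4, simulate_sample(f, phen, panel, n))
  truth <- attr(em, "truth")
  p_hat <- mean(truth == "CD56bright")
  expect_lt(abs(p_hat - 0.6), 3 * sqrt(0.6 * 0.4 / n))

  # contaminant fraction within 3 binomial sd, detectable on dump channels
  em2 <- withr::with_seed(5, simulate_sample(f, phen, panel, n,
                                             contaminant_fraction = 0.05))
  dump_pos <- rowSums(unclass(em2)[, panel$dump_markers] > 2) > 0
  expect_lt(abs(mean(dump_pos) - 0.05), 3 * sqrt(0.05 * 0.95 / n))

  # frequency vector must sum to 100
  expect_error(simulate_sample(f * 0.9, phen, panel, 10), "sum to 100")
})

test_that("simulate_cohort produces the default cohort layout deterministically", {
  cfg <- cohort_config(events_per_sample = 60, seed = 99)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  c1 <- simulate_cohort(cfg, dir = d1)
  c2 <- simulate_cohort(cfg, dir = d2)

  # 28 patients (14 X + 10 Y + 4 Z), two timepoints each, plus one donor
  expect_equal(length(unique(c1$truth$patient_id[c1$truth$group_label != "healthy"])), 28L)
  expect_equal(sum(c1$metadata$timepoint == "T0"), 29L) # 28 patients + donor
  expect_equal(nrow(c1$metadata), 57L)
  expect_equal(unname(table(c1$truth$group_label)[c("X", "Y", "Z")]),
               c(28L, 20L, 8L), ignore_attr = TRUE)

  # byte-identical rerun under the same seed
  for (f in basename(c1$files)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
  expect_identical(readLines(file.path(d1, "metadata.tsv")),
                   readLines(file.path(d2, "metadata.tsv")))

  # planted per-sample frequencies sum to 100
  pops <- names(build_default_phenotypes())
  sums <- rowSums(c1$truth[, pops])
  expect_equal(unname(sums), rep(100, nrow(c1$truth)), tolerance = 1e-9)
})

test_that("metadata respects assay detection limits", {
  # many seeds so that low draws occur
  md <- do.call(rbind, lapply(1:5, function(s) {
    simulate_cohort(cohort_config(events_per_sample = 1, seed = s), dir = NULL)$metadata
  }))
  expect_true(all(md$hiv_rna >= log10(20) - 1e-12, na.rm = TRUE))
  expect_true(all(md$il6 >= 0.46 - 1e-12, na.rm = TRUE))
  expect_true(all(md$cd4 >= 0 & md$cd8 >= 0, na.rm = TRUE))
  # the M3 floor is actually exercised: suppressed patients can hit 20 cp/mL
  m3 <- md[md$timepoint == "M3" & md$suppressed_m3 %in% TRUE, ]
  expect_true(all(m3$hiv_rna < log10(50)))
})

test_that("planted suppression counts follow the group profiles", {
  cohort <- simulate_cohort(cohort_config(events_per_sample = 1, seed = 3),
                            dir = NULL)
  truth_groups <- stats::setNames(
    c1 <- cohort$truth$group_label[cohort$truth$timepoint == "T0" &
                                     cohort$truth$group_label != "healthy"],
    cohort$truth$patient_id[cohort$truth$timepoint == "T0" &
                              cohort$truth$group_label != "healthy"])
  tab <- suppression_table(cohort$metadata, truth_groups)
  expect_equal(tab$n_suppressed[tab$group == "X"], 6L)
  expect_equal(tab$n[tab$group == "X"], 14L)
  expect_equal(tab$n_suppressed[tab$group == "Y"], 7L)
  expect_equal(tab$pct[tab$group == "Y"], 70)
  expect_equal(tab$n_suppressed[tab$group == "Z"], 1L)
  expect_equal(tab$pct[tab$group == "Z"], 25)
})
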