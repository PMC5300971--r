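markers5 <- nk_panel()$nk_markers

# helper: metaclusters object with planted populations and counts
planted_metaclusters <- function(counts_by_pop, sample_ids = "S1") {
  # counts_by_pop: named list population -> vector of per-sample event counts
  pops <- names(counts_by_pop)
  n <- length(pops)
  sig <- phenotype_means(build_default_phenotypes())[pops, , drop = FALSE]
  rows <- list(); mem <- list(); id <- 0L
  for (i in seq_len(n)) {
    id <- id + 1L
    rows[[i]] <- data.frame(metacluster_id = id, n_members = length(sample_ids),
                            retained = TRUE, population = pops[i],
                            as.data.frame(t(sig[i, ])), check.names = FALSE,
                            stringsAsFactors = FALSE)
    mem[[i]] <- data.frame(sample_id = sample_ids, cluster_id = i,
                           event_count = counts_by_pop[[i]],
                           metacluster_id = id, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "membership") <- do.call(rbind, mem)
  attr(out, "markers") <- markers5
  class(out) <- c("nk_metaclusters", "data.frame")
  out
}

test_that("population frequencies are percentages of total gated NK events", {
  mc <- planted_metaclusters(list("CD56bright" = 100))
  f <- population_frequencies(mc)
  expect_equal(unname(f["S1", "CD56bright"]), 100)

  mc <- planted_metaclusters(list("CD56bright" = 25, "CD56dim NKG2A+" = 25,
                                  "CD56dim CD57+" = 50))
  f <- population_frequencies(mc)
  expect_equal(unname(f["S1", c("CD56bright", "CD56dim NKG2A+",
                                "CD56dim CD57+")]),
               c(25, 25, 50))
  expect_equal(unname(attr(f, "total_nk_events")), 100)
})

test_that("same-named metaclusters pool additively", {
  mc2 <- planted_metaclusters(list("CD56bright" = 30, "CD56dim NKG2A+" = 50,
                                   "CD56dim CD57+" = 20))
  # split the bright metacluster into two sharing the name
  mc_split <- mc2
  mem <- attr(mc2, "membership")
  extra <- mc2[1, ]; extra$metacluster_id <- 99L
  mc_split <- rbind(mc2, extra)
  attr(mc_split, "markers") <- markers5
  mem2 <- rbind(mem, data.frame(sample_id = "S1", cluster_id = 4L,
                                event_count = 10, metacluster_id = 99L))
  mem2$event_count[1] <- 20 # 20 + 10 = the original 30
  attr(mc_split, "membership") <- mem2
  class(mc_split) <- class(mc2)
  f_joint <- population_frequencies(mc_split)
  f_ref <- population_frequencies(mc2)
  expect_equal(f_joint[, "CD56bright"], f_ref[, "CD56bright"])
})

test_that("rare and unclassified metaclusters stay in the denominator", {
  mc <- planted_metaclusters(list("CD56bright" = 60, "CD56dim NKG2A+" = 30))
  mc$retained[2] <- FALSE
  mc$population[2] <- NA_character_
  f <- population_frequencies(mc)
  expect_equal(unname(f["S1", "CD56bright"]), 100 * 60 / 90)
  expect_equal(unname(attr(f, "other_pct")["S1"]), 100 * 30 / 90)
  expect_false("CD56dim NKG2A+" %in% colnames(f))
})

test_that("cohort-wide rare populations are excluded at a strict threshold", {
  pops <- names(build_default_phenotypes())
  m <- matrix(10, 4, 13, dimnames = list(paste0("P", 1:4, "_T0"), pops))
  m[, "CD56neg CD16+CD57+"] <- 0.3
  out <- exclude_rare_populations(m, 0.5)
  expect_equal(ncol(out), 12L)
  expect_equal(attr(out, "excluded_populations"), "CD56neg CD16+CD57+")
  # threshold 0 drops nothing
  expect_equal(ncol(exclude_rare_populations(m, 0)), 13L)
  # boundary: strictly-below comparison retains an exact-threshold column
  m[, "CD56neg CD16+CD57+"] <- 0.5
  expect_equal(ncol(exclude_rare_populations(m, 0.5)), 13L)
  expect_error(exclude_rare_populations(m * 0, 5), "every population")
})

test_that("zero-noise cohorts stratify into the planted partition", {
  profs <- default_group_profiles(freq_spread = 0)
  pops <- names(build_default_phenotypes())
  rows <- list()
  for (p in profs) {
    for (i in seq_len(p$n_patients)) {
      f <- stats::setNames(numeric(13), pops)
      f[names(p$freq_center)] <- 100 * p$freq_center / sum(p$freq_center)
      rows[[paste0(p$group_label, i, "_T0")]] <- f
    }
  }
  m <- do.call(rbind, rows)
  gr <- stratify_patients(m, 3)
  a <- gr$assignments
  planted <- sub("[0-9]+_T0$", "", a$sample_id)
  expect_equal(ari(a$label, planted), 1)
  # labels map to the right planted groups via the signature populations
  expect_true(all(a$label == planted))
  expect_equal(unname(table(a$label)[c("X", "Y", "Z")]), c(14L, 10L, 4L),
               ignore_attr = TRUE)
})

test_that("stratification is invariant to row and column order", {
  withr::local_seed(26)
  profs <- default_group_profiles(freq_spread = 0.15)
  pops <- names(build_default_phenotypes())
  rows <- list()
  for (p in profs) {
    for (i in seq_len(p$n_patients)) {
      f <- stats::setNames(numeric(13), pops)
      f[names(p$freq_center)] <- sample_patient_frequencies(p)
      rows[[paste0(p$group_label, i, "_T0")]] <- f
    }
  }
  m <- do.call(rbind, rows)
  g1 <- stratify_patients(m, 3)
  perm <- sample(nrow(m))
  cperm <- sample(ncol(m))
  g2 <- stratify_patients(m[perm, cperm], 3)
  a1 <- g1$assignments
  a2 <- g2$assignments[match(a1$sample_id, g2$assignments$sample_id), ]
  expect_equal(ari(a1$label, a2$label), 1)
  expect_equal(a1$label, a2$label)
})

test_that("ambiguous group naming falls back to neutral labels", {
  pops <- names(build_default_phenotypes())
  m <- matrix(1, 6, 13, dimnames = list(paste0("P", 1:6, "_T0"), pops))
  # two clusters of patients, both dominated by the same signature population
  m[1:3, "CD56dim NKG2A+"] <- 60
  m[4:6, "CD56dim NKG2A+"] <- 40
  m[1:3, "CD56dim CD57+"] <- 30
  m[4:6, "CD56dim CD57+"] <- 20
  expect_warning(gr <- stratify_patients(m, 2), "ambiguous")
  expect_true(all(grepl("^G[0-9]+$", gr$assignments$label)))
})

test_that("maturation summaries add population frequencies by category", {
  pops <- names(build_default_phenotypes())
  m <- matrix(0, 1, 13, dimnames = list("P1_T0", pops))
  m[1, "CD56dim CD57+"] <- 40
  m[1, "CD56dim NKG2C+CD57+"] <- 10
  s <- maturation_summary(m)
  expect_equal(s$cd57_total, 50)
  expect_equal(s$Mature, 50)
  expect_equal(s$Progenitors, 0)

  # unmapped population errors by name
  m2 <- cbind(m, "CD56 weird" = 5)
  expect_error(maturation_summary(m2), "CD56 weird")

  # empty category in a custom map gives a zero aggregate
  cmap <- c(stats::setNames(rep("Everything", 13), pops))
  s2 <- maturation_summary(m, cmap)
  expect_equal(s2$Everything, 50)
})

test_that("suppression percentages are exact arithmetic", {
  md <- data.frame(
    patient_id = c(paste0("Y", 1:10), paste0("Z", 1:4), "N1"),
    timepoint = "M3",
    hiv_rna = c(rep(1.4, 7), rep(2.5, 3),  # Y: 7/10 below 50
                1.5, rep(3, 3),            # Z: 1/4
                3))                        # N: 0/1
  grouping <- stats::setNames(c(rep("Y", 10), rep("Z", 4), "N"), md$patient_id)
  tab <- suppression_table(md, grouping)
  expect_equal(tab$pct[tab$group == "Y"], 70)
  expect_equal(tab$pct[tab$group == "Z"], 25)
  expect_equal(tab$pct[tab$group == "N"], 0)
  comb <- suppression_table(md, grouping, combine = list("Y+Z" = c("Y", "Z")))
  expect_equal(comb$n_suppressed[comb$group == "Y+Z"], 8L)
  expect_equal(comb$n[comb$group == "Y+Z"], 14L)
})

test_that("frequency matrices round-trip through the tab-delimited export", {
  mc <- planted_metaclusters(list("CD56bright" = 25, "CD56dim NKG2A+" = 75))
  f <- population_frequencies(mc)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_frequency_matrix(f, path)
  back <- utils::read.delim(path, check.names = FALSE)
  expect_equal(back$`CD56bright`, 25)
  expect_equal(back$sample_id, "S1")
})
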