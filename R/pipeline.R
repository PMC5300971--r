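#' Run the full NK maturation pipeline on a set of samples
#'
#' Chains the stages: NK pre-gate per sample, per-sample mixture clustering
#' with fixed K, pooling and percentile-rescaling of cluster centroids,
#' hierarchical metaclustering with a fixed tree cut, rare-metacluster
#' filtering, population annotation, per-sample frequency matrix, cohort-wide
#' rare-population exclusion and patient stratification.
#'
#' @param samples Named list of [event_matrix()] objects (ungated; the NK
#'   gate is applied here), or a `simulate_cohort()` result.
#' @param K Mixture components per sample (default 27).
#' @param n_tree_groups Metacluster tree cut (default 19).
#' @param min_members Rare-metacluster retention threshold (default 3).
#' @param n_patient_groups Patient strata (default 3).
#' @param exclusion_threshold Cohort-wide rare-population exclusion, in %
#'   of NK (default 0.5).
#' @param opts [mixture_opts()] for the per-sample fits.
#' @param panel Marker panel.
#' @param gate_thresholds Named cutoff vector for [gate_nk()]; `NULL`
#'   derives them per sample with [default_gate_thresholds()].
#' @param t0_pattern Regular expression selecting the patient rows used for
#'   stratification (healthy donors do not match).
#' @return List of class `nk_pipeline`: `cluster_table`,
#'   `failed_sample_ids`, `rescaled`, `dendrogram`, `metaclusters`
#'   (annotated), `freq` (all named populations), `freq_analyzed` (after
#'   exclusion), `grouping`, `maturation`, `gates`.
#' @export
run_nk_pipeline <- function(samples, K = 27, n_tree_groups = 19,
                            min_members = 3, n_patient_groups = 3,
                            exclusion_threshold = 0.5,
                            opts = mixture_opts(n_init = 1),
                            panel = nk_panel(), gate_thresholds = NULL,
                            t0_pattern = "_T0$") {
  if (is.list(samples) && !is.null(samples$samples)) samples <- samples$samples
  gates <- list()
  gated <- list()
  for (sid in names(samples)) {
    em <- samples[[sid]]
    thr <- if (is.null(gate_thresholds)) {
      default_gate_thresholds(em, panel)
    } else gate_thresholds
    g <- gate_nk(em, thr, panel)
    gates[[sid]] <- g
    gated[[sid]] <- apply_gate(em, g)
  }
  cc <- cluster_cohort(gated, K, opts, markers = panel$nk_markers)
  rescaled <- rescale_centers(cc$cluster_table, panel$nk_markers)
  hc <- nk_hclust(rescaled)
  labels <- cut_tree(hc, n_tree_groups)
  mc <- build_metaclusters(rescaled, labels)
  mc <- filter_rare(mc, min_members)
  mc <- annotate(mc)
  freq <- population_frequencies(mc)
  freq_analyzed <- exclude_rare_populations(freq, exclusion_threshold)
  t0_rows <- grep(t0_pattern, rownames(freq_analyzed), value = TRUE)
  grouping <- NULL
  if (length(t0_rows) >= n_patient_groups) {
    grouping <- stratify_patients(freq_analyzed[t0_rows, , drop = FALSE],
                                  n_groups = n_patient_groups)
  }
  maturation <- tryCatch(maturation_summary(freq),
                         error = function(e) NULL)
  structure(list(cluster_table = cc$cluster_table,
                 failed_sample_ids = cc$failed_sample_ids,
                 rescaled = rescaled, dendrogram = hc, metaclusters = mc,
                 freq = freq, freq_analyzed = freq_analyzed,
                 grouping = grouping, maturation = maturation,
                 gates = gates),
            class = "nk_pipeline")
}

#' @export
print.nk_pipeline <- function(x, ...) {
  cat("<nk_pipeline>\n")
  cat("  clusters: ", nrow(x$cluster_table), " rows from ",
      length(unique(x$cluster_table$sample_id)), " samples (",
      length(x$failed_sample_ids), " failed)\n", sep = "")
  cat("  metaclusters: ", nrow(x$metaclusters), " (",
      sum(x$metaclusters$retained), " retained)\n", sep = "")
  cat("  populations analyzed: ", ncol(x$freq_analyzed), "\n", sep = "")
  if (!is.null(x$grouping)) print(x$grouping)
  invisible(x)
}

#' Recovered per-group population medians on synthetic cohorts
#'
#' Simulates a default synthetic cohort per seed (T0 samples plus healthy
#' donor), runs the full pipeline through [stratify_patients()], and
#' records the recovered groups' median frequencies of the four signature
#' populations plus the Mature-category aggregate. Used to check that the
#' pipeline recovers the frequencies the generator plants.
#'
#' @param seeds Integer vector of cohort seeds.
#' @param events_per_sample Events per sample (default 2000).
#' @param K,n_tree_groups Pipeline parameters.
#' @param timepoint `"T0"` (default) restricts simulation and analysis to
#'   inclusion samples.
#' @return Data.frame, one row per seed: `seed`, recovered
#'   `X_dim_nkg2a` (median CD56dim NKG2A+ in the X-like group),
#'   `Y_dim_cd57` , `Y_dim_nkg2c_cd57`, `Z_triple_neg`, `Y_mature`
#'   (Mature-category aggregate in Y), and the recovered group sizes.
#' @export
recover_group_medians <- function(seeds, events_per_sample = 2000, K = 27,
                                  n_tree_groups = 19, timepoint = "T0") {
  rows <- lapply(seeds, function(s) {
    cfg <- cohort_config(events_per_sample = events_per_sample, seed = s)
    cohort <- simulate_cohort(cfg, dir = NULL)
    keep <- grepl(paste0("_", timepoint, "$"), names(cohort$samples)) |
      grepl("^HD", names(cohort$samples))
    pl <- run_nk_pipeline(cohort$samples[keep], K = K,
                          n_tree_groups = n_tree_groups,
                          opts = mixture_opts(n_init = 1, seed = s))
    gr <- pl$grouping
    a <- gr$assignments
    med_of <- function(label, pop) {
      rows <- a$sample_id[a$label == label]
      if (!length(rows) || !pop %in% colnames(pl$freq_analyzed)) return(NA_real_)
      stats::median(pl$freq_analyzed[rows, pop])
    }
    mat <- maturation_summary(pl$freq_analyzed[a$sample_id, , drop = FALSE])
    y_rows <- a$label == "Y"
    data.frame(
      seed = s,
      X_dim_nkg2a = med_of("X", "CD56dim NKG2A+"),
      Y_dim_cd57 = med_of("Y", "CD56dim CD57+"),
      Y_dim_nkg2c_cd57 = med_of("Y", "CD56dim NKG2C+CD57+"),
      Z_triple_neg = med_of("Z", "CD56dim NKG2A-NKG2C-CD57-"),
      Y_mature = if (any(y_rows)) stats::median(mat$Mature[y_rows]) else NA_real_,
      n_X = sum(a$label == "X"), n_Y = sum(y_rows), n_Z = sum(a$label == "Z"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
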