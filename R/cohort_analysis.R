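#' Per-sample NK population frequency matrix
#'
#' Pools the event counts of each sample's clusters by annotated population
#' and expresses them as percentages of the sample's total gated NK events.
#' Metaclusters sharing a population name are pooled; rare (non-retained)
#' and unclassified metaclusters contribute no named population but stay in
#' the total-NK denominator.
#'
#' @param metaclusters An annotated `nk_metaclusters` (see [annotate()]);
#'   its `"membership"` attribute must carry `sample_id`, `cluster_id` and
#'   `event_count`.
#' @return A matrix of class `nk_freq` (rows = samples, columns = named
#'   populations, values = % of total NK). Attributes: `total_nk_events`
#'   (per row), `other_pct` (rare + unclassified mass per row).
#' @export
population_frequencies <- function(metaclusters) {
  stopifnot(inherits(metaclusters, "nk_metaclusters"))
  mem <- attr(metaclusters, "membership")
  if (is.null(mem$event_count)) {
    stop("membership lacks event counts; build the cluster table with cluster_cohort()")
  }
  pop_of <- stats::setNames(metaclusters$population,
                            metaclusters$metacluster_id)
  mem$population <- pop_of[as.character(mem$metacluster_id)]
  named <- !is.na(mem$population) & mem$population != "unclassified"
  pops <- sort(unique(mem$population[named]))
  samples <- unique(mem$sample_id)
  totals <- vapply(samples, function(s) {
    sum(mem$event_count[mem$sample_id == s])
  }, numeric(1))
  if (any(totals == 0)) {
    warning("sample(s) with zero gated events: ",
            paste(samples[totals == 0], collapse = ", "))
  }
  freq <- matrix(0, length(samples), length(pops),
                 dimnames = list(samples, pops))
  for (s in samples) {
    sel <- mem$sample_id == s & named
    if (!any(sel)) next
    cnt <- tapply(mem$event_count[sel], mem$population[sel], sum)
    freq[s, names(cnt)] <- 100 * cnt / totals[[s]]
  }
  freq[samples[totals == 0], ] <- NA_real_
  structure(freq, total_nk_events = totals,
            other_pct = 100 - rowSums(freq),
            class = c("nk_freq", class(freq)))
}

#' Drop populations that are rare cohort-wide
#'
#' Removes population columns whose cohort-wide mean frequency is strictly
#' below `threshold` percent of total NK cells.
#'
#' @param freq An `nk_freq` matrix (or plain matrix).
#' @param threshold Exclusion threshold in percent (default 0.5).
#' @return The reduced matrix; attribute `"excluded_populations"` lists the
#'   dropped columns.
#' @export
exclude_rare_populations <- function(freq, threshold = 0.5) {
  if (threshold < 0) stop("threshold must be >= 0 (percent units)")
  mu <- colMeans(freq, na.rm = TRUE)
  drop <- which(mu < threshold)
  if (length(drop) == ncol(freq)) {
    stop("exclusion threshold drops every population")
  }
  out <- freq[, setdiff(seq_len(ncol(freq)), drop), drop = FALSE]
  attr(out, "excluded_populations") <- colnames(freq)[drop]
  attr(out, "total_nk_events") <- attr(freq, "total_nk_events")
  out
}

#' Stratify patients by their NK population profile
#'
#' Hierarchically clusters the patient rows of the frequency matrix
#' (Euclidean distance, average linkage by default, raw percentages) and
#' cuts the tree into `n_groups`. Groups are mapped to the maturation-profile
#' labels X, Y and Z by matching group medians against signature
#' populations: X has the highest CD56dim NKG2A+ median, Y the highest
#' CD56dim CD57+, Z the highest CD56dim triple-negative. If two labels
#' claim the same group the mapping is ambiguous and groups keep their
#' neutral G1..Gn names with a warning. A column dendrogram over
#' populations is computed for two-way displays.
#'
#' @param freq Frequency matrix with one row per patient (typically the T0
#'   rows of [population_frequencies()]).
#' @param n_groups Number of patient groups (default 3).
#' @param metric,linkage Distance and agglomeration method.
#' @param signature_pops Named character vector mapping labels to their
#'   signature population.
#' @param standardize Z-score the columns before clustering (default FALSE:
#'   distances on raw percentages).
#' @return An object of class `nk_grouping`: list with `assignments`
#'   (data.frame `sample_id`, `group`, `label`), `row_dendrogram`,
#'   `col_dendrogram`, `group_medians` (groups x populations matrix) and
#'   `label_of_group`.
#' @export
stratify_patients <- function(freq, n_groups = 3, metric = "euclidean",
                              linkage = "average",
                              signature_pops = c(
                                X = "CD56dim NKG2A+",
                                Y = "CD56dim CD57+",
                                Z = "CD56dim NKG2A-NKG2C-CD57-"),
                              standardize = FALSE) {
  m <- unclass(freq)
  if (nrow(m) < n_groups) stop("fewer patients than groups")
  mc <- if (standardize) scale(m) else m
  row_hc <- nk_hclust(mc, metric = metric, linkage = linkage)
  col_hc <- if (ncol(m) >= 2) nk_hclust(t(mc), metric = metric,
                                        linkage = linkage) else NULL
  grp <- cut_tree(row_hc, n_groups)
  med <- t(vapply(sort(unique(grp)), function(g) {
    apply(m[grp == g, , drop = FALSE], 2L, stats::median)
  }, numeric(ncol(m))))
  rownames(med) <- paste0("G", sort(unique(grp)))
  label_of <- stats::setNames(rownames(med), rownames(med))
  sig_present <- signature_pops[signature_pops %in% colnames(m)]
  if (length(sig_present) == length(signature_pops)) {
    claim <- vapply(signature_pops, function(p) which.max(med[, p]), integer(1))
    if (anyDuplicated(claim)) {
      warning("ambiguous group naming: two labels claim the same group; ",
              "keeping neutral G1..Gn labels")
    } else {
      label_of[claim] <- names(signature_pops)
    }
  }
  assignments <- data.frame(sample_id = rownames(m),
                            group = paste0("G", grp),
                            label = unname(label_of[paste0("G", grp)]),
                            stringsAsFactors = FALSE)
  structure(list(assignments = assignments, row_dendrogram = row_hc,
                 col_dendrogram = col_hc, group_medians = med,
                 label_of_group = label_of, n_groups = n_groups),
            class = "nk_grouping")
}

#' @export
print.nk_grouping <- function(x, ...) {
  cat("<nk_grouping> ", x$n_groups, " groups: ",
      paste(sprintf("%s (n=%d)", x$label_of_group,
                    table(x$assignments$group)[names(x$label_of_group)]),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Default maturation-category map
#'
#' Assigns each of the thirteen default populations to one maturation
#' category: Progenitors (CD56bright variants), Effectors (CD56dim NKG2A+
#' with or without NKG2C), Intermediate (CD56dim triple-negative and
#' NKG2C+ single-positive), Mature (all CD56dim CD57+ variants) and
#' Dysfunctional (CD56neg/CD16low variants). The map is a documented
#' reconstruction and fully overridable.
#'
#' @return Named character vector population -> category.
#' @export
default_category_map <- function() {
  c("CD56bright" = "Progenitors",
    "CD56bright CD16low" = "Progenitors",
    "CD56dim NKG2A+" = "Effectors",
    "CD56dim NKG2A+NKG2C+" = "Effectors",
    "CD56dim NKG2A-NKG2C-CD57-" = "Intermediate",
    "CD56dim NKG2C+" = "Intermediate",
    "CD56dim CD57+" = "Mature",
    "CD56dim NKG2C+CD57+" = "Mature",
    "CD56dim NKG2A+CD57+" = "Mature",
    "CD56neg CD16+NKG2A+" = "Dysfunctional",
    "CD56neg CD16+CD57+" = "Dysfunctional",
    "CD56neg CD16+" = "Dysfunctional",
    "CD56dim CD16low" = "Dysfunctional")
}

#' Maturation summaries per sample
#'
#' Sums population frequencies into maturation-category aggregates and into
#' the total CD57+ compartment (every population whose name contains
#' "CD57+").
#'
#' @param freq Frequency matrix (rows = samples).
#' @param category_map Named character vector population -> category; every
#'   column of `freq` must be mapped.
#' @return Data.frame with `sample_id`, one column per category, and
#'   `cd57_total`.
#' @export
maturation_summary <- function(freq, category_map = default_category_map()) {
  m <- unclass(freq)
  unmapped <- setdiff(colnames(m), names(category_map))
  if (length(unmapped)) {
    stop("population(s) missing from the category map: ",
         paste(unmapped, collapse = ", "))
  }
  cats <- unique(unname(category_map))
  out <- data.frame(sample_id = rownames(m), stringsAsFactors = FALSE)
  for (cat in cats) {
    cols <- intersect(names(category_map)[category_map == cat], colnames(m))
    out[[cat]] <- if (length(cols)) rowSums(m[, cols, drop = FALSE]) else 0
  }
  cd57_cols <- grep("CD57\\+", colnames(m), value = TRUE)
  out$cd57_total <- if (length(cd57_cols)) {
    rowSums(m[, cd57_cols, drop = FALSE])
  } else 0
  rownames(out) <- NULL
  out
}

#' Viral suppression by patient group
#'
#' Counts, per group, the patients whose M3 HIV-RNA is below the threshold,
#' and reports the exact percentage.
#'
#' @param metadata Cohort metadata with `patient_id`, `timepoint` and
#'   `hiv_rna` (log10 copies/mL).
#' @param grouping An `nk_grouping`, or a named character vector
#'   patient_id -> group label.
#' @param threshold Suppression threshold in copies/mL (default 50).
#' @param combine Optional named list of label vectors to also report
#'   combined, e.g. `list("X+Z" = c("X", "Z"))`.
#' @return Data.frame with `group`, `n_suppressed`, `n`, `pct`.
#' @export
suppression_table <- function(metadata, grouping, threshold = 50,
                              combine = NULL) {
  if (inherits(grouping, "nk_grouping")) {
    a <- grouping$assignments
    pid <- sub("_(T0|M3)$", "", a$sample_id)
    grouping <- stats::setNames(a$label, pid)
  }
  m3 <- metadata[metadata$timepoint == "M3", , drop = FALSE]
  m3 <- m3[m3$patient_id %in% names(grouping), , drop = FALSE]
  if (!nrow(m3)) stop("no M3 rows for the grouped patients")
  grp <- unname(grouping[m3$patient_id])
  below <- m3$hiv_rna < log10(threshold)
  one <- function(label, sel) {
    data.frame(group = label, n_suppressed = sum(below[sel]), n = sum(sel),
               pct = 100 * sum(below[sel]) / sum(sel),
               stringsAsFactors = FALSE)
  }
  rows <- lapply(sort(unique(grp)), function(g) one(g, grp == g))
  if (!is.null(combine)) {
    rows <- c(rows, lapply(names(combine), function(nm) {
      one(nm, grp %in% combine[[nm]])
    }))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a frequency matrix as tab-delimited text
#'
#' @param freq An `nk_freq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frequency_matrix <- function(freq, path) {
  df <- data.frame(sample_id = rownames(freq), unclass(freq),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
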