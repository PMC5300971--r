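#' Percentile-rescale pooled cluster centroids
#'
#' Each marker dimension of the pooled cluster-center matrix is mapped
#' linearly so that its empirical 5th percentile lands on -3 and its 95th on
#' +3 (`x -> -3 + 6 * (x - p5) / (p95 - p5)`, inclusive linear-interpolation
#' percentiles). Values outside `[-3, 3]` are permitted, not clipped.
#'
#' @param cluster_table Data.frame from [cluster_cohort()] (or any table
#'   with `sample_id`, `cluster_id` and marker columns).
#' @param markers Marker columns to rescale.
#' @return An object of class `nk_rescaled`: list with `scaled` (matrix,
#'   rows keyed by `sample_id:cluster_id`), `anchors` (per-marker `p5`,
#'   `p95`), `keys` (the key data.frame).
#' @export
rescale_centers <- function(cluster_table, markers = nk_panel()$nk_markers) {
  missing <- setdiff(markers, colnames(cluster_table))
  if (length(missing)) {
    stop("cluster table lacks marker column(s): ", paste(missing, collapse = ", "))
  }
  m <- as.matrix(cluster_table[, markers, drop = FALSE])
  if (nrow(m) < 2L) stop("need at least 2 pooled centers to rescale")
  anchors <- t(apply(m, 2L, stats::quantile, probs = c(0.05, 0.95),
                     names = FALSE, type = 7))
  colnames(anchors) <- c("p5", "p95")
  flat <- which(anchors[, "p95"] - anchors[, "p5"] <= 0)
  if (length(flat)) {
    stop("marker(s) with p95 equal to p5 cannot be rescaled: ",
         paste(markers[flat], collapse = ", "))
  }
  scaled <- sweep(m, 2L, anchors[, "p5"])
  scaled <- sweep(scaled, 2L, anchors[, "p95"] - anchors[, "p5"], "/") * 6 - 3
  keys <- cluster_table[, intersect(c("sample_id", "cluster_id", "event_count"),
                                    colnames(cluster_table)), drop = FALSE]
  if (all(c("sample_id", "cluster_id") %in% colnames(keys))) {
    rownames(scaled) <- paste(keys$sample_id, keys$cluster_id, sep = ":")
  }
  structure(list(scaled = scaled, anchors = anchors, keys = keys,
                 markers = markers),
            class = "nk_rescaled")
}

#' Evaluate the stored rescale map
#'
#' @param rescaled An `nk_rescaled`.
#' @param marker Marker name.
#' @param value Raw-scale value(s).
#' @return Rescaled value(s).
#' @export
rescale_map <- function(rescaled, marker, value) {
  a <- rescaled$anchors[marker, ]
  -3 + 6 * (value - a["p5"]) / (a["p95"] - a["p5"])
}

#' Hierarchical clustering of rescaled centers
#'
#' Euclidean distance with average linkage by default, matching the
#' metaclustering stage of the pipeline. Thin wrapper around
#' [stats::hclust()]; with continuous centroid coordinates the dendrogram is
#' deterministic and invariant to input row order up to leaf labeling.
#'
#' @param x An `nk_rescaled`, or a numeric matrix.
#' @param metric Distance metric (passed to [stats::dist()]).
#' @param linkage Agglomeration method (passed to [stats::hclust()]).
#' @return An [stats::hclust] dendrogram.
#' @export
nk_hclust <- function(x, metric = "euclidean", linkage = "average") {
  m <- if (inherits(x, "nk_rescaled")) x$scaled else as.matrix(x)
  if (nrow(m) < 2L) stop("need at least 2 rows to build a dendrogram")
  if (any(!is.finite(m))) stop("non-finite values in clustering input")
  stats::hclust(stats::dist(m, method = metric), method = linkage)
}

#' Cut a dendrogram into a fixed number of groups
#'
#' @param dendrogram An [stats::hclust] object.
#' @param n_groups Number of groups, between 1 and the number of leaves.
#' @return Integer vector of group labels (named by leaf labels).
#' @export
cut_tree <- function(dendrogram, n_groups) {
  n <- length(dendrogram$order)
  if (n_groups < 1 || n_groups > n) {
    stop("n_groups must be between 1 and the number of leaves (", n, ")")
  }
  stats::cutree(dendrogram, k = n_groups)
}

#' Build metaclusters from a tree cut
#'
#' @param rescaled An `nk_rescaled`.
#' @param labels Group labels from [cut_tree()] (one per pooled center).
#' @return Data.frame of class `nk_metaclusters`: one row per metacluster
#'   with `metacluster_id`, `n_members`, `retained` (all `TRUE` initially),
#'   `population` (`NA` until annotated) and the unweighted mean signature
#'   per marker; attribute `"membership"` maps every pooled center to its
#'   metacluster.
#' @export
build_metaclusters <- function(rescaled, labels) {
  stopifnot(inherits(rescaled, "nk_rescaled"),
            length(labels) == nrow(rescaled$scaled))
  ids <- sort(unique(labels))
  sig <- t(vapply(ids, function(g) {
    colMeans(rescaled$scaled[labels == g, , drop = FALSE])
  }, numeric(ncol(rescaled$scaled))))
  out <- data.frame(metacluster_id = ids,
                    n_members = as.integer(table(labels)[as.character(ids)]),
                    retained = TRUE, population = NA_character_,
                    sig, check.names = FALSE, stringsAsFactors = FALSE)
  attr(out, "membership") <- data.frame(rescaled$keys,
                                        metacluster_id = labels,
                                        stringsAsFactors = FALSE)
  attr(out, "markers") <- rescaled$markers
  class(out) <- c("nk_metaclusters", "data.frame")
  out
}

#' Flag rarely-represented metaclusters
#'
#' Metaclusters with fewer member clusters than `min_members` are flagged
#' `retained = FALSE`. Their events are not removed from the total-NK
#' denominator downstream; they simply contribute no named population.
#'
#' @param metaclusters An `nk_metaclusters`.
#' @param min_members Minimum member clusters to retain (default 3).
#' @return The table with updated `retained` flags.
#' @export
filter_rare <- function(metaclusters, min_members = 3) {
  if (min_members < 1) stop("min_members must be >= 1")
  metaclusters$retained <- metaclusters$n_members >= min_members
  if (!any(metaclusters$retained)) {
    warning("filter_rare: every metacluster is below min_members")
  }
  metaclusters
}

#' Default annotation rules for the five-marker NK panel
#'
#' Level cutoffs on the rescaled scale: negative below -1, low in
#' `[-1, 0)`, dim/medium in `[0, 1.5)`, high/bright at or above 1.5 --
#' thirds of the anchored `[-3, 3]` range. Rules are ordered most-specific
#' first; the first rule whose predicates all hold names the metacluster.
#'
#' @param hi Lower bound of the high/bright band (default 1.5).
#' @param lo Upper bound of the negative band (default -1).
#' @return List of rules (class `nk_annotation_rules`); each rule has a
#'   `population` and a named list of per-marker interval predicates
#'   `c(min, max)`.
#' @export
default_annotation_rules <- function(hi = 1.5, lo = -1) {
  R <- function(population, CD56, CD16, NKG2A, NKG2C, CD57) {
    list(population = population,
         predicates = list(CD56 = CD56, CD16 = CD16, NKG2A = NKG2A,
                           NKG2C = NKG2C, CD57 = CD57))
  }
  NEG <- c(-Inf, lo)    # negative
  NLO <- c(-Inf, 0)     # negative or low
  LOW <- c(lo, 0)       # low
  MED <- c(0, hi)       # dim / medium
  HI  <- c(hi, Inf)     # high / bright
  POS <- c(0, Inf)      # medium or high
  ANY <- c(-Inf, Inf)
  rules <- list(
    # progenitors: brightest CD56, high NKG2A, no/low CD16
    R("CD56bright CD16low",         HI,  LOW, POS, ANY, NLO),
    R("CD56bright",                 HI,  NLO, POS, ANY, NLO),
    # CD56dim pool (medium CD56, high CD16)
    R("CD56dim NKG2A+NKG2C+",       MED, POS, HI,  HI,  NLO),
    R("CD56dim NKG2A+CD57+",        MED, POS, HI,  NLO, HI),
    R("CD56dim NKG2C+CD57+",        MED, POS, NLO, HI,  HI),
    R("CD56dim NKG2A+",             MED, POS, HI,  NLO, NLO),
    R("CD56dim NKG2C+",             MED, POS, NLO, HI,  NLO),
    R("CD56dim CD57+",              MED, POS, NLO, NLO, HI),
    R("CD56dim NKG2A-NKG2C-CD57-",  MED, POS, NLO, NLO, NLO),
    # dysfunctional: low CD56 or low CD16
    R("CD56neg CD16+NKG2A+",        NLO, POS, POS, ANY, NLO),
    R("CD56neg CD16+CD57+",         NLO, POS, NLO, ANY, POS),
    R("CD56neg CD16+",              NLO, POS, NLO, ANY, NLO),
    R("CD56dim CD16low",            MED, NLO, NLO, NLO, NLO)
  )
  structure(rules, class = "nk_annotation_rules")
}

#' Annotate metaclusters as named NK populations
#'
#' Each retained metacluster gets the population name of the first rule all
#' of whose per-marker interval predicates contain its mean signature
#' (intervals are closed below, open above). Several metaclusters may share
#' a name; they are pooled downstream. A signature matching no rule is
#' named `"unclassified"`.
#'
#' @param metaclusters An `nk_metaclusters`.
#' @param rules An `nk_annotation_rules` (default
#'   [default_annotation_rules()]).
#' @return The table with the `population` column filled for retained rows.
#' @export
annotate <- function(metaclusters, rules = default_annotation_rules()) {
  markers <- attr(metaclusters, "markers")
  sig <- as.matrix(metaclusters[, markers, drop = FALSE])
  metaclusters$population <- vapply(seq_len(nrow(sig)), function(i) {
    if (!metaclusters$retained[i]) return(NA_character_)
    .match_rule(sig[i, ], rules)
  }, character(1))
  metaclusters
}

.match_rule <- function(signature, rules) {
  for (r in rules) {
    ok <- TRUE
    for (m in names(r$predicates)) {
      iv <- r$predicates[[m]]
      v <- signature[[m]]
      if (is.na(v) || v < iv[1] || v >= iv[2]) { ok <- FALSE; break }
    }
    if (ok) return(r$population)
  }
  "unclassified"
}

#' Classify a single signature
#'
#' @param signature Named numeric vector of rescaled marker values.
#' @param rules Annotation rules.
#' @return Population name or `"unclassified"`.
#' @export
annotate_signature <- function(signature, rules = default_annotation_rules()) {
  .match_rule(as.list(signature), rules)
}

#' Export a dendrogram as Newick
#'
#' Branch lengths derive from the merge heights (via [ape::as.phylo()]).
#'
#' @param dendrogram An [stats::hclust].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(dendrogram, path) {
  ape::write.tree(ape::as.phylo(dendrogram), file = path)
  invisible(path)
}

#' Export rescaled centers as a MeV-style expression table
#'
#' Tab-delimited text: one row per pooled cluster (keyed
#' `sample_id:cluster_id`), one column per marker.
#'
#' @param rescaled An `nk_rescaled`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mev_table <- function(rescaled, path) {
  df <- data.frame(id = rownames(rescaled$scaled), rescaled$scaled,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
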