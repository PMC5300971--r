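#' Marker panel for the NK maturation pipeline
#'
#' A marker panel names the five NK phenotyping channels (in fixed order),
#' the dump channels used to exclude T cells, monocytes and B cells, and the
#' viability channel. All event matrices handled by the pipeline carry these
#' channels.
#'
#' @param nk_markers Character vector of exactly five NK channel names, in
#'   the canonical order CD56, CD16, NKG2A, NKG2C, CD57.
#' @param dump_markers Character vector of dump channel names.
#' @param viability_marker Single viability channel name.
#'
#' @return An object of class `nk_panel`: a list with elements `nk_markers`,
#'   `dump_markers`, `viability_marker`.
#' @export
#' @examples
#' nk_panel()
nk_panel <- function(nk_markers = c("CD56", "CD16", "NKG2A", "NKG2C", "CD57"),
                     dump_markers = c("CD3", "CD14", "CD19"),
                     viability_marker = "LiveDead") {
  nk_markers <- as.character(nk_markers)
  dump_markers <- as.character(dump_markers)
  viability_marker <- as.character(viability_marker)
  if (length(nk_markers) != 5L) {
    stop("a marker panel needs exactly 5 NK markers, got ", length(nk_markers))
  }
  all_names <- c(nk_markers, dump_markers, viability_marker)
  if (anyDuplicated(all_names)) {
    stop("panel channel names must be unique: ",
         paste(unique(all_names[duplicated(all_names)]), collapse = ", "))
  }
  structure(
    list(nk_markers = nk_markers,
         dump_markers = dump_markers,
         viability_marker = viability_marker),
    class = "nk_panel"
  )
}

#' @export
print.nk_panel <- function(x, ...) {
  cat("NK marker panel\n")
  cat("  NK markers: ", paste(x$nk_markers, collapse = ", "), "\n", sep = "")
  cat("  dump:       ", paste(x$dump_markers, collapse = ", "), "\n", sep = "")
  cat("  viability:  ", x$viability_marker, "\n", sep = "")
  invisible(x)
}

#' All channels of a panel
#'
#' @param panel An [nk_panel()].
#' @return Character vector of all channel names (NK, dump, viability).
#' @export
panel_channels <- function(panel) {
  stopifnot(inherits(panel, "nk_panel"))
  c(panel$nk_markers, panel$dump_markers, panel$viability_marker)
}

# Transformed-intensity grid the expression levels map to. The generator and
# the default annotation rules share this vocabulary; means must be strictly
# increasing in the level order.
.nk_level_grid <- c(neg = 0, low = 1, dim = 2.5, bright = 4, high = 4)

#' Expression levels recognised by the pipeline
#'
#' Levels map monotonically to transformed-intensity means
#' (`neg` = 0, `low` = 1, `dim` = 2.5, `bright`/`high` = 4 by default).
#'
#' @return Named numeric vector mapping level names to default means.
#' @export
nk_level_grid <- function() .nk_level_grid

#' Define an NK phenotype
#'
#' A phenotype is a named marker signature: an expression level per NK
#' marker, plus the transformed-scale mean and standard deviation used when
#' events are simulated from it.
#'
#' @param name Population label.
#' @param levels Named character vector, one level per NK marker, values in
#'   `c("neg", "low", "dim", "bright", "high")`.
#' @param panel An [nk_panel()].
#' @param means Optional named numeric vector of per-marker means; defaults
#'   to the level grid.
#' @param sds Per-marker standard deviations (recycled); must be positive.
#'
#' @return An object of class `nk_phenotype`.
#' @export
nk_phenotype <- function(name, levels, panel = nk_panel(),
                         means = NULL, sds = 0.3) {
  markers <- panel$nk_markers
  if (!all(markers %in% names(levels))) {
    stop("phenotype '", name, "' is missing levels for: ",
         paste(setdiff(markers, names(levels)), collapse = ", "))
  }
  levels <- levels[markers]
  bad <- setdiff(levels, names(.nk_level_grid))
  if (length(bad)) stop("unknown expression level(s): ", paste(bad, collapse = ", "))
  if (is.null(means)) {
    means <- .nk_level_grid[levels]
    names(means) <- markers
  } else {
    if (!all(markers %in% names(means))) stop("means must cover all NK markers")
    means <- means[markers]
  }
  sds <- rep_len(sds, length(markers))
  names(sds) <- markers
  if (any(sds <= 0)) stop("per-marker sds must be > 0")
  structure(
    list(name = name, levels = levels, means = means, sds = sds),
    class = "nk_phenotype"
  )
}

#' @export
print.nk_phenotype <- function(x, ...) {
  cat("NK phenotype:", x$name, "\n")
  print(data.frame(level = x$levels, mean = x$means, sd = x$sds))
  invisible(x)
}

#' Default NK maturation phenotypes
#'
#' The thirteen NK populations the pipeline annotates: two CD56bright
#' variants (progenitors), seven CD56dim variants spanning the
#' NKG2A/NKG2C/CD57 maturation combinations, and four CD56neg/CD16low
#' "dysfunctional" variants described in HIV infection. Every pair of
#' phenotypes is separated by at least one full level step (>= 3 default
#' standard deviations) on at least one marker, so the populations are
#' recoverable by clustering.
#'
#' @param panel An [nk_panel()].
#' @param sds Per-marker event-level standard deviation(s) on the
#'   transformed scale (default 0.3).
#' @return Named list of thirteen [nk_phenotype()] objects.
#' @export
#' @examples
#' names(build_default_phenotypes())
build_default_phenotypes <- function(panel = nk_panel(), sds = 0.3) {
  L <- function(cd56, cd16, nkg2a, nkg2c, cd57) {
    stats::setNames(c(cd56, cd16, nkg2a, nkg2c, cd57), panel$nk_markers)
  }
  defs <- list(
    # progenitors: highest CD56 and NKG2A, no/low CD16
    "CD56bright"                  = L("bright", "neg",  "high", "neg",  "neg"),
    "CD56bright CD16low"          = L("bright", "low",  "high", "neg",  "neg"),
    # CD56dim effector pool, NKG2A/NKG2C/CD57 combinations
    "CD56dim NKG2A+"              = L("dim",    "high", "high", "neg",  "neg"),
    "CD56dim NKG2A+NKG2C+"        = L("dim",    "high", "high", "high", "neg"),
    "CD56dim NKG2A-NKG2C-CD57-"   = L("dim",    "high", "neg",  "neg",  "neg"),
    "CD56dim NKG2C+"              = L("dim",    "high", "neg",  "high", "neg"),
    "CD56dim CD57+"               = L("dim",    "high", "neg",  "neg",  "high"),
    "CD56dim NKG2C+CD57+"         = L("dim",    "high", "neg",  "high", "high"),
    "CD56dim NKG2A+CD57+"         = L("dim",    "high", "high", "neg",  "high"),
    # dysfunctional variants: low CD56 or low CD16
    "CD56neg CD16+NKG2A+"         = L("neg",    "high", "high", "neg",  "neg"),
    "CD56neg CD16+CD57+"          = L("neg",    "high", "neg",  "neg",  "high"),
    "CD56neg CD16+"               = L("neg",    "high", "neg",  "neg",  "neg"),
    "CD56dim CD16low"             = L("dim",    "low",  "neg",  "neg",  "neg")
  )
  out <- lapply(names(defs), function(nm) {
    nk_phenotype(nm, defs[[nm]], panel = panel, sds = sds)
  })
  names(out) <- names(defs)
  out
}

#' Check level-to-mean monotonicity across a phenotype set
#'
#' For every marker, the per-phenotype means must be non-decreasing in the
#' level order neg < low < dim < bright/high. Called before simulation so a
#' mis-specified custom phenotype set fails early.
#'
#' @param phenotypes List of [nk_phenotype()] objects.
#' @return Invisibly `TRUE`; errors on violation.
#' @keywords internal
check_phenotype_monotonicity <- function(phenotypes) {
  markers <- names(phenotypes[[1]]$means)
  rank_of <- c(neg = 1, low = 2, dim = 3, bright = 4, high = 4)
  for (m in markers) {
    lv <- vapply(phenotypes, function(p) rank_of[[p$levels[[m]]]], numeric(1))
    mu <- vapply(phenotypes, function(p) p$means[[m]], numeric(1))
    ord <- order(lv, mu)
    if (is.unsorted(mu[ord])) {
      stop("levels do not map monotonically to means on marker ", m)
    }
  }
  invisible(TRUE)
}

#' Phenotype signature matrix
#'
#' @param phenotypes List of [nk_phenotype()] objects.
#' @return Numeric matrix (phenotypes x markers) of transformed-scale means.
#' @export
phenotype_means <- function(phenotypes) {
  m <- t(vapply(phenotypes, function(p) p$means,
                numeric(length(phenotypes[[1]]$means))))
  rownames(m) <- vapply(phenotypes, function(p) p$name, character(1))
  m
}
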