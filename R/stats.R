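# Rank-based group comparisons. Mid-ranks are used throughout; the
# Kruskal-Wallis statistic carries the tie-correction factor
# 1 - sum(t^3 - t) / (N^3 - N) and Dunn's pairwise z uses the matching tie
# term. Only large-sample approximations (chi-square, normal, t) are
# provided; with very small groups the p-values are approximate.

.tie_sizes <- function(r) {
  t <- table(r)
  as.numeric(t[t > 1])
}

#' Tie-corrected Kruskal-Wallis test
#'
#' `H = [12 / (N (N + 1)) * sum(R_g^2 / n_g) - 3 (N + 1)] / C` with
#' mid-ranks, rank sums `R_g` and tie correction
#' `C = 1 - sum(t^3 - t) / (N^3 - N)`; the p-value comes from the
#' chi-square distribution with `k - 1` degrees of freedom. When every
#' value is identical the statistic is 0 and p = 1.
#'
#' @param groups List of (>= 2) non-empty numeric vectors.
#' @return Object of class `nk_rank_test`: list with `statistic`, `df`,
#'   `p_value`, `mean_ranks`, `tie_correction`, `group_labels`, `n`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(!vapply(groups, length, integer(1)))) stop("groups must be non-empty")
  labels <- names(groups)
  if (is.null(labels)) labels <- paste0("g", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), vapply(groups, length, integer(1)))
  N <- length(x)
  r <- rank(x) # mid-ranks
  ties <- .tie_sizes(r)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (C <= 0) { # every value identical
    res <- list(statistic = 0, df = length(groups) - 1L, p_value = 1,
                mean_ranks = stats::setNames(as.numeric(tapply(r, g, mean)),
                                             labels),
                tie_correction = 0,
                group_labels = labels, n = tabulate(g))
    class(res) <- "nk_rank_test"
    return(res)
  }
  Rg <- tapply(r, g, sum)
  ng <- tabulate(g)
  H <- (12 / (N * (N + 1)) * sum(Rg^2 / ng) - 3 * (N + 1)) / C
  H <- max(H, 0)
  res <- list(statistic = H, df = length(groups) - 1L,
              p_value = stats::pchisq(H, length(groups) - 1L,
                                      lower.tail = FALSE),
              mean_ranks = stats::setNames(as.numeric(Rg / ng), labels),
              tie_correction = C,
              group_labels = labels, n = ng)
  class(res) <- "nk_rank_test"
  res
}

#' @export
print.nk_rank_test <- function(x, ...) {
  cat("Kruskal-Wallis: H = ", format(x$statistic), ", df = ", x$df,
      ", p = ", format.pval(x$p_value), "\n", sep = "")
  invisible(x)
}

#' Significance stars at the 0.05 / 0.01 / 0.001 thresholds
#'
#' @param p Numeric vector of p-values.
#' @return Character vector: `***` below 0.001, `**` below 0.01, `*` below
#'   0.05, empty otherwise.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Dunn's multiple-comparison post-hoc test
#'
#' Pairwise z statistics on the joint mid-ranks:
#' `z_ij = (Rbar_i - Rbar_j) / sqrt((N (N + 1) / 12 - T) (1/n_i + 1/n_j))`
#' with tie term `T = sum(t^3 - t) / (12 (N - 1))`; two-sided normal
#' p-values, Bonferroni-adjusted over all `k (k - 1) / 2` pairs by default.
#' Stars follow the 0.05 / 0.01 / 0.001 convention.
#'
#' @param groups List of (>= 2) numeric vectors.
#' @param adjustment `"bonferroni"` (default) or `"none"`.
#' @return Data.frame of class `nk_dunn`: one row per pair with `group_i`,
#'   `group_j`, `z`, `p_raw`, `p_adjusted`, `stars`, `low_power` (TRUE when
#'   a singleton group is involved).
#' @export
dunn_posttest <- function(groups, adjustment = c("bonferroni", "none")) {
  adjustment <- match.arg(adjustment)
  if (length(groups) < 2) stop("need at least 2 groups")
  labels <- names(groups)
  if (is.null(labels)) labels <- paste0("g", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), vapply(groups, length, integer(1)))
  N <- length(x)
  r <- rank(x)
  ties <- .tie_sizes(r)
  tie_term <- if (N > 1) sum(ties^3 - ties) / (12 * (N - 1)) else 0
  Rbar <- tapply(r, g, mean)
  ng <- tabulate(g)
  k <- length(groups)
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(idx) {
    i <- pairs[1, idx]; j <- pairs[2, idx]
    se2 <- (N * (N + 1) / 12 - tie_term) * (1 / ng[i] + 1 / ng[j])
    z <- if (se2 > 0) (Rbar[i] - Rbar[j]) / sqrt(se2) else 0
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(group_i = labels[i], group_j = labels[j], z = unname(z),
               p_raw = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- if (adjustment == "bonferroni") pmin(1, out$p_raw * m) else out$p_raw
  out$stars <- significance_stars(out$p_adjusted)
  out$low_power <- ng[pairs[1, ]] < 2 | ng[pairs[2, ]] < 2
  class(out) <- c("nk_dunn", "data.frame")
  out
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (tie-safe); the p-value uses the
#' t approximation `t = rho sqrt((n - 2) / (1 - rho^2))` with `n - 2`
#' degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Object of class `nk_correlation`: list with `rho`, `p_value`,
#'   `n`, `method`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("zero rank variance: correlation undefined")
    return(structure(list(rho = NA_real_, p_value = NA_real_, n = n,
                          method = "spearman"), class = "nk_correlation"))
  }
  rho <- stats::cor(rx, ry)
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  structure(list(rho = rho, p_value = p, n = n, method = "spearman"),
            class = "nk_correlation")
}

#' Simple linear regression
#'
#' Ordinary least squares of `y` on `x` (via [stats::lm()]), reporting
#' slope, intercept, r-squared and the slope's p-value.
#'
#' @param x,y Numeric vectors, length >= 3, `var(x) > 0`.
#' @return Object of class `nk_correlation`: list with `slope`,
#'   `intercept`, `r_squared`, `p_value`, `n`.
#' @export
linear_regression <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::var(x) == 0) stop("var(x) = 0: slope undefined")
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = s$r.squared,
                 p_value = unname(s$coefficients[2, 4]),
                 n = length(x), method = "linear_regression"),
            class = "nk_correlation")
}

#' @export
print.nk_correlation <- function(x, ...) {
  if (x$method == "spearman") {
    cat("Spearman rho = ", format(x$rho), ", p = ", format.pval(x$p_value),
        ", n = ", x$n, "\n", sep = "")
  } else {
    cat("Linear regression: slope = ", format(x$slope), ", intercept = ",
        format(x$intercept), ", r^2 = ", format(x$r_squared), ", p = ",
        format.pval(x$p_value), ", n = ", x$n, "\n", sep = "")
  }
  invisible(x)
}

#' Group comparison report
#'
#' For every population frequency and metadata variable: per-group medians
#' and interquartile ranges, the Kruskal-Wallis p-value, and Dunn's pairwise
#' adjusted p-values with significance stars. Variables with no data in any
#' group are skipped with a warning.
#'
#' @param freq Frequency matrix (rows = samples), or `NULL`.
#' @param metadata Data.frame with `sample_id` and numeric variables, or
#'   `NULL`.
#' @param grouping An `nk_grouping` or named vector sample_id -> label.
#' @param variables Metadata columns to analyze (default: the numeric ones).
#' @return Data.frame of class `nk_group_report`: one row per variable with
#'   per-group `median_<label>` / `iqr_<label>` columns, `kw_p`, and one
#'   `dunn_<i>_<j>` adjusted p-value (with stars) per pair.
#' @export
group_report <- function(freq = NULL, metadata = NULL, grouping,
                         variables = NULL) {
  if (inherits(grouping, "nk_grouping")) {
    a <- grouping$assignments
    grouping <- stats::setNames(a$label, a$sample_id)
  }
  tabs <- list()
  if (!is.null(freq)) {
    f <- as.data.frame(unclass(freq))
    f$sample_id <- rownames(freq)
    tabs$freq <- f
  }
  if (!is.null(metadata)) {
    md <- metadata
    if (is.null(variables)) {
      variables <- setdiff(names(md)[vapply(md, is.numeric, logical(1))],
                           c("sample_id"))
    }
    tabs$meta <- md[, c("sample_id", variables), drop = FALSE]
  }
  if (!length(tabs)) stop("nothing to report on")
  labels <- sort(unique(unname(grouping)))
  rows <- list()
  for (tab in tabs) {
    vars <- setdiff(names(tab), "sample_id")
    keep <- tab$sample_id %in% names(grouping)
    tab <- tab[keep, , drop = FALSE]
    glab <- unname(grouping[tab$sample_id])
    for (v in vars) {
      vals <- tab[[v]]
      grps <- lapply(labels, function(l) vals[glab == l & is.finite(vals)])
      names(grps) <- labels
      if (all(vapply(grps, length, integer(1)) == 0)) {
        warning("variable ", v, " has no data in any group; skipped")
        next
      }
      if (any(vapply(grps, length, integer(1)) == 0)) {
        warning("variable ", v, " missing in some group(s); skipped")
        next
      }
      kw <- kruskal_wallis(grps)
      dn <- dunn_posttest(grps)
      row <- data.frame(variable = v, stringsAsFactors = FALSE)
      for (l in labels) {
        row[[paste0("median_", l)]] <- stats::median(grps[[l]])
        row[[paste0("iqr_", l)]] <- stats::IQR(grps[[l]])
      }
      row$kw_p <- kw$p_value
      row$kw_stars <- significance_stars(kw$p_value)
      for (i in seq_len(nrow(dn))) {
        key <- paste0("dunn_", dn$group_i[i], "_", dn$group_j[i])
        row[[key]] <- dn$p_adjusted[i]
        row[[paste0(key, "_stars")]] <- dn$stars[i]
      }
      rows[[paste0(v)]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("nk_group_report", "data.frame")
  out
}

#' Write a group report as tab-delimited text
#'
#' @param report An `nk_group_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_group_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
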