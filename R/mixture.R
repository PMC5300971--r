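#' Options for mixture fitting
#'
#' @param family `"gaussian"` (full-covariance Gaussian components, the
#'   default) or `"student"` (multivariate Student-t with fixed degrees of
#'   freedom `dof`, the heavier-tailed model traditional in cytometry).
#' @param max_iter Maximum EM iterations.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param n_init Number of k-means++ restarts; the restart with the best
#'   final log-likelihood wins.
#' @param seed Integer seed; fixes initialization so fits are reproducible.
#' @param reg Covariance ridge: `reg * trace(S)/d` is added to the diagonal
#'   of every component covariance.
#' @param dof Student-t degrees of freedom (used when `family = "student"`).
#' @return A list of class `nk_mix_opts`.
#' @export
mixture_opts <- function(family = c("gaussian", "student"), max_iter = 100,
                         tol = 1e-6, n_init = 3, seed = 1, reg = 1e-6,
                         dof = 4) {
  family <- match.arg(family)
  structure(list(family = family, max_iter = as.integer(max_iter), tol = tol,
                 n_init = as.integer(n_init), seed = as.integer(seed),
                 reg = reg, dof = dof),
            class = "nk_mix_opts")
}

# condition used to signal a per-sample fit failure
.fit_failure <- function(msg, sample_id = NA_character_) {
  structure(class = c("nk_fit_failure", "error", "condition"),
            list(message = paste0(msg, if (!is.na(sample_id))
      paste0(" [sample ", sample_id, "]") else ""),
      call = NULL, sample_id = sample_id))
}

# log density of N(mu, Sigma) rows of x, via Cholesky; ridge escalates until
# the factorization succeeds
.chol_safe <- function(S, ridge) {
  d <- ncol(S)
  for (i in 0:8) {
    R <- tryCatch(chol(S + (ridge * 10^i) * diag(d)), error = function(e) NULL)
    if (!is.null(R)) return(R)
  }
  NULL
}

.logdens_gauss <- function(x, mu, R) {
  # R: upper Cholesky factor of Sigma
  xc <- sweep(x, 2L, mu)
  y <- backsolve(R, t(xc), transpose = TRUE)
  q <- colSums(y * y)
  -0.5 * (ncol(x) * log(2 * pi) + q) - sum(log(diag(R)))
}

.logdens_student <- function(x, mu, R, nu) {
  d <- ncol(x)
  xc <- sweep(x, 2L, mu)
  y <- backsolve(R, t(xc), transpose = TRUE)
  q <- colSums(y * y)
  lgamma((nu + d) / 2) - lgamma(nu / 2) - (d / 2) * log(nu * pi) -
    sum(log(diag(R))) - ((nu + d) / 2) * log1p(q / nu)
}

# seeded k-means++ center selection
.kmeanspp <- function(x, K) {
  n <- nrow(x)
  centers <- matrix(NA_real_, K, ncol(x))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- x[idx, ]
  d2 <- rowSums(sweep(x, 2L, centers[1L, ])^2)
  if (K > 1L) for (k in 2:K) {
    p <- d2 / sum(d2)
    if (!all(is.finite(p)) || sum(d2) == 0) {
      idx <- sample.int(n, 1L)
    } else {
      idx <- sample.int(n, 1L, prob = p)
    }
    centers[k, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2L, centers[k, ])^2))
  }
  centers
}

.init_from_centers <- function(x, centers) {
  K <- nrow(centers)
  # hard-assign to nearest center, then moment estimates per component
  d2 <- vapply(seq_len(K), function(k) rowSums(sweep(x, 2L, centers[k, ])^2),
               numeric(nrow(x)))
  lab <- max.col(-d2, ties.method = "first")
  .moment_params(x, lab, K)
}

.moment_params <- function(x, lab, K) {
  n <- nrow(x); d <- ncol(x)
  gvar <- stats::var(as.vector(x))
  means <- matrix(0, K, d)
  covs <- array(0, c(K, d, d))
  w <- numeric(K)
  for (k in seq_len(K)) {
    idx <- which(lab == k)
    w[k] <- max(length(idx), 0.5) / n
    if (length(idx) == 0L) {
      means[k, ] <- x[sample.int(n, 1L), ]
      covs[k, , ] <- gvar * diag(d)
    } else {
      means[k, ] <- colMeans(x[idx, , drop = FALSE])
      cv <- if (length(idx) > d) stats::cov(x[idx, , drop = FALSE]) else gvar * diag(d)
      covs[k, , ] <- cv
    }
  }
  list(weights = w / sum(w), means = means, covariances = covs)
}

# one EM run from explicit starting parameters; returns model or NULL-ish
# failure record
.em_run <- function(x, K, params, opts) {
  n <- nrow(x); d <- ncol(x)
  w <- params$weights; mu <- params$means; S <- params$covariances
  trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  z <- NULL
  for (it in seq_len(opts$max_iter)) {
    # E step
    ld <- matrix(0, n, K)
    for (k in seq_len(K)) {
      Sk <- S[k, , , drop = TRUE]
      if (d == 1L) Sk <- matrix(Sk, 1, 1)
      ridge <- opts$reg * sum(diag(Sk)) / d + 1e-12
      R <- .chol_safe(Sk, ridge)
      if (is.null(R)) return(list(failed = TRUE, reason = "singular covariance"))
      ld[, k] <- log(w[k]) + if (opts$family == "gaussian") {
        .logdens_gauss(x, mu[k, ], R)
      } else {
        .logdens_student(x, mu[k, ], R, opts$dof)
      }
    }
    mx <- ld[cbind(seq_len(n), max.col(ld, ties.method = "first"))]
    lse <- mx + log(rowSums(exp(ld - mx)))
    ll <- sum(lse)
    if (!is.finite(ll)) return(list(failed = TRUE, reason = "non-finite likelihood"))
    trace <- c(trace, ll)
    z <- exp(ld - lse)
    if (opts$family == "student") {
      # ECM weights: expected scale factors given current parameters
      u <- matrix(0, n, K)
      for (k in seq_len(K)) {
        Sk <- S[k, , , drop = TRUE]
        if (d == 1L) Sk <- matrix(Sk, 1, 1)
        R <- .chol_safe(Sk, opts$reg * sum(diag(Sk)) / d + 1e-12)
        xc <- sweep(x, 2L, mu[k, ])
        y <- backsolve(R, t(xc), transpose = TRUE)
        u[, k] <- (opts$dof + d) / (opts$dof + colSums(y * y))
      }
    }
    if (is.finite(ll_prev) && abs(ll - ll_prev) < opts$tol * (1 + abs(ll))) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
    # M step
    zw <- if (opts$family == "student") z * u else z
    Nk <- colSums(z)
    if (any(Nk < 1 / 10)) return(list(failed = TRUE, reason = "component collapse"))
    w <- Nk / n
    denom <- colSums(zw)
    mu <- t(zw) %*% x / denom
    for (k in seq_len(K)) {
      xc <- sweep(x, 2L, mu[k, ])
      Sk <- crossprod(xc * zw[, k], xc) / Nk[k]
      ridge <- opts$reg * sum(diag(Sk)) / d + 1e-12
      S[k, , ] <- Sk + ridge * diag(d)
    }
  }
  list(failed = FALSE, weights = w, means = mu, covariances = S,
       loglik = trace[length(trace)], loglik_trace = trace,
       converged = converged, responsibilities = z)
}

# post-fit failure screen per the pipeline's failure definition
.screen_model <- function(fit, n, d) {
  if (fit$failed) return(fit$reason)
  if (!is.finite(fit$loglik)) return("non-finite likelihood")
  if (min(fit$weights) < 1 / (10 * n)) return("degenerate component weight")
  for (k in seq_len(nrow(fit$means))) {
    ev <- eigen(fit$covariances[k, , ], symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0 || max(ev) / min(ev) > 1e12) return("ill-conditioned covariance")
  }
  NULL
}

#' Fit a finite mixture model to gated events
#'
#' EM with seeded k-means++ initialization and `n_init` restarts; the
#' restart with the highest final log-likelihood is returned. Components are
#' full-covariance Gaussians (or Student-t with fixed degrees of freedom).
#' A fit fails when all restarts end with a non-finite likelihood, a
#' component weight below `1/(10n)`, or a covariance condition number above
#' 1e12; failure raises a condition of class `nk_fit_failure`.
#'
#' @param x An [event_matrix()] or numeric matrix (rows = events).
#' @param K Number of components (`1 <= K <= nrow(x)`).
#' @param opts An [mixture_opts()].
#' @param markers Columns to cluster on (default: all columns of `x`).
#' @param init_params Optional explicit starting parameters (list with
#'   `weights`, `means`, `covariances`); overrides the seeded restarts.
#' @return An object of class `nk_mixture`: list with `K`, `weights`,
#'   `means`, `covariances`, `family`, `loglik`, `loglik_trace`,
#'   `converged`, `n`, `markers`.
#' @export
fit_mixture <- function(x, K, opts = mixture_opts(), markers = NULL,
                        init_params = NULL) {
  sid <- if (inherits(x, "nk_events")) attr(x, "sample_id") else NA_character_
  m <- unclass(x)
  if (!is.null(markers)) m <- m[, markers, drop = FALSE]
  storage.mode(m) <- "double"
  n <- nrow(m); d <- ncol(m)
  if (K < 1) stop("K must be >= 1")
  if (n < K) stop(.fit_failure(paste0("fewer events (", n, ") than components (",
                                      K, ")"), sid))
  if (K == 1L && opts$family == "gaussian") {
    mu <- colMeans(m)
    S <- array(0, c(1, d, d))
    Sk <- stats::cov(m) * (n - 1) / n
    if (n == 1L) Sk <- diag(d) * 0
    ridge <- opts$reg * max(sum(diag(Sk)) / d, 1e-8)
    S[1, , ] <- Sk + ridge * diag(d)
    R <- .chol_safe(S[1, , ], 1e-10)
    ll <- sum(.logdens_gauss(m, mu, R))
    return(structure(list(K = 1L, weights = 1, means = matrix(mu, 1, d,
                          dimnames = list(NULL, colnames(m))),
                          covariances = S, family = opts$family, dof = opts$dof,
                          loglik = ll, loglik_trace = ll, converged = TRUE,
                          n = n, markers = colnames(m), sample_id = sid),
                     class = "nk_mixture"))
  }
  run_one <- function(params) .em_run(m, K, params, opts)
  fits <- list()
  if (!is.null(init_params)) {
    fits[[1]] <- run_one(init_params)
  } else {
    for (i in seq_len(opts$n_init)) {
      params <- withr::with_seed(opts$seed + i - 1L, {
        if (K == 1L) .moment_params(m, rep(1L, n), 1L)
        else .init_from_centers(m, .kmeanspp(m, K))
      })
      fits[[i]] <- run_one(params)
    }
  }
  reasons <- vapply(fits, function(f) {
    r <- .screen_model(f, n, d)
    if (is.null(r)) NA_character_ else r
  }, character(1))
  ok <- which(is.na(reasons))
  if (!length(ok)) {
    stop(.fit_failure(paste0("all restarts degenerate (",
                             paste(unique(reasons), collapse = "; "), ")"), sid))
  }
  best <- ok[which.max(vapply(fits[ok], `[[`, numeric(1), "loglik"))]
  fit <- fits[[best]]
  structure(list(K = as.integer(K), weights = fit$weights,
                 means = `colnames<-`(fit$means, colnames(m)),
                 covariances = fit$covariances, family = opts$family,
                 dof = opts$dof, loglik = fit$loglik,
                 loglik_trace = fit$loglik_trace, converged = fit$converged,
                 n = n, markers = colnames(m), sample_id = sid),
            class = "nk_mixture")
}

#' @export
print.nk_mixture <- function(x, ...) {
  cat("<nk_mixture> K = ", x$K, " (", x$family, "), n = ", x$n,
      ", loglik = ", format(x$loglik), ", converged = ", x$converged,
      "\n", sep = "")
  invisible(x)
}

#' Log-likelihood and posterior responsibilities of events under a model
#' @keywords internal
.posterior <- function(model, m) {
  n <- nrow(m); K <- model$K; d <- ncol(m)
  ld <- matrix(0, n, K)
  for (k in seq_len(K)) {
    Sk <- model$covariances[k, , , drop = TRUE]
    if (d == 1L) Sk <- matrix(Sk, 1, 1)
    R <- .chol_safe(Sk, 1e-12)
    ld[, k] <- log(model$weights[k]) + if (model$family == "gaussian") {
      .logdens_gauss(m, model$means[k, ], R)
    } else {
      .logdens_student(m, model$means[k, ], R, model$dof)
    }
  }
  mx <- ld[cbind(seq_len(n), max.col(ld, ties.method = "first"))]
  lse <- mx + log(rowSums(exp(ld - mx)))
  list(logdens = ld, loglik = sum(lse), z = exp(ld - lse))
}

#' Assign events to mixture components
#'
#' Maximum-a-posteriori labels; ties break to the lowest component id.
#'
#' @param model An `nk_mixture` from [fit_mixture()].
#' @param x Events with the channels the model was fitted on.
#' @return Integer vector of component labels in `1:K`.
#' @export
assign_events <- function(model, x) {
  m <- unclass(x)
  if (!all(model$markers %in% colnames(m))) {
    stop("event matrix lacks the model's channels: ",
         paste(setdiff(model$markers, colnames(m)), collapse = ", "))
  }
  m <- m[, model$markers, drop = FALSE]
  post <- .posterior(model, m)
  max.col(post$logdens, ties.method = "first")
}

#' Scan component counts with BIC and ICL
#'
#' Fits the mixture for every K in `K_range` and scores it with BIC
#' (`2 * loglik - p * log(n)`, larger is better) and ICL
#' (`BIC - 2 * assignment entropy`). Failed fits are kept in the table with
#' `converged = FALSE` and excluded from the argmax.
#'
#' @param x Events.
#' @param K_range Integer vector of component counts to scan.
#' @param opts An [mixture_opts()].
#' @param markers Columns to cluster on.
#' @return A data.frame (class `nk_model_selection`) with columns `K`,
#'   `loglik`, `n_params`, `BIC`, `ICL`, `converged`; attributes `best_bic`
#'   and `best_icl` hold the argmax K.
#' @export
select_K <- function(x, K_range, opts = mixture_opts(), markers = NULL) {
  if (!length(K_range)) stop("K_range must be non-empty")
  m <- unclass(x)
  if (!is.null(markers)) m <- m[, markers, drop = FALSE]
  n <- nrow(m); d <- ncol(m)
  rows <- lapply(K_range, function(K) {
    fit <- tryCatch(fit_mixture(m, K, opts), nk_fit_failure = function(e) NULL,
                    error = function(e) NULL)
    if (is.null(fit)) {
      return(data.frame(K = K, loglik = NA_real_, n_params = NA_real_,
                        BIC = NA_real_, ICL = NA_real_, converged = FALSE))
    }
    p <- (K - 1) + K * d + K * d * (d + 1) / 2
    bic <- 2 * fit$loglik - p * log(n)
    z <- .posterior(fit, m)$z
    ent <- -sum(ifelse(z > 0, z * log(z), 0))
    data.frame(K = K, loglik = fit$loglik, n_params = p, BIC = bic,
               ICL = bic - 2 * ent, converged = fit$converged)
  })
  tab <- do.call(rbind, rows)
  ok <- which(tab$converged)
  attr(tab, "best_bic") <- if (length(ok)) tab$K[ok][which.max(tab$BIC[ok])] else NA
  attr(tab, "best_icl") <- if (length(ok)) tab$K[ok][which.max(tab$ICL[ok])] else NA
  class(tab) <- c("nk_model_selection", "data.frame")
  tab
}

#' Cluster every sample of a cohort with a fixed K
#'
#' Per-sample mixture fits; samples whose fit fails are collected in
#' `failed_sample_ids` rather than aborting the run. The returned cluster
#' table has one row per (successful sample, component): sample id, cluster
#' id, the five marker centroid coordinates and the MAP event count.
#'
#' @param samples Named list of gated [event_matrix()] objects.
#' @param K Components per sample.
#' @param opts An [mixture_opts()]; each sample gets a seed derived from
#'   `opts$seed` and its position.
#' @param markers Channels to cluster on (default: the NK markers of
#'   [nk_panel()]).
#' @return List with `cluster_table` (data.frame: `sample_id`, `cluster_id`,
#'   marker centroids, `event_count`), `models` (per-sample `nk_mixture`),
#'   and `failed_sample_ids`.
#' @export
cluster_cohort <- function(samples, K, opts = mixture_opts(),
                           markers = nk_panel()$nk_markers) {
  if (!length(samples)) stop("need at least one sample")
  ids <- names(samples)
  if (is.null(ids)) ids <- paste0("S", seq_along(samples))
  rows <- list()
  models <- list()
  failed <- character(0)
  for (i in seq_along(samples)) {
    sid <- ids[i]
    opts_i <- opts
    opts_i$seed <- opts$seed + 1000L * i
    fit <- tryCatch(
      fit_mixture(samples[[i]], K, opts_i, markers = markers),
      nk_fit_failure = function(e) e,
      error = function(e) e
    )
    if (inherits(fit, "condition")) {
      failed <- c(failed, sid)
      next
    }
    lab <- assign_events(fit, samples[[i]])
    counts <- tabulate(lab, nbins = K)
    df <- data.frame(sample_id = sid, cluster_id = seq_len(K),
                     fit$means, event_count = counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
    rows[[sid]] <- df
    models[[sid]] <- fit
  }
  if (!length(rows)) stop("all samples failed to be computed")
  ct <- do.call(rbind, rows)
  rownames(ct) <- NULL
  list(cluster_table = ct, models = models, failed_sample_ids = failed)
}

#' Write a cluster table
#'
#' Tab-delimited, fixed column order: sample_id, cluster_id, the marker
#' centroids, event_count.
#'
#' @param cluster_table Data.frame from [cluster_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(cluster_table, path) {
  utils::write.table(cluster_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
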