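# Shared fixture builders (all generated in code, deterministic under the
# seeds fixed here).

# two well-separated 5-D Gaussian blobs with truth labels; means are `sep`
# standard deviations apart on every dimension
two_blob_fixture <- function(n_per = 1000, sep = 5, sd = 1, seed = 42) {
  withr::with_seed(seed, {
    d <- 5
    mu1 <- rep(0, d)
    mu2 <- rep(sep * sd, d)
    x <- rbind(
      matrix(stats::rnorm(n_per * d, 0, sd), n_per, d) +
        matrix(mu1, n_per, d, byrow = TRUE),
      matrix(stats::rnorm(n_per * d, 0, sd), n_per, d) +
        matrix(mu2, n_per, d, byrow = TRUE)
    )
    colnames(x) <- paste0("M", 1:d)
    list(x = x, truth = rep(1:2, each = n_per), means = rbind(mu1, mu2))
  })
}

# k tight Gaussian blobs in 2-D for model-selection tests
blobs_fixture <- function(k = 3, n_per = 120, sep = 8, seed = 7) {
  withr::with_seed(seed, {
    centers <- matrix(c(0, 0, sep, 0, 0, sep, sep, sep, -sep, sep),
                      ncol = 2, byrow = TRUE)[seq_len(k), , drop = FALSE]
    x <- do.call(rbind, lapply(seq_len(k), function(i) {
      matrix(stats::rnorm(n_per * 2), n_per, 2) +
        matrix(centers[i, ], n_per, 2, byrow = TRUE)
    }))
    colnames(x) <- c("M1", "M2")
    list(x = x, truth = rep(seq_len(k), each = n_per))
  })
}

# adjusted Rand index between two labelings (independent of any clustering
# code in the package)
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(v) sum(v * (v - 1) / 2)
  sum_ij <- comb2(as.vector(tab))
  sum_a <- comb2(rowSums(tab))
  sum_b <- comb2(colSums(tab))
  n <- length(a)
  expected <- sum_a * sum_b / (n * (n - 1) / 2)
  maxind <- (sum_a + sum_b) / 2
  if (maxind == expected) return(1)
  (sum_ij - expected) / (maxind - expected)
}

# minimal cluster table: `sizes[i]` member clusters per planted metacluster,
# centered on distinct signatures
toy_cluster_table <- function(sizes, signatures, jitter = 0.05, seed = 5,
                              events_per_cluster = 100) {
  stopifnot(length(sizes) == nrow(signatures))
  withr::with_seed(seed, {
    rows <- do.call(rbind, lapply(seq_along(sizes), function(i) {
      m <- matrix(stats::rnorm(sizes[i] * ncol(signatures), 0, jitter),
                  sizes[i], ncol(signatures))
      sweep(m, 2L, signatures[i, ], `+`)
    }))
    colnames(rows) <- colnames(signatures)
    data.frame(sample_id = "S1", cluster_id = seq_len(nrow(rows)), rows,
               event_count = events_per_cluster, check.names = FALSE)
  })
}

# small event matrix drawn from the default phenotypes at given frequencies
toy_sample <- function(freqs, n_events = 1000, contaminant = 0, seed = 11,
                       sample_id = "S1") {
  phen <- build_default_phenotypes()
  f <- stats::setNames(numeric(length(phen)), names(phen))
  f[names(freqs)] <- freqs
  f <- 100 * f / sum(f)
  withr::with_seed(seed, {
    simulate_sample(f, phen, nk_panel(), n_events, contaminant,
                    sample_id = sample_id)
  })
}

# generator-truth gate thresholds for simulated data (dump/viability
# midpoint between the planted negative level 0 and positive level 4)
truth_thresholds <- function(panel = nk_panel()) {
  thr <- rep(2, length(panel$dump_markers) + 1)
  names(thr) <- c(panel$dump_markers, panel$viability_marker)
  c(thr, CD56 = 0.5, CD16 = 0.5)
}
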