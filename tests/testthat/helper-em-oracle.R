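# Naive reference EM for Gaussian mixtures: plain loops, solve()/det()
# densities, no numerical shortcuts. Used as the independent oracle for the
# packaged implementation on small instances. Mirrors the same model
# (full-covariance Gaussian, per-iteration ridge reg * trace(S)/d).

ref_dmvnorm <- function(xi, mu, S) {
  d <- length(mu)
  diff <- xi - mu
  q <- as.numeric(t(diff) %*% solve(S) %*% diff)
  exp(-0.5 * q) / sqrt((2 * pi)^d * det(S))
}

ref_em <- function(x, K, params, max_iter = 500, tol = 1e-12, reg = 1e-6) {
  n <- nrow(x); d <- ncol(x)
  w <- params$weights
  mu <- params$means
  S <- params$covariances
  ll_prev <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- matrix(0, n, K)
    for (i in seq_len(n)) {
      for (k in seq_len(K)) {
        Sk <- matrix(S[k, , ], d, d)
        dens[i, k] <- w[k] * ref_dmvnorm(x[i, ], mu[k, ], Sk)
      }
    }
    rs <- rowSums(dens)
    ll <- sum(log(rs))
    z <- dens / rs
    if (is.finite(ll_prev) && abs(ll - ll_prev) < tol * (1 + abs(ll))) break
    ll_prev <- ll
    Nk <- colSums(z)
    w <- Nk / n
    for (k in seq_len(K)) {
      mu[k, ] <- colSums(z[, k] * x) / Nk[k]
      Sk <- matrix(0, d, d)
      for (i in seq_len(n)) {
        diff <- x[i, ] - mu[k, ]
        Sk <- Sk + z[i, k] * (diff %*% t(diff))
      }
      Sk <- Sk / Nk[k]
      ridge <- reg * sum(diag(Sk)) / d + 1e-12
      S[k, , ] <- Sk + ridge * diag(d)
    }
  }
  list(loglik = ll, weights = w, means = mu, covariances = S)
}
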