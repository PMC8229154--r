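# Small synthetic cohorts and whitened group data used across tests.

tiny_cohort <- function(seed = 1, noise_sd = 0, n_pd = 6, n_ctr = 4, ...) {
  cfg <- cohort_config(n_pd = n_pd, n_ctr = n_ctr, noise_sd = noise_sd, ...)
  simulate_cohort(cfg, seed = seed)
}

group_whiten <- function(cohort, K = cohort$config$n_components,
                         n_keep = K) {
  red <- lapply(cohort$bold, reduce_subject, n_keep = n_keep)
  concat_group_pca(red, K = K)
}

# Orthonormal zero-row-mean spatial maps for exact-identity constructions.
orthonormal_maps <- function(k, v, seed = 1) {
  withr::with_seed(seed, {
    g <- matrix(rnorm(k * v), k, v)
    g <- g - rowMeans(g)
    s <- svd(g)
    maps <- s$u %*% t(s$v) / sqrt(v)        # orthogonal rows, row means ~0
    maps <- maps - rowMeans(maps)
    t(qr.Q(qr(t(maps))))                    # exact orthonormal rows
  })
}

# Independent MDL transcription used as the oracle against mdl_curve().
oracle_mdl <- function(ev, n) {
  p <- length(ev)
  sapply(0:(p - 1), function(k) {
    lam <- ev[(k + 1):p]
    lik <- -n * (p - k) * log(prod(lam^(1 / (p - k))) / (sum(lam) / (p - k)))
    pen <- 0.5 * k * (2 * p - k + 1) * log(n)
    lik + pen
  })
}

# Exhaustive best-subset selection by BIC over subsets of size <= max_size.
best_subset_bic <- function(x, y, max_size = 4) {
  n <- length(y)
  p <- ncol(x)
  sets <- list(integer(0))
  for (sz in seq_len(max_size)) {
    sets <- c(sets, utils::combn(p, sz, simplify = FALSE))
  }
  bics <- vapply(sets, function(s) {
    rss <- sum(stats::.lm.fit(cbind(1, x[, s, drop = FALSE]), y)$residuals^2)
    n * log(rss / n) + (length(s) + 1) * log(n)
  }, numeric(1))
  sets[[which.min(bics)]]
}
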