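test_that("subject PCA is exact on low-rank data and bounded by eigenvalue mass", {
  withr::with_seed(21, {
    v <- 300; nt <- 50
    maps <- matrix(rnorm(3 * v), 3, v)
    tcs <- matrix(rnorm(3 * nt), 3, nt)
    x <- crossprod(maps, tcs)                 # exact rank 3
    red <- reduce_subject(x, 3)
    rec <- red$reduced %*% t(red$basis) + red$row_center
    expect_lt(max(abs(rec - x)) / max(abs(x)), 1e-8)
    expect_error(reduce_subject(x, 4), "rank")

    # full-rank retention is lossless
    y <- x + matrix(rnorm(v * nt, sd = 0.5), v, nt)
    redf <- reduce_subject(y, nt - 1L)
    recf <- redf$reduced %*% t(redf$basis) + redf$row_center
    expect_lt(max(abs(recf - y)), 1e-8)

    # retained energy matches the top-k partial sums of an SVD oracle
    redk <- reduce_subject(y, 10)
    yc <- y - rowMeans(y)
    d2 <- svd(yc, nu = 0, nv = 0)$d^2 / (v - 1)
    expect_equal(colSums(redk$reduced^2) / (v - 1), d2[1:10],
                 tolerance = 1e-8)
    expect_equal(redk$eigenvalues[1:10], d2[1:10], tolerance = 1e-8)
  })
})

test_that("group PCA whitens, back-projects, and matches a dense oracle", {
  co <- tiny_cohort(seed = 22, noise_sd = 0.5, n_pd = 3, n_ctr = 2,
                    grid = c(16, 16, 8), n_components = 4, n_timepoints = 60)
  red <- lapply(co$bold, reduce_subject, n_keep = 6)
  grp <- concat_group_pca(red, K = 4)

  z <- grp$whitened
  expect_equal(rowMeans(z), rep(0, 4), tolerance = 1e-8)
  expect_equal(apply(z, 1, var), rep(1, 4), tolerance = 1e-8)
  # de-whitening composed with whitening is the identity on the subspace
  expect_equal(t(grp$whitening) %*% grp$dewhitening, diag(4),
               tolerance = 1e-8)

  # eigenvalues equal those of the dense pooled covariance
  y <- do.call(cbind, lapply(red, `[[`, "reduced"))
  yc <- sweep(y, 2, colMeans(y))
  ev <- eigen(crossprod(yc) / (nrow(yc) - 1), symmetric = TRUE)$values
  expect_equal(grp$eigenvalues, pmax(ev, 0), tolerance = 1e-6)
})

test_that("noise-free group subspace captures the sources and degenerates correctly", {
  co <- tiny_cohort(seed = 23, noise_sd = 0, n_pd = 3, n_ctr = 2,
                    grid = c(16, 16, 8), n_components = 4, n_timepoints = 60)
  red <- lapply(co$bold, reduce_subject, n_keep = 4)
  grp <- concat_group_pca(red, K = 4)
  ev <- grp$eigenvalues
  expect_gte(sum(ev[1:4]) / sum(ev), 0.99)

  # single subject: group PCA equals that subject's PCA subspace
  one <- concat_group_pca(red[1], K = 4)
  b1 <- red[[1]]$reduced[, 1:4]
  proj <- t(one$whitened) # voxels x 4
  cc <- svd(crossprod(qr.Q(qr(b1)), qr.Q(qr(proj))))$d
  expect_lt(max(abs(cc - 1)), 1e-8)

  # two-stage PCA spans the same space as direct PCA of the concatenation
  xall <- do.call(cbind, lapply(co$bold, function(b) b$data - rowMeans(b$data)))
  direct <- svd(xall, nu = 4, nv = 0)$u
  twostage <- qr.Q(qr(t(grp$whitened)))
  angles <- svd(crossprod(direct, twostage))$d
  expect_lt(max(acos(pmin(angles, 1))), 1e-6)

  expect_error(concat_group_pca(red, K = 1000), "rank")
  bad <- c(red[1], list(matrix(0, 10, 3)))
  expect_error(concat_group_pca(bad, K = 2), "voxel count")
})

test_that("MDL recovers the signal rank and matches an exhaustive oracle", {
  withr::with_seed(24, {
    p <- 20; n <- 10000
    for (k in c(2, 4, 8)) {
      lam <- c(rep(10, k), rep(1, p - k))
      x <- matrix(rnorm(n * p), n, p) %*% diag(sqrt(lam))
      ev <- eigen(crossprod(x) / n, symmetric = TRUE)$values
      est <- estimate_order_mdl(ev, n)
      expect_equal(est, k)
      # exhaustive independent evaluation of the description length
      expect_equal(unname(which.min(oracle_mdl(ev, n))) - 1L, est)
      expect_equal(unname(mdl_curve(ev, n)), oracle_mdl(ev, n),
                   tolerance = 1e-8)
    }
  })
})

test_that("MDL reports no structure for flat or pure-noise spectra", {
  expect_warning(k0 <- estimate_order_mdl(rep(2, 10), 1000), "no detectable")
  expect_equal(k0, 0L)
  withr::with_seed(25, {
    x <- matrix(rnorm(20000 * 12), 20000, 12)
    ev <- eigen(crossprod(x) / 20000, symmetric = TRUE)$values
    expect_warning(k <- estimate_order_mdl(ev, 20000), "no detectable")
    expect_equal(k, 0L)
  })
})

test_that("MDL is invariant to global scaling of the spectrum", {
  withr::with_seed(26, {
    ev <- sort(c(rep(8, 3), rep(1, 9)) * (1 + runif(12, 0, 0.01)),
               decreasing = TRUE)
    expect_equal(estimate_order_mdl(ev, 5000),
                 estimate_order_mdl(ev * 731.4, 5000))
  })
  expect_error(mdl_curve(c(3, 1), 100), "3 distinct")
  expect_error(mdl_curve(c(5, 3, 2, 1), 3), "n_samples")
})
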