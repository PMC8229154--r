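#' Subject-level PCA reduction
#'
#' Voxel-wise demeaning followed by projection onto the top `n_keep`
#' principal time-directions of one subject's BOLD matrix. The stored basis
#' reconstructs the demeaned data up to the discarded eigenvalue mass.
#'
#' @param bold A [masked_bold()] object (or plain voxels x time matrix).
#' @param n_keep Number of temporal principal directions to retain.
#' @return List of class `subject_reduction`: `reduced` (voxels x n_keep),
#'   `basis` (time x n_keep, orthonormal), `eigenvalues` (all, descending),
#'   `row_center` (per-voxel means), `id`.
#' @export
reduce_subject <- function(bold, n_keep) {
  x <- if (inherits(bold, "masked_bold")) bold$data else as.matrix(bold)
  nt <- ncol(x)
  nv <- nrow(x)
  if (!is_count(n_keep) || n_keep < 1 || n_keep > min(nv, nt)) {
    stopf("n_keep must be an integer in [1, min(voxels, timepoints)]")
  }
  ctr <- rowMeans(x)
  xc <- x - ctr
  cv <- crossprod(xc) / (nv - 1)          # temporal covariance, T x T
  eg <- eigen(cv, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  ev[ev < 1e-12 * max(ev)] <- 0
  rank <- sum(ev > 0)
  if (n_keep > rank) {
    stopf("n_keep = %d exceeds data rank %d", n_keep, rank)
  }
  basis <- eg$vectors[, seq_len(n_keep), drop = FALSE]
  structure(list(reduced = xc %*% basis, basis = basis, eigenvalues = ev,
                 row_center = ctr,
                 id = if (inherits(bold, "masked_bold")) bold$id else NULL),
            class = "subject_reduction")
}

#' Group PCA on temporally concatenated subject reductions
#'
#' Subject-reduced matrices are concatenated along the (reduced) time
#' dimension and whitened to `K` dimensions for spatial ICA: the returned
#' whitened matrix is K x voxels with zero-mean, unit-variance rows; voxels
#' are the statistical samples. Whitening and de-whitening transforms are
#' stored, along with each subject's block and temporal basis so component
#' time courses can be reconstructed in native time.
#'
#' @param reductions List of [reduce_subject()] results (or voxels x k
#'   matrices) sharing one mask.
#' @param K Group model order (<= pooled rank).
#' @return List of class `reduced_data`: `whitened` (K x voxels),
#'   `whitening` (pooled x K), `dewhitening` (pooled x K), `eigenvalues`
#'   (pooled covariance spectrum), `n_samples` (number of voxels),
#'   `blocks`, `bases`, `col_center`, `K`, `pooled` (voxels x pooled
#'   demeaned concatenation, kept for bootstrap resampling).
#' @export
concat_group_pca <- function(reductions, K) {
  mats <- lapply(reductions, function(r) {
    if (inherits(r, "subject_reduction")) r$reduced else as.matrix(r)
  })
  nv <- vapply(mats, nrow, integer(1))
  if (length(unique(nv)) != 1L) {
    stopf("subjects disagree on voxel count: %s",
          paste(unique(nv), collapse = ", "))
  }
  v <- nv[1]
  y <- do.call(cbind, mats)
  m <- ncol(y)
  ends <- cumsum(vapply(mats, ncol, integer(1)))
  blocks <- cbind(start = c(1L, utils::head(ends, -1) + 1L), end = ends)
  ctr <- colMeans(y)
  yc <- sweep(y, 2, ctr)
  cv <- crossprod(yc) / (v - 1)
  eg <- eigen(cv, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  ev[ev < 1e-12 * max(ev)] <- 0
  rank <- sum(ev > 0)
  if (!is_count(K) || K < 1 || K > rank) {
    stopf("K = %s exceeds pooled rank %d", format(K), rank)
  }
  ek <- eg$vectors[, seq_len(K), drop = FALSE]
  lk <- ev[seq_len(K)]
  whitening <- sweep(ek, 2, sqrt(lk), "/")        # pooled x K
  dewhitening <- sweep(ek, 2, sqrt(lk), "*")      # pooled x K
  z <- t(yc %*% whitening)                        # K x voxels
  bases <- lapply(reductions, function(r) {
    if (inherits(r, "subject_reduction")) r$basis else NULL
  })
  structure(list(whitened = z, whitening = whitening,
                 dewhitening = dewhitening, eigenvalues = ev,
                 n_samples = v, blocks = blocks, bases = bases,
                 col_center = ctr, K = K, pooled = yc),
            class = "reduced_data")
}

#' MDL curve over candidate model orders
#'
#' Wax-Kailath minimum description length for k latent sources given the
#' eigenvalue spectrum of a sample covariance estimated from `n_samples`
#' observations of p variables:
#' MDL(k) = -(p-k) N log(GM(lambda_(k+1..p)) / AM(lambda_(k+1..p)))
#'          + k (2p - k + 1) / 2 log N.
#'
#' @param eigenvalues Descending nonnegative spectrum (values below
#'   1e-12 of the maximum are clamped to zero and dropped from p).
#' @param n_samples Effective number of samples behind the covariance.
#' @return Numeric vector `MDL(k)` for k = 0 .. p-1 (names give k).
#' @export
mdl_curve <- function(eigenvalues, n_samples) {
  ev <- sort(as.numeric(eigenvalues), decreasing = TRUE)
  ev[ev < 1e-12 * max(ev)] <- 0
  ev <- ev[ev > 0]
  p <- length(ev)
  if (length(unique(ev)) < 3) stopf("need at least 3 distinct eigenvalues")
  if (n_samples <= p) stopf("n_samples (%g) must exceed the number of eigenvalues (%d)",
                            n_samples, p)
  ks <- 0:(p - 1)
  mdl <- vapply(ks, function(k) {
    tail <- ev[(k + 1):p]
    gm_log <- mean(log(tail))
    am <- mean(tail)
    -(p - k) * n_samples * (gm_log - log(am)) +
      0.5 * k * (2 * p - k + 1) * log(n_samples)
  }, numeric(1))
  names(mdl) <- ks
  mdl
}

#' Estimate the number of latent sources by MDL
#'
#' Returns the order k minimizing [mdl_curve()]. A spectrum with no
#' detectable structure (minimum at k = 0, e.g. all eigenvalues equal)
#' returns 0 with a warning. The estimate is invariant to global scaling of
#' the eigenvalues.
#'
#' @inheritParams mdl_curve
#' @return Integer selected order.
#' @export
estimate_order_mdl <- function(eigenvalues, n_samples) {
  ev <- as.numeric(eigenvalues)
  if (max(ev) <= 0 || (max(ev) - min(ev)) < 1e-10 * max(ev)) {
    warnf("degenerate (flat) eigenvalue spectrum: no detectable sources")
    return(0L)
  }
  mdl <- mdl_curve(eigenvalues, n_samples)
  k <- as.integer(names(mdl)[which.min(mdl)])
  if (k == 0L) warnf("MDL found no detectable sources (k = 0)")
  k
}
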