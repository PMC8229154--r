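#' Cluster-quality (Iq) index
#'
#' Stability of one estimate cluster: the mean pairwise similarity inside
#' the cluster (self-pairs excluded) minus the mean similarity between
#' cluster members and all outside estimates. A perfectly tight, perfectly
#' separated cluster scores 1. Conventions: a singleton cluster has intra
#' similarity 1; when the cluster contains every estimate the extra term
#' is 0. Iq is invariant under relabeling of the estimates.
#'
#' @param similarity Symmetric similarity matrix in \[0, 1\] with unit
#'   diagonal.
#' @param members Integer or logical index of the cluster's estimates.
#' @return Scalar Iq in \[-1, 1\].
#' @export
iq_index <- function(similarity, members) {
  s <- as.matrix(similarity)
  n <- nrow(s)
  if (n != ncol(s) || max(abs(s - t(s))) > 1e-8) {
    stopf("similarity must be a symmetric matrix")
  }
  idx <- if (is.logical(members)) which(members) else as.integer(members)
  if (length(idx) == 0L) stopf("cluster is empty")
  if (any(idx < 1 | idx > n)) stopf("member index out of range")
  m <- length(idx)
  intra <- if (m == 1L) 1 else {
    sub <- s[idx, idx]
    (sum(sub) - sum(diag(sub))) / (m * (m - 1))
  }
  out <- setdiff(seq_len(n), idx)
  extra <- if (length(out) == 0L) 0 else mean(s[idx, out, drop = FALSE])
  intra - extra
}

#' ICASSO stability analysis of InfoMax ICA
#'
#' Runs InfoMax `n_runs` times under resampling, pools all component
#' estimates, clusters them by average-linkage agglomeration on the
#' distance 1 - |correlation| (cut at exactly K clusters), and summarizes
#' each cluster by its Iq stability index and its centrotype (the member
#' with maximal total intra-cluster similarity). Components are returned in
#' decreasing Iq order as IC1, IC2, ...
#'
#' Resampling modes: `"bootstrap"` resamples the sample (voxel) dimension
#' of the whitened data with replacement and re-whitens before each run
#' (initial weights still random per run); `"randinit"` reruns on the
#' intact data from fresh random initial weights; `"both"` combines the
#' two; `"none"` repeats the identical run (a degenerate mode in which
#' every cluster has Iq 1, useful only as a self-check).
#'
#' @param reduced A `reduced_data` object (or whitened K x samples matrix).
#' @param n_runs Number of ICA runs (>= 2), canonically 100.
#' @param resample One of `"bootstrap"`, `"randinit"`, `"both"`, `"none"`.
#' @param seed Integer seed controlling all runs.
#' @param ... Passed to [run_infomax()] (`max_iter`, `tol`, `lrate`).
#' @return List of class `icasso_result`: `maps` (K x samples centrotype
#'   estimates, skewness-positive), `iq` (per component), `cluster`
#'   (assignment of each pooled estimate), `similarity`, `centrotypes`
#'   (pooled indices), `n_runs`, `n_converged`, `K`.
#' @export
run_icasso <- function(reduced, n_runs = 100,
                       resample = c("bootstrap", "randinit", "both", "none"),
                       seed = 1, ...) {
  resample <- match.arg(resample)
  z <- if (inherits(reduced, "reduced_data")) reduced$whitened else as.matrix(reduced)
  k <- nrow(z)
  v <- ncol(z)
  if (!is_count(n_runs) || n_runs < 2) stopf("n_runs must be an integer >= 2")
  run_seeds <- if (resample == "none") rep(spawn_seeds(seed, 1), n_runs)
               else spawn_seeds(seed, n_runs)

  runs <- lapply(seq_len(n_runs), function(r) {
    rs <- run_seeds[r]
    if (resample %in% c("bootstrap", "both")) {
      idx <- withr::with_seed(rs + 1, sample.int(v, v, replace = TRUE))
      zb <- z[, idx, drop = FALSE]
      zb <- zb - rowMeans(zb)
      cv <- tcrossprod(zb) / (v - 1)
      eg <- eigen(cv, symmetric = TRUE)
      ev <- pmax(eg$values, 1e-12)
      sph <- sweep(t(eg$vectors), 1, sqrt(ev), "/")   # K x K re-whitening
      fit <- run_infomax(sph %*% zb, seed = rs, ...)
      list(unmixing = fit$unmixing %*% sph, converged = fit$converged)
    } else {
      fit <- run_infomax(z, seed = rs, ...)
      list(unmixing = fit$unmixing, converged = fit$converged)
    }
  })
  ok <- vapply(runs, function(r) r$converged, logical(1))
  if (any(!ok)) {
    warnf("%d of %d ICA runs did not converge and were excluded",
          sum(!ok), n_runs)
  }
  if (sum(ok) < n_runs / 2) {
    stopf("more than half of the ICA runs failed to converge (%d/%d)",
          sum(!ok), n_runs)
  }
  runs <- runs[ok]
  est <- do.call(rbind, lapply(runs, function(r) r$unmixing %*% z))
  run_of <- rep(seq_along(runs), each = k)

  sim <- abs(stats::cor(t(est)))
  sim[!is.finite(sim)] <- 0
  sim <- pmin(pmax((sim + t(sim)) / 2, 0), 1)
  diag(sim) <- 1

  hc <- stats::hclust(stats::as.dist(1 - sim), method = "average")
  cl <- stats::cutree(hc, k = k)

  iq <- vapply(seq_len(k), function(cc) iq_index(sim, cl == cc), numeric(1))
  cts <- vapply(seq_len(k), function(cc) {
    idx <- which(cl == cc)
    idx[which.max(rowSums(sim[idx, idx, drop = FALSE]))]
  }, integer(1))

  ord <- order(iq, decreasing = TRUE)
  maps <- est[cts[ord], , drop = FALSE]
  flip <- vapply(seq_len(k), function(i) {
    if (skewness(maps[i, ]) < 0) -1 else 1
  }, numeric(1))
  maps <- flip * maps
  rownames(maps) <- paste0("IC", seq_len(k))

  structure(list(maps = maps, iq = stats::setNames(iq[ord], rownames(maps)),
                 cluster = cl, similarity = sim, centrotypes = cts[ord],
                 run_of = run_of, n_runs = n_runs, n_converged = sum(ok),
                 K = k),
            class = "icasso_result")
}
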