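#' InfoMax independent component analysis
#'
#' Natural-gradient InfoMax with the logistic nonlinearity on whitened data
#' (rows zero-mean, unit-variance; for group spatial ICA the columns are
#' voxels, i.e. the statistical samples). Weights start from small random
#' Gaussians, the learning rate anneals by 0.9 whenever the update
#' direction reverses, and convergence is declared when the largest
#' absolute weight change over a full data pass drops below `tol`.
#' Super-Gaussian sources (such as compact spatial maps) match the logistic
#' score function. Each returned source map has its sign fixed so that its
#' skewness is nonnegative; the run is fully reproducible from `seed`.
#'
#' @param x Whitened K x samples matrix, or a `reduced_data` object.
#' @param seed Integer seed (weight initialization and sample ordering).
#' @param max_iter Maximum full passes over the data.
#' @param tol Convergence tolerance on the weight change.
#' @param lrate Initial learning rate.
#' @param block Mini-batch size; default `ceiling(sqrt(samples / 3))`.
#' @return List of class `ica_run`: `unmixing` (K x K), `maps`
#'   (K x samples), `converged`, `iterations`, `seed`.
#' @export
run_infomax <- function(x, seed = 1, max_iter = 500, tol = 1e-6,
                        lrate = 0.015, block = NULL) {
  z <- if (inherits(x, "reduced_data")) x$whitened else as.matrix(x)
  k <- nrow(z)
  v <- ncol(z)
  if (k == 1L) {
    s <- sign(skewness(z[1, ]))
    if (s == 0) s <- 1
    return(structure(list(unmixing = matrix(s, 1, 1), maps = s * z,
                          converged = TRUE, iterations = 0L, seed = seed),
                     class = "ica_run"))
  }
  if (is.null(block)) block <- max(8L, ceiling(sqrt(v / 3)))
  withr::with_seed(seed, {
    init_w <- function() diag(k) + matrix(stats::rnorm(k * k, sd = 0.05), k, k)
    w <- init_w()
    lr <- lrate
    d_prev <- NULL
    converged <- FALSE
    iters <- 0L
    restarts <- 0L
    eye <- diag(k)
    for (it in seq_len(max_iter)) {
      iters <- it
      w_old <- w
      perm <- sample.int(v)
      starts <- seq(1L, v, by = block)
      blown <- FALSE
      for (b in starts) {
        idx <- perm[b:min(b + block - 1L, v)]
        u <- w %*% z[, idx, drop = FALSE]
        y <- 1 / (1 + exp(-u))
        w <- w + lr * (eye + ((1 - 2 * y) %*% t(u)) / length(idx)) %*% w
        if (any(!is.finite(w)) || max(abs(w)) > 1e8) { blown <- TRUE; break }
      }
      if (blown) {
        restarts <- restarts + 1L
        if (restarts > 10L) break
        lr <- lr / 2
        w <- init_w()
        d_prev <- NULL
        next
      }
      d <- w - w_old
      if (!is.null(d_prev)) {
        dot <- sum(d * d_prev)
        if (dot < 0) lr <- lr * 0.9
      }
      d_prev <- d
      if (max(abs(d)) < tol) { converged <- TRUE; break }
    }
    # deterministic full-batch polish to the exact fixed point: the block
    # passes get close fast but carry mini-batch noise of order lrate
    if (converged) {
      lr_fb <- lrate
      d_prev <- NULL
      for (it in seq_len(max_iter)) {
        u <- w %*% z
        y <- 1 / (1 + exp(-u))
        d <- lr_fb * (eye + ((1 - 2 * y) %*% t(u)) / v) %*% w
        w_new <- w + d
        if (any(!is.finite(w_new)) || max(abs(w_new)) > 1e8) break
        w <- w_new
        if (!is.null(d_prev) && sum(d * d_prev) < 0) lr_fb <- lr_fb * 0.9
        d_prev <- d
        if (max(abs(d)) < tol) break
      }
    }
    # in whitened space the true unmixing is a rotation: symmetric
    # orthogonalization removes the residual non-orthogonality of the
    # natural-gradient fixed point, so component estimates are exactly
    # decorrelated
    sw <- svd(w)
    w <- sw$u %*% t(sw$v)
    maps <- w %*% z
    flip <- vapply(seq_len(k), function(i) {
      if (skewness(maps[i, ]) < 0) -1 else 1
    }, numeric(1))
    w <- flip * w
    maps <- flip * maps
    structure(list(unmixing = w, maps = maps, converged = converged,
                   iterations = iters, seed = seed),
              class = "ica_run")
  })
}
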