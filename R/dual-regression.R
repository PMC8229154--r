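#' Dual (spatial-temporal) regression back-reconstruction
#'
#' Produces one subject's component time courses and spatial maps from the
#' group-level maps in two least-squares stages. Stage 1 regresses each
#' time point's volume on the group maps (demeaned over voxels), giving the
#' subject time courses; stage 2 regresses each voxel's series on the
#' variance-normalized time courses, giving subject spatial maps whose
#' betas carry amplitude. The subject's BOLD series is demeaned per voxel
#' first; no other detrending is applied.
#'
#' Scaling a group map by c scales its stage-1 time course by 1/c and, with
#' normalization on, leaves the stage-2 maps unchanged.
#'
#' @param bold A [masked_bold()] object (or voxels x time matrix).
#' @param group_maps Components x voxels matrix over the same mask, full
#'   row rank.
#' @param normalize_timecourses Variance-normalize the stage-1 time courses
#'   before stage 2 (the usual convention), default `TRUE`.
#' @return List of class `subject_networks`: `id`, `timecourses`
#'   (components x time, un-normalized), `maps` (components x voxels).
#' @export
dual_regression <- function(bold, group_maps, normalize_timecourses = TRUE) {
  x <- if (inherits(bold, "masked_bold")) bold$data else as.matrix(bold)
  g <- as.matrix(group_maps)
  if (ncol(g) != nrow(x)) {
    stopf("group maps cover %d voxels but BOLD has %d", ncol(g), nrow(x))
  }
  gd <- g - rowMeans(g)
  sv <- svd(gd, nu = 0, nv = 0)$d
  if (min(sv) < 1e-10 * max(sv)) {
    cc <- abs(stats::cor(t(gd)))
    diag(cc) <- 0
    pairs <- which(cc > 0.999, arr.ind = TRUE)
    pairs <- pairs[pairs[, 1] < pairs[, 2], , drop = FALSE]
    ids <- rownames(g)
    if (is.null(ids)) ids <- paste0("row", seq_len(nrow(g)))
    nm <- if (nrow(pairs) > 0) {
      paste(apply(pairs, 1, function(p) paste(ids[p], collapse = "~")),
            collapse = ", ")
    } else "unidentified"
    stopf("group maps are rank deficient (collinear: %s)", nm)
  }
  xc <- x - rowMeans(x)
  d1 <- t(gd)                                   # voxels x K
  tc <- solve(crossprod(d1), crossprod(d1, xc)) # K x time
  tcn <- tc
  if (normalize_timecourses) {
    s <- apply(tc, 1, stats::sd)
    if (any(s == 0)) stopf("stage-1 time course with zero variance")
    tcn <- tc / s
  }
  d2 <- t(tcn)                                  # time x K
  maps <- solve(crossprod(d2), crossprod(d2, t(xc)))  # K x voxels
  rownames(maps) <- rownames(g)
  rownames(tc) <- rownames(g)
  structure(list(id = if (inherits(bold, "masked_bold")) bold$id else NULL,
                 timecourses = tc, maps = maps),
            class = "subject_networks")
}
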