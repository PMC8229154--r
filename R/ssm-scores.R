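#' Scaled-subprofile-model network expression scores
#'
#' Quantifies, for each subject and each retained group network, how
#' strongly the subject expresses that network's topography. For component
#' k the subjects x voxels matrix of back-reconstructed maps is (a) row
#' centered (each subject's own voxel mean removed), (b) column centered
#' against the across-subjects mean profile (double centering), and (c)
#' projected onto the group z-map, normalized by the topography's squared
#' norm. Each score column is then z-transformed against the reference
#' (control) group, so control columns have mean 0 and standard deviation 1
#' and patient scores read as deviations from normal expression in control
#' standard-deviation units.
#'
#' The classical SSM log-transform (appropriate for strictly positive PET
#' images) is omitted: ICA maps are signed. The subtractive double
#' centering is retained, which preserves the model's invariances — adding
#' a constant to a subject's map, or rescaling a topography by a positive
#' factor, leaves the scores unchanged.
#'
#' @param subject_networks List of [dual_regression()] results, one per
#'   subject, aligned with `groups`.
#' @param group_maps Components x voxels matrix of group topographies
#'   (typically the retained z-maps), rows named by component id.
#' @param groups Character/factor group label per subject.
#' @param ref_group Reference group for the z step, default `"Ctr"`.
#' @param reference Apply the reference z-transform (needs >= 2 reference
#'   subjects), default `TRUE`.
#' @return List of class `network_scores`: `scores` (subjects x components
#'   matrix, columns named by component id), `groups`, `ref_group`.
#' @export
compute_network_scores <- function(subject_networks, group_maps, groups,
                                   ref_group = "Ctr", reference = TRUE) {
  n <- length(subject_networks)
  g <- as.matrix(group_maps)
  k <- nrow(g)
  if (length(groups) != n) stopf("`groups` must have one label per subject")
  if (reference) {
    if (sum(groups == ref_group) < 2) {
      stopf("need at least 2 '%s' subjects for reference z-scoring", ref_group)
    }
  }
  ids <- rownames(g)
  if (is.null(ids)) ids <- paste0("IC", seq_len(k))
  norms <- rowSums(g^2)
  if (any(norms == 0)) {
    stopf("zero-norm topography: %s", paste(ids[norms == 0], collapse = ", "))
  }
  scores <- matrix(NA_real_, n, k, dimnames = list(
    vapply(seq_len(n), function(i) {
      id <- subject_networks[[i]]$id
      if (is.null(id)) sprintf("sub%03d", i) else id
    }, character(1)), ids))
  for (kk in seq_len(k)) {
    p <- do.call(rbind, lapply(subject_networks, function(sn) sn$maps[kk, ]))
    p <- p - rowMeans(p)                 # subject centering
    p <- sweep(p, 2, colMeans(p))        # mean-profile removal
    scores[, kk] <- drop(p %*% g[kk, ]) / norms[kk]
  }
  if (reference) {
    ref <- groups == ref_group
    mu <- colMeans(scores[ref, , drop = FALSE])
    sg <- apply(scores[ref, , drop = FALSE], 2, stats::sd)
    if (any(sg == 0)) stopf("reference-group score column with zero variance")
    scores <- sweep(sweep(scores, 2, mu), 2, sg, "/")
  }
  structure(list(scores = scores, groups = groups,
                 ref_group = if (reference) ref_group else NULL),
            class = "network_scores")
}

#' Write network scores as a tab-separated subjects x components table
#'
#' @param scores A `network_scores` object.
#' @param path Output path.
#' @export
write_network_scores <- function(scores, path) {
  tab <- data.frame(id = rownames(scores$scores), group = scores$groups,
                    scores$scores, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
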