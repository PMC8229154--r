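#' Match estimated components to reference maps
#'
#' One-to-one assignment between estimated and reference spatial maps
#' maximizing the total |correlation| — exhaustive over permutations up to
#' 8 components, greedy beyond. Used to compare ICA output with the
#' generator's ground truth, where component order and sign are arbitrary.
#'
#' @param est_maps Estimated components x voxels matrix.
#' @param ref_maps Reference components x voxels matrix (same voxel count,
#'   same number of rows).
#' @return List with `assignment` (for each reference row, the matched
#'   estimate row) and `correlations` (matched |correlation| per reference
#'   component).
#' @export
match_components <- function(est_maps, ref_maps) {
  k <- nrow(ref_maps)
  if (nrow(est_maps) != k) stopf("component counts differ")
  cc <- abs(stats::cor(t(ref_maps), t(est_maps)))   # k x k: ref x est
  if (k <= 8) {
    perms <- all_permutations(k)
    scores <- vapply(seq_len(nrow(perms)), function(i) {
      sum(cc[cbind(seq_len(k), perms[i, ])])
    }, numeric(1))
    asg <- perms[which.max(scores), ]
  } else {
    asg <- integer(k)
    used <- logical(k)
    for (i in order(apply(cc, 1, max), decreasing = TRUE)) {
      j <- order(cc[i, ], decreasing = TRUE)
      j <- j[!used[j]][1]
      asg[i] <- j
      used[j] <- TRUE
    }
  }
  list(assignment = asg, correlations = cc[cbind(seq_len(k), asg)])
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Run the full network-analysis pipeline on a cohort
#'
#' Motion screening, subject-level PCA, group PCA with (optional) MDL
#' order selection, ICASSO-stabilized InfoMax, component QC, dual
#' regression, control-referenced SSM scores, per-domain stepwise models,
#' and the patient-vs-control score comparison.
#'
#' @param bold List of [masked_bold()] objects, one per subject, aligned
#'   with `metadata` rows.
#' @param metadata Subject table (see [read_subject_table()]).
#' @param K Group model order; `NULL` selects it by MDL on the pooled
#'   eigenvalue spectrum.
#' @param subject_keep Subject-level PCA retention; default
#'   `ceiling(1.5 * K)` when `K` is given, else a conservative cap.
#' @param n_runs ICASSO runs, default 20.
#' @param resample ICASSO resampling mode, default `"bootstrap"`.
#' @param seed Integer seed for the stochastic stages.
#' @param labels Optional component label table/file for QC.
#' @param iq_min,cutoff,min_voxels QC settings.
#' @param motion_threshold_mm Motion exclusion threshold.
#' @param alpha_enter,alpha_remove Stepwise thresholds.
#' @return List with the stage outputs: `metadata` (retained), `reduced`,
#'   `K`, `icasso`, `components`, `subject_networks`, `scores`, `models`,
#'   `group_comparison`, `motion_excluded`.
#' @export
run_network_pipeline <- function(bold, metadata, K = NULL,
                                 subject_keep = NULL, n_runs = 20,
                                 resample = "bootstrap", seed = 1,
                                 labels = NULL, iq_min = 0.8, cutoff = 1.0,
                                 min_voxels = 50,
                                 motion_threshold_mm = 3.0,
                                 alpha_enter = 0.05, alpha_remove = 0.10) {
  stopifnot(length(bold) == nrow(metadata))
  scr <- screen_motion(metadata, motion_threshold_mm)
  keep <- metadata$id %in% scr$retained$id
  bold <- bold[keep]
  metadata <- metadata[keep, , drop = FALSE]

  nt <- ncol(bold[[1]]$data)
  nv <- nrow(bold[[1]]$data)
  if (is.null(subject_keep)) {
    subject_keep <- if (is.null(K)) {
      # keep the pooled dimension below the voxel sample count so the MDL
      # covariance spectrum stays estimable
      max(4L, min(nt - 1L, 40L, floor((nv - 1) / length(bold))))
    } else ceiling(1.5 * K)
  }
  reductions <- lapply(bold, reduce_subject, n_keep = subject_keep)

  if (is.null(K)) {
    pooled <- concat_group_pca(reductions, K = subject_keep)
    K <- estimate_order_mdl(pooled$eigenvalues, pooled$n_samples)
    if (K < 1) stopf("MDL found no sources in the group data")
  }
  reduced <- concat_group_pca(reductions, K = K)

  icasso <- run_icasso(reduced, n_runs = n_runs, resample = resample,
                       seed = seed)
  tcs <- component_timecourses(reduced, icasso$maps)
  components <- assemble_component_set(icasso, labels = labels,
                                       iq_min = iq_min, cutoff = cutoff,
                                       min_voxels = min_voxels,
                                       timecourses = tcs,
                                       tr_seconds = bold[[1]]$tr_seconds)
  if (length(components$ic_ids) == 0L) stopf("no components survived QC")

  subject_networks <- lapply(bold, dual_regression,
                             group_maps = components$z_maps)
  scores <- compute_network_scores(subject_networks, components$z_maps,
                                   metadata$group, ref_group = "Ctr")
  models <- fit_domain_models(scores, metadata,
                              alpha_enter = alpha_enter,
                              alpha_remove = alpha_remove)
  comparison <- compare_groups(scores)

  list(metadata = metadata, reduced = reduced, K = K, icasso = icasso,
       components = components, subject_networks = subject_networks,
       scores = scores, models = models, group_comparison = comparison,
       motion_excluded = scr$excluded)
}
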