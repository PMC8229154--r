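#' Z-score a spatial map
#'
#' Centers and scales a per-voxel map to mean 0 and (population) standard
#' deviation 1 over the mask — the scale on which the voxel-extent cutoff
#' is interpreted. Affine transforms of the input (a*x + b, a > 0) give the
#' identical output.
#'
#' @param x Numeric per-voxel vector.
#' @return Z-scored vector.
#' @export
zscore_map <- function(x) {
  s <- sd_pop(x)
  if (s == 0) stopf("cannot z-score a constant map")
  (x - mean(x)) / s
}

#' Voxel-extent filter
#'
#' A component fails if fewer than `min_voxels` voxels reach |z| >= cutoff
#' on its z-scored map (exactly `min_voxels` suprathreshold voxels passes:
#' the exclusion rule is a strict "fewer than").
#'
#' @param z_map Z-scored per-voxel vector.
#' @param cutoff Threshold on |z|, default 1.0.
#' @param min_voxels Minimum suprathreshold extent, default 50.
#' @return List with `pass` (logical) and `count`.
#' @export
voxel_extent_filter <- function(z_map, cutoff = 1.0, min_voxels = 50) {
  count <- sum(abs(z_map) >= cutoff)
  list(pass = count >= min_voxels, count = count)
}

#' Fraction of spectral power at low frequencies
#'
#' Periodogram power in (0, `band_edge_hz`] divided by total power
#' excluding the zero-frequency (mean) term. A resting-state network time
#' course is expected to be dominated by fluctuations below ~0.1 Hz; white
#' noise instead yields roughly `band_edge_hz / Nyquist`.
#'
#' @param timecourse Numeric time series.
#' @param tr_seconds Sampling interval (repetition time), seconds.
#' @param band_edge_hz Band edge, must be below Nyquist = 1/(2 TR).
#' @return Ratio in \[0, 1\].
#' @export
low_freq_ratio <- function(timecourse, tr_seconds, band_edge_hz = 0.10) {
  nyq <- 1 / (2 * tr_seconds)
  if (band_edge_hz >= nyq) {
    stopf("band edge %.3f Hz is not below Nyquist (%.3f Hz)", band_edge_hz, nyq)
  }
  n <- length(timecourse)
  if (stats::var(timecourse) == 0) {
    stopf("low-frequency ratio undefined for a constant time course")
  }
  p <- Mod(stats::fft(timecourse - mean(timecourse)))^2
  nf <- floor(n / 2)
  freqs <- seq_len(nf) / (n * tr_seconds)
  pw <- p[2:(nf + 1)]
  sum(pw[freqs <= band_edge_hz]) / sum(pw)
}

#' Reconstruct component time courses in native time
#'
#' Regresses the pooled (concatenated, reduced) group data on the component
#' maps to obtain each component's course along the pooled reduced-time
#' dimension, then maps each subject's block through that subject's
#' temporal PCA basis back to scanner time.
#'
#' @param reduced A `reduced_data` from [concat_group_pca()] built from
#'   [reduce_subject()] results (so temporal bases are available).
#' @param maps Components x voxels matrix (e.g. ICASSO centrotype maps).
#' @return List of timepoints x components matrices, one per subject.
#' @export
component_timecourses <- function(reduced, maps) {
  if (is.null(reduced$bases) || any(vapply(reduced$bases, is.null, logical(1)))) {
    stopf("reduced data lacks subject temporal bases")
  }
  # pooled' ~ A maps  =>  A = pooled' maps' (maps maps')^-1, pooled x K
  a <- t(reduced$pooled) %*% t(maps) %*% solve(tcrossprod(maps))
  lapply(seq_along(reduced$bases), function(i) {
    rows <- reduced$blocks[i, "start"]:reduced$blocks[i, "end"]
    reduced$bases[[i]] %*% a[rows, , drop = FALSE]
  })
}

qc_labels <- c("artifact", "AUD", "CCN", "DMN", "SMN", "VIS", "CBL", "SCN",
               "unlabeled")

#' Read a component label file
#'
#' Two-column whitespace/tab-separated text: component id (e.g. `IC36`) and
#' label, one of artifact, AUD, CCN, DMN, SMN, VIS, CBL, SCN, unlabeled.
#' Duplicate component ids are rejected.
#'
#' @param path Path to the label file.
#' @return Data frame with columns `ic_id`, `label`.
#' @export
read_component_labels <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("ic_id", "label"))
  validate_labels(tab)
}

validate_labels <- function(labels) {
  if (!all(c("ic_id", "label") %in% names(labels))) {
    stopf("labels need columns `ic_id` and `label`")
  }
  if (anyDuplicated(labels$ic_id)) {
    stopf("duplicate component id(s) in label set: %s",
          paste(unique(labels$ic_id[duplicated(labels$ic_id)]), collapse = ", "))
  }
  bad <- setdiff(labels$label, qc_labels)
  if (length(bad) > 0L) {
    stopf("unknown label(s): %s (allowed: %s)", paste(bad, collapse = ", "),
          paste(qc_labels, collapse = ", "))
  }
  labels
}

#' Screen, filter, and label group components
#'
#' Applies the component retention rules in a fixed order — cluster
#' stability (Iq below `iq_min`), user-supplied artifact label, then the
#' voxel-extent filter — and returns the retained component set together
#' with an exclusion report giving one reasoned row per dropped component.
#' Retained components carry their canonical-network labels (or
#' `"unlabeled"`). Low-frequency dominance of the component time courses is
#' computed and reported when time courses are supplied, but excludes a
#' component only if `enforce_lowfreq` is set (visual QC of spectra is the
#' field's norm, so the numeric rule is opt-in).
#'
#' Re-running the assembly on its own retained set changes nothing, and the
#' retained plus excluded ids always partition the input.
#'
#' @param icasso An `icasso_result` (or list with `maps` and `iq`).
#' @param labels Optional data frame (`ic_id`, `label`) or label file path.
#' @param iq_min Minimum Iq, default 0.8.
#' @param cutoff,min_voxels Extent-filter settings (defaults 1.0 and 50).
#' @param timecourses Optional list of per-subject timepoints x components
#'   matrices (see [component_timecourses()]).
#' @param tr_seconds Repetition time for the spectral check.
#' @param band_edge_hz Band edge for the low-frequency ratio.
#' @param enforce_lowfreq If non-`NULL`, exclude components whose mean
#'   low-frequency ratio falls below this value.
#' @return List of class `component_set`: `ic_ids`, `z_maps` (retained x
#'   voxels), `iq`, `counts`, `low_freq_ratio`, `labels`, and `exclusions`
#'   (data frame `ic_id`, `reason`, `detail`).
#' @export
assemble_component_set <- function(icasso, labels = NULL, iq_min = 0.8,
                                   cutoff = 1.0, min_voxels = 50,
                                   timecourses = NULL, tr_seconds = 2.0,
                                   band_edge_hz = 0.10,
                                   enforce_lowfreq = NULL) {
  maps <- icasso$maps
  iq <- icasso$iq
  ids <- rownames(maps)
  if (is.null(ids)) ids <- paste0("IC", seq_len(nrow(maps)))
  if (is.character(labels)) labels <- read_component_labels(labels)
  if (!is.null(labels)) {
    labels <- validate_labels(labels)
    unknown <- setdiff(labels$ic_id, ids)
    if (length(unknown) > 0L) {
      stopf("label file references unknown component(s): %s",
            paste(unknown, collapse = ", "))
    }
  }
  lab <- stats::setNames(rep("unlabeled", length(ids)), ids)
  if (!is.null(labels)) lab[labels$ic_id] <- labels$label

  z_maps <- t(apply(maps, 1, zscore_map))
  rownames(z_maps) <- ids
  counts <- apply(z_maps, 1, function(z) sum(abs(z) >= cutoff))
  lfr <- rep(NA_real_, length(ids))
  if (!is.null(timecourses)) {
    lfr <- vapply(seq_along(ids), function(k) {
      mean(vapply(timecourses, function(tc) {
        low_freq_ratio(tc[, k], tr_seconds, band_edge_hz)
      }, numeric(1)))
    }, numeric(1))
  }

  reason <- rep(NA_character_, length(ids))
  detail <- rep(NA_character_, length(ids))
  for (k in seq_along(ids)) {
    if (!is.null(iq) && iq[k] < iq_min) {
      reason[k] <- "low_iq"
      detail[k] <- sprintf("Iq %.3f < %.2f", iq[k], iq_min)
    } else if (lab[k] == "artifact") {
      reason[k] <- "artifact"
      detail[k] <- "labeled artifact"
    } else if (counts[k] < min_voxels) {
      reason[k] <- "low_extent"
      detail[k] <- sprintf("%d voxels at |z| >= %g (< %d)", counts[k],
                           cutoff, min_voxels)
    } else if (!is.null(enforce_lowfreq) && is.finite(lfr[k]) &&
               lfr[k] < enforce_lowfreq) {
      reason[k] <- "high_freq"
      detail[k] <- sprintf("low-frequency ratio %.2f < %.2f", lfr[k],
                           enforce_lowfreq)
    }
  }
  keep <- is.na(reason)
  structure(list(
    ic_ids = ids[keep],
    z_maps = z_maps[keep, , drop = FALSE],
    iq = if (is.null(iq)) NULL else iq[keep],
    counts = counts[keep],
    low_freq_ratio = lfr[keep],
    labels = lab[keep],
    exclusions = data.frame(ic_id = ids[!keep], reason = reason[!keep],
                            detail = detail[!keep], stringsAsFactors = FALSE),
    settings = list(iq_min = iq_min, cutoff = cutoff, min_voxels = min_voxels,
                    enforce_lowfreq = enforce_lowfreq)
  ), class = "component_set")
}

#' @export
print.component_set <- function(x, ...) {
  cat(sprintf("<component_set> %d retained, %d excluded\n",
              length(x$ic_ids), nrow(x$exclusions)))
  if (nrow(x$exclusions) > 0) {
    cat("exclusions:\n")
    print(x$exclusions, row.names = FALSE)
  }
  invisible(x)
}

#' Write an exclusion report as structured text
#'
#' @param set A `component_set`.
#' @param path Output path.
#' @export
write_exclusion_report <- function(set, path) {
  utils::write.table(set$exclusions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
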