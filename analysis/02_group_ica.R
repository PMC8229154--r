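#!/usr/bin/env Rscript
# Group spatial ICA of the simulated cohort: subject PCA, temporal
# concatenation, MDL order selection, ICASSO-stabilized InfoMax.
# Writes the component stability/QC table to results/ and the component
# maps as NIfTI under scratch/.

library(icanets)

seed <- 1
cohort_dir <- file.path("scratch", "cohort")
if (!dir.exists(cohort_dir)) stop("run analysis/01_simulate_cohort.R first")

meta <- read_subject_table(file.path(cohort_dir, "metadata.tsv"))
mask <- file.path(cohort_dir, "mask.nii")
bold <- lapply(meta$id, function(id) {
  load_bold_masked(file.path(cohort_dir, paste0(id, "_bold.nii")), mask,
                   id = id)
})

reductions <- lapply(bold, reduce_subject, n_keep = 12)
pooled <- concat_group_pca(reductions, K = 12)
K <- estimate_order_mdl(pooled$eigenvalues, pooled$n_samples)
cat("MDL-selected model order:", K, "\n")

reduced <- concat_group_pca(reductions, K = K)
ica <- run_icasso(reduced, n_runs = 20, resample = "bootstrap", seed = seed)
cat("ICASSO: ", ica$n_converged, "/", ica$n_runs, "runs converged;",
    "Iq range", round(min(ica$iq), 3), "-", round(max(ica$iq), 3), "\n")

tcs <- component_timecourses(reduced, ica$maps)
set <- assemble_component_set(ica, timecourses = tcs,
                              tr_seconds = bold[[1]]$tr_seconds)
print(set)

tab <- data.frame(ic_id = set$ic_ids, iq = round(set$iq, 4),
                  suprathreshold_voxels = set$counts,
                  low_freq_ratio = round(set$low_freq_ratio, 3),
                  label = set$labels)
write.table(tab, file.path("results", "components.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_exclusion_report(set, file.path("results", "component_exclusions.tsv"))

map_dir <- file.path("scratch", "component_maps")
dir.create(map_dir, recursive = TRUE, showWarnings = FALSE)
src <- bold[[1]]
for (i in seq_along(set$ic_ids)) {
  save_map(set$z_maps[i, ], src$mask_index, src$dims, src$affine,
           file.path(map_dir, paste0(set$ic_ids[i], "_zmap.nii")))
}
saveRDS(list(set = set, reduced_K = K), file.path("scratch", "ica_state.rds"))
cat("component table -> results/components.tsv; maps ->", map_dir, "\n")
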