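#!/usr/bin/env Rscript
# Back-reconstruct subject-level networks by dual regression, compute
# control-referenced SSM expression scores, and compare PD vs Ctr per
# component. Writes the score matrix and the group comparison to results/.

library(icanets)

cohort_dir <- file.path("scratch", "cohort")
state_file <- file.path("scratch", "ica_state.rds")
if (!file.exists(state_file)) stop("run analysis/02_group_ica.R first")
set <- readRDS(state_file)$set

meta <- read_subject_table(file.path(cohort_dir, "metadata.tsv"))
mask <- file.path(cohort_dir, "mask.nii")
bold <- lapply(meta$id, function(id) {
  load_bold_masked(file.path(cohort_dir, paste0(id, "_bold.nii")), mask,
                   id = id)
})

sn <- lapply(bold, dual_regression, group_maps = set$z_maps)
scores <- compute_network_scores(sn, set$z_maps, meta$group)
write_network_scores(scores, file.path("results", "network_scores.tsv"))

cmp <- compare_groups(scores)
cmp$t <- round(cmp$t, 3)
cmp$p <- signif(cmp$p, 3)
write.table(cmp, file.path("results", "group_comparison.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("components with PD-vs-Ctr score differences at p < 0.05:",
    sum(cmp$significant), "of", nrow(cmp), "\n")
saveRDS(scores, file.path("scratch", "scores.rds"))
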