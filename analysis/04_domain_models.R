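#!/usr/bin/env Rscript
# Stepwise multiple regression of each MoCA domain on the network scores
# (PD subjects only), composition of the domain-related network maps, and
# hub detection. Writes the model report and hub table to results/.

library(icanets)

scores_file <- file.path("scratch", "scores.rds")
if (!file.exists(scores_file)) stop("run analysis/03_dual_regression_scores.R first")
scores <- readRDS(scores_file)
set <- readRDS(file.path("scratch", "ica_state.rds"))$set
meta <- read_subject_table(file.path("scratch", "cohort", "metadata.tsv"))

models <- fit_domain_models(scores, meta)
for (m in models) print(m)
write_domain_models(models, file.path("results", "domain_models.tsv"))

gen <- Filter(function(m) m$generated, models)
cat(length(gen), "of", length(models), "domain networks generated\n")

if (length(gen) >= 2) {
  hubs <- find_hubs(models, min_membership = 2)
  write.table(hubs, file.path("results", "hubs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cat("hub components (>= 2 domain models):",
      if (nrow(hubs)) paste(hubs$ic_id, collapse = ", ") else "none", "\n")
}

map_dir <- file.path("scratch", "domain_maps")
dir.create(map_dir, recursive = TRUE, showWarnings = FALSE)
mask <- file.path("scratch", "cohort", "mask.nii")
ref <- load_bold_masked(file.path("scratch", "cohort",
                                  paste0(meta$id[1], "_bold.nii")), mask)
for (m in gen) {
  cm <- compose_domain_network(m, set$z_maps)
  save_map(cm$values, ref$mask_index, ref$dims, ref$affine,
           file.path(map_dir, paste0(m$domain, "_network.nii")))
}
cat("composite domain-network maps ->", map_dir, "\n")
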