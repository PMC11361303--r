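#!/usr/bin/env Rscript
# Step 1: simulate the default longitudinal three-layer cohort (93 subjects
# x 3 timepoints, four community states, genus/pathway/metabolite layers
# plus QC pools) and write the tables that every later step consumes.

suppressPackageStartupMessages(library(commstate))

out_dir <- "results/cohort"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- cohort_config(seed = 20240801)
co <- generate_cohort(cfg)

write_feature_table(co$taxa, file.path(out_dir, "taxa_counts.tsv"))
write_feature_table(co$fun, file.path(out_dir, "pathway_abundance.tsv"))
write_feature_table(co$metabolome,
                    file.path(out_dir, "metabolome_intensity.tsv"))
write.table(co$meta, file.path(out_dir, "sample_metadata.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

truth <- co$truth
saveRDS_free <- list(  # truth serialized as plain text
  trajectories = apply(truth$trajectories, 1, paste, collapse = ","),
  metabolite_icc = truth$metabolite_icc,
  stay_prob = cfg$stay_prob)
writeLines(jsonlite::toJSON(saveRDS_free, digits = NA, auto_unbox = TRUE,
                            pretty = TRUE),
           file.path(out_dir, "truth.json"))

stab <- mean(apply(truth$trajectories, 1,
                   function(z) all(z == z[1])))
message(sprintf(
  "cohort: %d samples, %d genera; %.0f%% of subjects keep their state",
  sum(!co$meta$is_qc_pool), nrow(co$taxa$values), 100 * stab))
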