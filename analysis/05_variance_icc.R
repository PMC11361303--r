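#!/usr/bin/env Rscript
# Step 5: per-feature variance components and ICC for the three omics
# layers (taxa and pathways on the CLR scale with the relaxed 10%/10 core
# filter, metabolome on log10 after QC filtering), cross-layer
# Kruskal-Wallis/Dunn comparisons, and abundance-variance correlations.
# Restricted to subjects that shifted community state, matching the
# stability-focused design of the comparison.

suppressPackageStartupMessages(library(commstate))

meta <- read_sample_metadata("results/cohort/sample_metadata.tsv")
qc_ids <- meta$sample_id[meta$is_qc_pool]
meta <- meta[!meta$is_qc_pool, ]
stab <- read.delim("results/stability_classes.tsv")
shifted <- stab$subject_id[stab$class == "shifted"]
meta_sh <- meta[meta$subject_id %in% shifted, ]
message(sprintf("variance analysis over %d shifted subjects", length(shifted)))

taxa <- read_feature_table("results/cohort/taxa_counts.tsv", layer = "taxa")
fun <- read_feature_table("results/cohort/pathway_abundance.tsv",
                          layer = "function")
met <- read_feature_table("results/cohort/metabolome_intensity.tsv",
                          layer = "metabolome")

keep <- function(t) feature_table(
  t$values[, intersect(colnames(t$values), meta_sh$sample_id), drop = FALSE],
  t$layer, t$transform_tag)

vt <- variance_components(clr_transform(filter_core_features(
  keep(taxa), 0.10, 10)), meta_sh)
vf <- variance_components(clr_transform(filter_core_features(
  keep(fun), 0.10, 10)), meta_sh)
met_f <- qc_filter_metabolome(met, qc_ids)
vm <- variance_components(feature_table(
  log10(keep(met_f)$values + 1), "metabolome", "pareto_log"), meta_sh)

vcs <- rbind(vt, vf, vm)
write.table(vcs, "results/variance_components.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

lc <- compare_layers(vcs)
for (metric in names(lc)) {
  m <- lc[[metric]]
  message(sprintf(
    "%s: medians taxa %.3g / function %.3g / metabolome %.3g (KW p %.3g)",
    metric, m$medians["taxa"], m$medians["function"],
    m$medians["metabolome"], m$p_value))
  write.table(m$dunn, sprintf("results/dunn_%s.tsv", metric), sep = "\t",
              quote = FALSE, row.names = FALSE)
}

for (lay in c("taxa", "function", "metabolome")) {
  av <- abundance_variance_correlation(vcs[vcs$layer == lay, ])
  message(sprintf(
    "%s: abundance vs intra-individual variance Spearman rho %.2f (p %.3g)",
    lay, av$rho, av$p_value))
}
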