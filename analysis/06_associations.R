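#!/usr/bin/env Rscript
# Step 6: Prevotella/Bacteroides and Blautia/Bacteroides log ratios,
# state-explained ratio variance, and covariate-adjusted per-metabolite
# association tests with Bonferroni control.

suppressPackageStartupMessages(library(commstate))

taxa <- read_feature_table("results/cohort/taxa_counts.tsv", layer = "taxa")
met <- read_feature_table("results/cohort/metabolome_intensity.tsv",
                          layer = "metabolome")
meta <- read_sample_metadata("results/cohort/sample_metadata.tsv")
qc_ids <- meta$sample_id[meta$is_qc_pool]
meta <- meta[!meta$is_qc_pool, ]
assign <- read.delim("results/community_assignments.tsv")

pb <- log_ratio(taxa, "Prevotella", "Bacteroides", c = 1)
bb <- log_ratio(taxa, "Blautia", "Bacteroides", c = 1)

# how much of the ratio does the community type explain?
ev <- explained_variance(pb[assign$sample_id],
                         data.frame(state = factor(assign$state)))
message(sprintf("community type explains %.1f%% of the P/B ratio variance",
                ev$pct_variance[ev$predictor == "state"]))

# metabolite panel: QC filter, Pareto-log scale, covariate-adjusted OLS
met_f <- qc_filter_metabolome(met, qc_ids)
met_pl <- pareto_log_transform(met_f)
covars <- data.frame(sample_id = meta$sample_id, sex = meta$sex,
                     race_ethnicity = meta$race_ethnicity, bmi = meta$bmi,
                     timepoint = factor(meta$timepoint))
for (ratio in c("pb", "bb")) {
  y <- if (ratio == "pb") pb else bb
  res <- adjusted_feature_associations(y, met_pl, covars, meta = meta)
  res <- res[order(res$p), ]
  write.table(res, sprintf("results/%s_metabolite_associations.tsv", ratio),
              sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf(
    "%s ratio: %d of %d metabolites significant after Bonferroni",
    toupper(ratio), sum(res$p_adj < 0.05), nrow(res)))
}
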