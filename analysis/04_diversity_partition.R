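#!/usr/bin/env Rscript
# Step 4: alpha diversity on rarefied counts, intra- vs inter-individual
# Bray-Curtis partition, and per-subject regressions of sqrt median
# intra-individual dissimilarity on mean Shannon and mean CLR core genera.

suppressPackageStartupMessages(library(commstate))

taxa <- read_feature_table("results/cohort/taxa_counts.tsv", layer = "taxa")
meta <- read_sample_metadata("results/cohort/sample_metadata.tsv")
meta <- meta[!meta$is_qc_pool, ]

# rarefy to a common depth before Shannon; the simulated depths sit near
# 5,000 reads, so 2,000 keeps nearly all samples
rar <- rarefy(taxa, depth = 2000, seed = 4)
shan <- shannon_index(rar)
write.table(data.frame(sample_id = names(shan), shannon = shan),
            "results/shannon_index.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

core <- filter_core_features(taxa, 0.30, 10)
dm <- distance_matrix(relabund_transform(core), "bray_curtis")
write_distance_matrix(dm, "results/bray_curtis.tsv")
pp <- partition_dissimilarity(dm, meta)
message(sprintf(
  "intra median %.3f vs inter median %.3f (Mann-Whitney p = %.3g)",
  median(pp$intra), median(pp$inter), pp$p_value))
write.table(pp$subject_median, "results/subject_median_dissimilarity.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

# per-subject predictors: mean Shannon and mean CLR core-genus abundance
subj_of <- meta$subject_id[match(names(shan), meta$sample_id)]
mean_shannon <- tapply(shan, subj_of, mean)
clr <- clr_transform(core)
subj_clr <- meta$subject_id[match(colnames(clr$values), meta$sample_id)]
mean_clr <- t(apply(clr$values, 1, function(z) tapply(z, subj_clr, mean)))

sm <- pp$subject_median
preds <- data.frame(mean_shannon = as.numeric(mean_shannon[sm$subject_id]),
                    t(mean_clr[, sm$subject_id]))
reg <- dissimilarity_regressions(sm$sqrt_median_intra, preds,
                                 bonferroni = TRUE)
write.table(reg, "results/dissimilarity_regressions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
top <- reg[order(reg$p), ][1:5, ]
message("strongest dissimilarity predictors: ",
        paste(sprintf("%s (beta %.2f, p %.3g)", top$predictor, top$beta,
                      top$p), collapse = "; "))
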