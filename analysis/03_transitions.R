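#!/usr/bin/env Rscript
# Step 3: subject trajectories, stability classes, the transition
# null model (16-category chi-square with standardized residuals), the
# empirical Markov matrix, and per-transition dissimilarity medians.

suppressPackageStartupMessages(library(commstate))

assign <- read.delim("results/community_assignments.tsv")
meta <- read_sample_metadata("results/cohort/sample_metadata.tsv")
meta <- meta[!meta$is_qc_pool, ]

trajs <- build_trajectories(assign, meta)
stab <- classify_stability(trajs)
write.table(stab, "results/stability_classes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("%d of %d subjects shifted community state",
                sum(stab$class == "shifted"), nrow(stab)))

tal <- transition_chisq(trajs, expected_mode = "cross_pairing")
write.table(tal$table, "results/transition_tally.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(jsonlite::toJSON(list(statistic = tal$statistic, df = tal$df,
                                 p_value = tal$p_value,
                                 total_transitions = tal$total_transitions),
                            auto_unbox = TRUE, digits = NA),
           "results/transition_chisq.json")
message(sprintf("chi-square GOF: X2 = %.1f (df %d), p = %.3g",
                tal$statistic, tal$df, tal$p_value))
sig <- tal$table[tal$table$significant & !is.na(tal$table$residual), ]
message("cells beyond +/-1.96: ",
        paste(sprintf("%s->%s (%.2f)", sig$from, sig$to, sig$residual),
              collapse = ", "))

P <- empirical_markov(trajs)
write.table(data.frame(from = rownames(P), P, check.names = FALSE),
            "results/empirical_markov.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

taxa <- read_feature_table("results/cohort/taxa_counts.tsv", layer = "taxa")
core <- filter_core_features(taxa, 0.30, 10)
dm <- distance_matrix(relabund_transform(core), "bray_curtis")
td <- transition_dissimilarity(trajs, dm, meta)
write.table(td, "results/transition_dissimilarity.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
self_med <- median(td$median_dissimilarity[td$from == td$to], na.rm = TRUE)
cross_med <- median(td$median_dissimilarity[td$from != td$to], na.rm = TRUE)
message(sprintf(
  "median Bray-Curtis: self transitions %.2f, cross transitions %.2f",
  self_med, cross_med))
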