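# Small in-code fixtures shared across test files.

make_ft <- function(values, layer = "taxa", transform_tag = "raw",
                    features = NULL, samples = NULL) {
  if (is.null(features)) features <- sprintf("f%02d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(values)))
  dimnames(values) <- list(features, samples)
  feature_table(values, layer, transform_tag)
}

# a fast cohort config: full state machinery, slim layers
slim_cfg <- function(...) {
  args <- utils::modifyList(list(n_genera = 8, n_pathways = 6,
                                 n_metabolites = 6,
                                 depth_log_mean = log(500)),
                            list(...))
  do.call(cohort_config, args)
}

# truth state per sample, in the generator's sample order (timepoint-major)
truth_states_by_sample <- function(co) {
  tr <- co$truth$trajectories
  unlist(lapply(seq_len(ncol(tr)), function(tt) tr[, tt]), use.names = FALSE)
}

# metadata without QC pool rows
study_meta <- function(co) co$meta[!co$meta$is_qc_pool, , drop = FALSE]
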