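#' Per-feature variance components and ICC
#'
#' One-way random-effects (method-of-moments) decomposition per feature,
#' subjects as the grouping factor: with I subjects, n_i replicates and N
#' total samples, MSB and MSW come from the one-way ANOVA,
#' \code{n0 = (N - sum(n_i^2)/N)/(I - 1)}, the within-subject variance is
#' MSW, the between-subject variance is \code{max(0, (MSB - MSW)/n0)}
#' (negative moment estimates truncate to zero), and
#' \code{ICC = inter/(inter + intra)} (0 when the total is 0). Values are
#' expected on the layer's analysis scale (CLR for taxa/function, log10 for
#' the metabolome).
#'
#' @param t \code{feature_table} on its analysis scale.
#' @param meta sample metadata (\code{sample_id}, \code{subject_id}).
#' @param estimator only \code{"moments"} is implemented.
#' @return data.frame with one row per feature: \code{feature_id},
#'   \code{layer}, \code{inter_var}, \code{intra_var}, \code{total_var},
#'   \code{icc}, \code{mean_abundance}; the count of truncated
#'   between-subject variances is attached as attribute
#'   \code{"n_truncated"}.
#' @export
variance_components <- function(t, meta, estimator = "moments") {
  stopifnot(inherits(t, "feature_table"))
  estimator <- match.arg(estimator, "moments")
  meta <- validate_metadata(meta)
  meta <- meta[!meta$is_qc_pool, , drop = FALSE]
  ids <- sample_ids(t)
  sub <- meta$subject_id[match(ids, meta$sample_id)]
  if (anyNA(sub))
    stop("sample(s) missing from metadata: ",
         paste(ids[is.na(sub)], collapse = ", "))
  tab <- table(sub)
  singletons <- names(tab)[tab < 2]
  if (length(singletons)) {
    warning("excluding ", length(singletons),
            " subject(s) with a single sample")
    keep <- !(sub %in% singletons)
    sub <- sub[keep]
    t <- feature_table(t$values[, keep, drop = FALSE], t$layer,
                       t$transform_tag)
  }
  sub <- factor(sub)
  I <- nlevels(sub)
  if (I < 3) stop("need at least 3 subjects with repeated samples")
  x <- t$values  # features x samples
  N <- ncol(x)
  n_i <- as.numeric(table(sub))
  grp_sum <- base::t(rowsum(base::t(x), sub))       # features x subjects
  grp_mean <- sweep(grp_sum, 2, n_i, "/")
  grand <- rowMeans(x)
  ssb <- rowSums(sweep((grp_mean - grand)^2, 2, n_i, "*"))
  sst <- rowSums((x - grand)^2)
  ssw <- sst - ssb
  msb <- ssb / (I - 1)
  msw <- ssw / (N - I)
  n0 <- (N - sum(n_i^2) / N) / (I - 1)
  raw_b <- (msb - msw) / n0
  n_trunc <- sum(raw_b < 0)
  inter <- pmax(0, raw_b)
  intra <- msw
  total <- inter + intra
  icc <- ifelse(total > 0, inter / total, 0)
  out <- data.frame(feature_id = feature_ids(t), layer = t$layer,
                    inter_var = inter, intra_var = intra, total_var = total,
                    icc = icc, mean_abundance = rowMeans(x),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_truncated") <- n_trunc
  out
}

#' Compare variance metrics across omics layers
#'
#' Tie-corrected Kruskal-Wallis on each of total variance, intra-individual
#' variance and ICC across the (taxa, function, metabolome) layers, with
#' Dunn's pairwise z tests Bonferroni-adjusted over the three layer pairs.
#'
#' @param vcs row-bound [variance_components()] output for all three
#'   layers.
#' @return list of class \code{layer_comparison}, one element per metric,
#'   each holding the Kruskal-Wallis \code{H}, \code{df}, \code{p_value},
#'   the per-layer medians, and the Dunn pairwise table.
#' @export
compare_layers <- function(vcs) {
  layers <- c("taxa", "function", "metabolome")
  missing <- setdiff(layers, unique(vcs$layer))
  if (length(missing))
    stop("layer(s) missing from input: ", paste(missing, collapse = ", "))
  counts <- table(vcs$layer)
  if (any(counts[layers] < 2)) stop("need >= 2 features per layer")
  out <- list()
  for (metric in c("total_var", "intra_var", "icc")) {
    vals <- vcs[[metric]]
    grp <- factor(vcs$layer, levels = layers)
    kw <- stats::kruskal.test(vals, grp)
    dunn <- dunn_test(vals, grp)
    out[[metric]] <- list(
      H = unname(kw$statistic), df = unname(kw$parameter),
      p_value = kw$p.value,
      medians = tapply(vals, grp, stats::median),
      dunn = dunn)
  }
  structure(out, class = "layer_comparison")
}

# Dunn's post-hoc test: pairwise rank-sum z statistics with tie correction
# and Bonferroni adjustment over the pairs.
dunn_test <- function(values, groups) {
  groups <- factor(groups)
  if (any(table(groups) == 0)) stop("empty group")
  r <- rank(values)
  N <- length(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12
  lev <- levels(groups)
  combs <- utils::combn(lev, 2)
  res <- data.frame(group1 = combs[1, ], group2 = combs[2, ],
                    z = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(ncol(combs))) {
    g1 <- combs[1, i]; g2 <- combs[2, i]
    n1 <- sum(groups == g1); n2 <- sum(groups == g2)
    m1 <- mean(r[groups == g1]); m2 <- mean(r[groups == g2])
    se <- sqrt((v0 - tie_term) * (1 / n1 + 1 / n2))
    z <- if (se > 0) (m1 - m2) / se else 0
    res$z[i] <- z
    res$p[i] <- 2 * stats::pnorm(-abs(z))
  }
  res$p_adj <- pmin(1, res$p * nrow(res))
  res
}

#' Abundance versus within-subject variance correlation
#'
#' Spearman correlation between per-feature mean abundance (on the layer's
#' analysis scale) and intra-individual variance. If the variances are all
#' tied the correlation is reported as 0 with \code{tie_flag = TRUE}.
#'
#' @param vcs [variance_components()] output for one layer.
#' @return list with \code{rho}, \code{p_value}, \code{n}, \code{tie_flag}.
#' @export
abundance_variance_correlation <- function(vcs) {
  if (nrow(vcs) < 4) stop("need at least 4 features")
  if (length(unique(vcs$intra_var)) == 1L ||
      length(unique(vcs$mean_abundance)) == 1L)
    return(list(rho = 0, p_value = 1, n = nrow(vcs), tie_flag = TRUE))
  ct <- suppressWarnings(stats::cor.test(vcs$mean_abundance, vcs$intra_var,
                                         method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = nrow(vcs),
       tie_flag = FALSE)
}
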