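#' Shannon diversity index per sample
#'
#' H = -sum p_i log(p_i) over the sample's relative abundances; zero-count
#' features contribute nothing. Best computed on rarefied counts so depths
#' are comparable.
#'
#' @param t \code{feature_table} of nonnegative values with positive
#'   per-sample totals.
#' @param log_base logarithm base, default natural log.
#' @return named numeric vector, one value per sample.
#' @export
shannon_index <- function(t, log_base = exp(1)) {
  stopifnot(inherits(t, "feature_table"))
  totals <- colSums(t$values)
  if (any(totals <= 0))
    stop("sample(s) with zero total: ",
         paste(sample_ids(t)[totals <= 0], collapse = ", "))
  p <- sweep(t$values, 2, totals, "/")
  pl <- p * log(p, base = log_base)
  pl[p == 0] <- 0
  -colSums(pl)
}

#' Pairwise dissimilarity matrix
#'
#' Bray-Curtis: \code{sum |x - y| / sum (x + y)}. Canberra: the plain sum of
#' \code{|x - y| / (x + y)} over features where \code{x + y > 0} (no
#' rescaling by the number of contributing terms).
#'
#' @param t \code{feature_table} of nonnegative values.
#' @param metric \code{"bray_curtis"} or \code{"canberra"}.
#' @return object of class \code{distance_matrix}: list with the symmetric
#'   \code{matrix} (zero diagonal, sample ids as dimnames) and the
#'   \code{metric} tag.
#' @export
distance_matrix <- function(t, metric = c("bray_curtis", "canberra")) {
  stopifnot(inherits(t, "feature_table"))
  metric <- match.arg(metric)
  x <- t$values
  if (any(x < 0)) stop("dissimilarities require nonnegative values")
  totals <- colSums(x)
  n <- ncol(x)
  if (metric == "bray_curtis") {
    if (any(totals <= 0))
      stop("all-zero sample(s): ",
           paste(sample_ids(t)[totals <= 0], collapse = ", "))
    num <- as.matrix(stats::dist(base::t(x), method = "manhattan"))
    den <- outer(totals, totals, "+")
    d <- num / den
  } else {
    d <- matrix(0, n, n)
    for (j in seq_len(nrow(x))) {
      xi <- x[j, ]
      den <- outer(xi, xi, "+")
      num <- abs(outer(xi, xi, "-"))
      term <- num / den
      term[den == 0] <- 0
      d <- d + term
    }
    if (any(totals <= 0) && n > 1) {
      # a pair of all-zero samples has no defined terms
      zz <- which(totals <= 0)
      if (length(zz) > 1) stop("pair(s) of all-zero samples")
    }
  }
  dimnames(d) <- list(sample_ids(t), sample_ids(t))
  diag(d) <- 0
  d <- (d + base::t(d)) / 2  # enforce exact symmetry against FP noise
  structure(list(matrix = d, metric = metric), class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("distance_matrix: %d samples, metric=%s\n",
              nrow(x$matrix), x$metric))
  invisible(x)
}

#' Write / read a distance matrix as square TSV
#' @param dm a \code{distance_matrix}.
#' @param path file path.
#' @export
write_distance_matrix <- function(dm, path) {
  df <- data.frame(sample_id = rownames(dm$matrix), dm$matrix,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Partition dissimilarities within and between subjects
#'
#' Splits all off-diagonal sample pairs into intra-individual (same
#' subject) and inter-individual sets, computes each subject's median
#' intra-individual dissimilarity and its square root, and compares the two
#' sets with a two-sided Mann-Whitney U test. When every dissimilarity is
#' tied the tie-corrected normal approximation degenerates and p = 1 is
#' reported.
#'
#' @param dm a \code{distance_matrix} over the longitudinal samples.
#' @param meta sample metadata with \code{sample_id}, \code{subject_id}.
#' @return list of class \code{dissimilarity_partition}: \code{intra},
#'   \code{inter} (value sets), \code{subject_median} (data.frame with
#'   per-subject median and sqrt-median), \code{mw_u}, \code{p_value}.
#' @export
partition_dissimilarity <- function(dm, meta) {
  stopifnot(inherits(dm, "distance_matrix"))
  meta <- validate_metadata(meta)
  meta <- meta[!meta$is_qc_pool, , drop = FALSE]
  ids <- rownames(dm$matrix)
  sub <- meta$subject_id[match(ids, meta$sample_id)]
  if (anyNA(sub))
    stop("sample(s) in the distance matrix missing from metadata: ",
         paste(ids[is.na(sub)], collapse = ", "))
  n <- length(ids)
  pair <- which(upper.tri(dm$matrix), arr.ind = TRUE)
  same <- sub[pair[, 1]] == sub[pair[, 2]]
  intra <- dm$matrix[pair[same, , drop = FALSE]]
  inter <- dm$matrix[pair[!same, , drop = FALSE]]
  if (!length(intra))
    stop("no intra-individual pairs; need subjects with >= 2 samples")
  if (!length(inter))
    stop("no inter-individual pairs; need >= 2 subjects")
  isub <- sub[pair[same, 1]]
  med <- tapply(intra, isub, stats::median)
  subject_median <- data.frame(subject_id = names(med),
                               median_intra = as.numeric(med),
                               sqrt_median_intra = sqrt(as.numeric(med)),
                               stringsAsFactors = FALSE)
  if (length(unique(c(intra, inter))) == 1L) {
    u <- length(intra) * length(inter) / 2
    p <- 1
  } else {
    wt <- stats::wilcox.test(intra, inter, alternative = "two.sided",
                             exact = FALSE, correct = TRUE)
    u <- unname(wt$statistic)
    p <- wt$p.value
  }
  structure(list(intra = intra, inter = inter,
                 subject_median = subject_median,
                 mw_u = u, p_value = p, n_pairs = n * (n - 1) / 2),
            class = "dissimilarity_partition")
}

#' Spearman correlation between paired per-subject changes
#'
#' Average-rank ties; p-value by the t approximation. Used to relate
#' per-subject ranges of one quantity (e.g. CLR genus abundance across the
#' three timepoints) to another (e.g. a pathway's CLR range); the caller
#' applies Bonferroni across pathways.
#'
#' @param subject_deltas_a,subject_deltas_b paired numeric vectors (>= 4).
#' @return list with \code{rho} and \code{p_value}.
#' @export
delta_correlation <- function(subject_deltas_a, subject_deltas_b) {
  if (length(subject_deltas_a) != length(subject_deltas_b))
    stop("inputs must be paired")
  ok <- stats::complete.cases(subject_deltas_a, subject_deltas_b)
  a <- subject_deltas_a[ok]; b <- subject_deltas_b[ok]
  if (length(a) < 4) stop("need at least 4 paired subjects")
  ct <- suppressWarnings(stats::cor.test(a, b, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(a))
}
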