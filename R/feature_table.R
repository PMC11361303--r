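#' Construct a feature table
#'
#' A feature table holds one omics layer as a features x samples numeric
#' matrix with a layer tag (\code{"taxa"}, \code{"function"} or
#' \code{"metabolome"}) and a transform tag recording what scale the values
#' are on. Taxa tables on the \code{"raw"} or \code{"rarefied"} scale must be
#' integer counts.
#'
#' @param values numeric matrix, features in rows, samples in columns; both
#'   dimnames required and unique.
#' @param layer one of \code{"taxa"}, \code{"function"}, \code{"metabolome"}.
#' @param transform_tag one of \code{"raw"}, \code{"rarefied"}, \code{"clr"},
#'   \code{"relabund"}, \code{"pareto_log"}.
#' @return an object of class \code{feature_table}.
#' @export
feature_table <- function(values, layer = c("taxa", "function", "metabolome"),
                          transform_tag = c("raw", "rarefied", "clr",
                                            "relabund", "pareto_log")) {
  layer <- match.arg(layer)
  transform_tag <- match.arg(transform_tag)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (features x samples)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have feature ids as rownames and sample ids as colnames")
  dup_f <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_f))
    stop("duplicate feature id(s): ", paste(dup_f, collapse = ", "))
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s))
    stop("duplicate sample id(s): ", paste(dup_s, collapse = ", "))
  if (anyNA(values))
    stop("`values` contains missing entries")
  if (transform_tag %in% c("raw", "rarefied", "relabund") && any(values < 0))
    stop("negative values are not allowed on the '", transform_tag, "' scale")
  if (layer == "taxa" && transform_tag %in% c("raw", "rarefied") &&
      any(values != round(values)))
    stop("taxa tables on the '", transform_tag, "' scale must hold integer counts")
  structure(list(values = values, layer = layer, transform_tag = transform_tag),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d features x %d samples [layer=%s, scale=%s]\n",
              nrow(x$values), ncol(x$values), x$layer, x$transform_tag))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

feature_ids <- function(t) rownames(t$values)
sample_ids <- function(t) colnames(t$values)

#' Read a feature table from TSV
#'
#' Expects feature ids in the first column and sample ids in the header
#' (features as rows). Set \code{samples_as_rows = TRUE} to accept the
#' transposed orientation.
#'
#' @param path path to a tab-separated file.
#' @param layer layer tag, see [feature_table()].
#' @param transform_tag scale tag, default \code{"raw"}.
#' @param samples_as_rows logical; transpose on read.
#' @return a \code{feature_table}.
#' @export
read_feature_table <- function(path, layer, transform_tag = "raw",
                               samples_as_rows = FALSE) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) stop("feature table needs an id column plus >=1 sample")
  ids <- df[[1]]
  header <- names(df)[-1]  # data.frame subsetting would uniquify duplicates
  body <- as.matrix(df[, -1, drop = FALSE])
  colnames(body) <- header
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body),
                                dimnames = dimnames(body)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric value at row '%s', column '%s'",
                 ids[bad[1]], colnames(body)[bad[2]]))
  }
  if (any(num < 0)) {
    bad <- which(num < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative value at row '%s', column '%s'",
                 ids[bad[1]], colnames(num)[bad[2]]))
  }
  rownames(num) <- ids
  if (samples_as_rows) num <- t(num)
  if (all(num == round(num)) && max(num) < .Machine$integer.max)
    storage.mode(num) <- "integer"  # lossless for count tables
  feature_table(num, layer = layer, transform_tag = transform_tag)
}

#' Write a feature table to TSV
#'
#' @param t a \code{feature_table}.
#' @param path output path; feature ids go in a first column named
#'   \code{feature_id}.
#' @export
write_feature_table <- function(t, path) {
  df <- data.frame(feature_id = feature_ids(t), t$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' Requires columns \code{sample_id}, \code{subject_id}, \code{timepoint};
#' any further columns are carried along as covariates. An optional logical
#' column \code{is_qc_pool} marks QC pool injections (default \code{FALSE}).
#'
#' @param path path to a tab-separated metadata file.
#' @return a \code{data.frame} with one row per sample.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_metadata(df)
}

#' Validate a sample metadata frame
#'
#' @param df data.frame with at least sample_id, subject_id, timepoint.
#' @return the validated frame (with is_qc_pool filled in).
#' @export
validate_metadata <- function(df) {
  need <- c("sample_id", "subject_id", "timepoint")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(df$is_qc_pool)) df$is_qc_pool <- FALSE
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in metadata")
  real <- df[!df$is_qc_pool, , drop = FALSE]
  key <- paste(real$subject_id, real$timepoint)
  if (anyDuplicated(key))
    stop("duplicate (subject_id, timepoint) among non-QC samples: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  df
}

#' Core-feature prevalence filter
#'
#' Keeps features observed at a count of at least \code{min_count} in at
#' least \code{ceiling(prevalence_frac * n_samples)} samples (boundary
#' inclusive). The sample set is unchanged.
#'
#' @param t raw \code{feature_table}.
#' @param prevalence_frac fraction of samples required, default 0.30.
#' @param min_count minimum per-sample count, default 10.
#' @return filtered \code{feature_table}.
#' @export
filter_core_features <- function(t, prevalence_frac = 0.30, min_count = 10) {
  stopifnot(inherits(t, "feature_table"))
  n <- ncol(t$values)
  need <- ceiling(prevalence_frac * n)
  hits <- rowSums(t$values >= min_count)
  keep <- hits >= need
  if (!any(keep))
    stop("no features pass the core filter; lower `prevalence_frac` or `min_count`")
  feature_table(t$values[keep, , drop = FALSE], t$layer, t$transform_tag)
}

#' Rarefy counts to a common depth
#'
#' Subsamples each sample's reads without replacement (multivariate
#' hypergeometric) to exactly \code{depth}. Samples with fewer total reads
#' than \code{depth} are dropped; their ids are attached as attribute
#' \code{"dropped_samples"} and reported via message.
#'
#' @param t raw taxa \code{feature_table} with integer counts.
#' @param depth target depth (reads per sample), must be positive.
#' @param seed integer seed; result is deterministic given the seed.
#' @return rarefied \code{feature_table} (transform_tag \code{"rarefied"}).
#' @export
rarefy <- function(t, depth, seed) {
  stopifnot(inherits(t, "feature_table"))
  if (t$layer != "taxa") stop("rarefaction applies to taxa count tables")
  if (depth <= 0) stop("`depth` must be positive")
  totals <- colSums(t$values)
  keep <- totals >= depth
  dropped <- sample_ids(t)[!keep]
  if (length(dropped))
    message("rarefy: dropping ", length(dropped),
            " sample(s) below depth ", depth, ": ",
            paste(dropped, collapse = ", "))
  if (!any(keep)) stop("all samples fall below the rarefaction depth")
  x <- t$values[, keep, drop = FALSE]
  out <- x
  with_rng_seed(seed, {
    for (j in seq_len(ncol(x))) {
      if (totals[keep][j] == depth) next  # unique subsample
      reads <- rep.int(seq_len(nrow(x)), x[, j])
      drawn <- sample(reads, depth, replace = FALSE)
      out[, j] <- tabulate(drawn, nbins = nrow(x))
    }
  })
  res <- feature_table(out, t$layer, "rarefied")
  attr(res, "dropped_samples") <- dropped
  res
}

#' Centered log-ratio transform
#'
#' Per sample: \code{log(x + pseudocount)} centered by its mean over
#' features, so columns sum to zero.
#'
#' @param t \code{feature_table} of nonnegative values.
#' @param pseudocount added before the log, default 1.
#' @return \code{feature_table} on the \code{"clr"} scale.
#' @export
clr_transform <- function(t, pseudocount = 1) {
  stopifnot(inherits(t, "feature_table"))
  if (pseudocount <= 0 && any(t$values == 0))
    stop("pseudocount must be positive when zeros are present")
  lx <- log(t$values + pseudocount)
  out <- sweep(lx, 2, colMeans(lx), "-")
  feature_table(out, t$layer, "clr")
}

#' Relative-abundance transform
#'
#' @param t raw \code{feature_table}; samples with zero total are rejected.
#' @return \code{feature_table} with per-sample proportions.
#' @export
relabund_transform <- function(t) {
  stopifnot(inherits(t, "feature_table"))
  totals <- colSums(t$values)
  if (any(totals <= 0))
    stop("sample(s) with zero total: ",
         paste(sample_ids(t)[totals <= 0], collapse = ", "))
  feature_table(sweep(t$values, 2, totals, "/"), t$layer, "relabund")
}

#' QC filter for metabolome tables
#'
#' Keeps features whose coefficient of variation (sample SD / mean) across
#' the QC pool injections is below \code{cv_max} and that have nonzero
#' intensity in strictly more than \code{presence_min} of the non-QC
#' samples. QC samples are removed from the output.
#'
#' @param t metabolome \code{feature_table} including QC pool columns.
#' @param qc_ids character vector of QC pool sample ids (>= 2 required).
#' @param cv_max CV threshold, default 0.20.
#' @param presence_min presence fraction threshold (strict), default 0.80.
#' @return filtered \code{feature_table} without QC columns.
#' @export
qc_filter_metabolome <- function(t, qc_ids, cv_max = 0.20, presence_min = 0.80) {
  stopifnot(inherits(t, "feature_table"))
  if (t$layer != "metabolome") stop("QC filtering applies to metabolome tables")
  qc_ids <- intersect(qc_ids, sample_ids(t))
  if (length(qc_ids) < 2) stop("need at least 2 QC pool samples")
  qc <- t$values[, qc_ids, drop = FALSE]
  study <- t$values[, setdiff(sample_ids(t), qc_ids), drop = FALSE]
  mu <- rowMeans(qc)
  sdv <- apply(qc, 1, stats::sd)
  cv <- ifelse(mu == 0, Inf, sdv / mu)
  presence <- rowMeans(study > 0)
  keep <- (cv < cv_max) & (presence > presence_min)
  if (!any(keep)) stop("no metabolite passes the QC filter")
  feature_table(study[keep, , drop = FALSE], t$layer, t$transform_tag)
}

#' Pareto scaling after log10 transform
#'
#' Per feature: \code{y = log10(x + 1)}, then center and divide by the
#' square root of the sample SD of \code{y}. Features with zero SD are set
#' to all-zero and reported via message.
#'
#' @param t QC-filtered metabolome \code{feature_table}.
#' @return \code{feature_table} on the \code{"pareto_log"} scale.
#' @export
pareto_log_transform <- function(t) {
  stopifnot(inherits(t, "feature_table"))
  y <- log10(t$values + 1)
  mu <- rowMeans(y)
  sdv <- apply(y, 1, stats::sd)
  flat <- sdv == 0
  if (any(flat))
    message("pareto_log_transform: ", sum(flat),
            " constant feature(s) set to zero")
  sdv[flat] <- 1
  out <- (y - mu) / sqrt(sdv)
  out[flat, ] <- 0
  feature_table(out, t$layer, "pareto_log")
}

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards.
with_rng_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}
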