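#' Pseudocounted log10 genus ratio per sample
#'
#' \code{log10((numerator + c) / (denominator + c))}, e.g. the
#' Prevotella/Bacteroides (P/B) or Blautia/Bacteroides (B/B) ratio, a
#' one-dimensional community-composition summary.
#'
#' @param t raw taxa \code{feature_table}.
#' @param numerator,denominator genus (feature) names.
#' @param c pseudocount, default 1 (must be positive so the ratio is
#'   finite at zero counts).
#' @return named numeric vector over samples, with attributes recording the
#'   genera and pseudocount.
#' @export
log_ratio <- function(t, numerator, denominator, c = 1) {
  stopifnot(inherits(t, "feature_table"))
  if (c <= 0) stop("pseudocount `c` must be positive")
  for (g in c(numerator, denominator))
    if (!(g %in% feature_ids(t))) stop("genus not in table: ", g)
  r <- log10((t$values[numerator, ] + c) / (t$values[denominator, ] + c))
  attr(r, "numerator") <- numerator
  attr(r, "denominator") <- denominator
  attr(r, "pseudocount") <- c
  r
}

# Build a covariate design matrix (intercept + one-hot categoricals with
# reference level); errors on rank deficiency, naming the aliased columns.
covariate_design <- function(covariates) {
  for (j in names(covariates))
    if (is.character(covariates[[j]]))
      covariates[[j]] <- factor(covariates[[j]])
  # constant covariates carry no adjustment and would alias the intercept
  constant <- vapply(covariates, function(v) length(unique(v)) < 2, TRUE)
  if (any(constant)) {
    message("dropping constant covariate(s): ",
            paste(names(covariates)[constant], collapse = ", "))
    covariates <- covariates[, !constant, drop = FALSE]
  }
  if (ncol(covariates) == 0)
    return(stats::model.matrix(~ 1,
                               data = data.frame(row.names =
                                                   rownames(covariates))))
  Z <- stats::model.matrix(~ ., data = covariates)
  q <- qr(Z)
  if (q$rank < ncol(Z)) {
    aliased <- colnames(Z)[q$pivot[(q$rank + 1):ncol(Z)]]
    stop("rank-deficient covariate design; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  Z
}

#' Covariate-adjusted per-feature associations with a log ratio
#'
#' For each feature, ordinary least squares of the ratio on the feature plus
#' covariates; the feature coefficient's two-sided t-test p-value is
#' Bonferroni-adjusted over all features tested. The covariate-adjusted
#' Spearman correlation is the Spearman correlation between the residuals of
#' (ratio ~ covariates) and (feature ~ covariates). Complete-case analysis;
#' the number of dropped samples is attached as an attribute, as is the
#' count of samples from repeated subjects when \code{meta} is supplied.
#'
#' @param y named ratio vector (see [log_ratio()]).
#' @param feats \code{feature_table} on the \code{pareto_log} scale.
#' @param covariates data.frame of per-sample covariates, rownames or a
#'   \code{sample_id} column identifying samples.
#' @param meta optional metadata used only to flag repeated subjects.
#' @return data.frame: \code{feature_id}, \code{beta}, \code{p},
#'   \code{p_adj}, \code{rho}, \code{n}.
#' @export
adjusted_feature_associations <- function(y, feats, covariates, meta = NULL) {
  stopifnot(inherits(feats, "feature_table"))
  if (!is.null(covariates$sample_id)) {
    rownames(covariates) <- covariates$sample_id
    covariates$sample_id <- NULL
  }
  ids <- intersect(names(y), intersect(sample_ids(feats),
                                       rownames(covariates)))
  cov <- covariates[ids, , drop = FALSE]
  ok <- stats::complete.cases(cov) & !is.na(y[ids])
  dropped <- sum(!ok)
  ids <- ids[ok]
  if (length(ids) < ncol(cov) + 3) stop("too few complete-case samples")
  Z <- covariate_design(cov[ids, , drop = FALSE])
  yv <- y[ids]
  X <- base::t(feats$values[, ids, drop = FALSE])  # samples x features
  # residualize once against the covariates; the coefficient of the feature
  # in [feature + covariates] equals the regression of residual y on
  # residual feature (Frisch-Waugh), with df = n - rank(Z) - 1
  Qz <- qr(Z)
  ry <- qr.resid(Qz, yv)
  RX <- qr.resid(Qz, X)
  n <- length(yv)
  df <- n - ncol(Z) - 1
  ssx <- colSums(RX^2)
  beta <- ifelse(ssx > 0, colSums(RX * ry) / ssx, NA_real_)
  rss <- sum(ry^2) - ifelse(ssx > 0, beta^2 * ssx, 0)
  se <- sqrt(pmax(rss / df, 0) / ssx)
  tstat <- beta / se
  p <- 2 * stats::pt(-abs(tstat), df)
  m <- ncol(X)
  rho <- vapply(seq_len(m), function(j) {
    if (ssx[j] == 0) return(NA_real_)
    suppressWarnings(stats::cor(ry, RX[, j], method = "spearman"))
  }, 0)
  out <- data.frame(feature_id = colnames(X), beta = beta, p = p,
                    p_adj = pmin(1, p * m), rho = rho, n = n,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_dropped") <- dropped
  if (!is.null(meta)) {
    meta <- validate_metadata(meta)
    sub <- meta$subject_id[match(ids, meta$sample_id)]
    attr(out, "n_repeated_subject_samples") <-
      sum(duplicated(sub) | duplicated(sub, fromLast = TRUE))
  }
  out
}

#' Sequential explained variance per predictor
#'
#' Type-I (sequential) sum-of-squares share per predictor, as a percent of
#' the total sum of squares, in the declared predictor order. The shares
#' depend on that order unless predictors are orthogonal; the order used is
#' recorded in the output.
#'
#' @param y numeric response.
#' @param design data.frame of predictors; column order is the entry order.
#' @return data.frame: \code{predictor} (plus a final \code{residual} row),
#'   \code{pct_variance}, \code{p_value} (sequential F test, NA for the
#'   residual row).
#' @export
explained_variance <- function(y, design) {
  for (j in names(design))
    if (is.character(design[[j]])) design[[j]] <- factor(design[[j]])
  dat <- data.frame(.y = y, design, check.names = FALSE)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  fml <- stats::as.formula(paste(".y ~",
                                 paste(sprintf("`%s`", names(design)),
                                       collapse = " + ")))
  fit <- stats::lm(fml, data = dat)
  if (any(is.na(stats::coef(fit)))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  an <- stats::anova(fit)
  tss <- sum(an[["Sum Sq"]])
  data.frame(predictor = rownames(an),
             pct_variance = 100 * an[["Sum Sq"]] / tss,
             p_value = an[["Pr(>F)"]],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-subject dissimilarity regressions
#'
#' One simple (univariable) linear regression per predictor of the
#' per-subject sqrt-transformed median intra-individual dissimilarity on
#' that predictor (e.g. mean Shannon index, or the mean CLR abundance of
#' each core genus), with the beta coefficient as the effect size.
#'
#' @param outcome named numeric vector, one value per subject.
#' @param predictors data.frame of per-subject predictors (rows align with
#'   \code{outcome}).
#' @param bonferroni also report Bonferroni-adjusted p-values over the
#'   predictors, default FALSE.
#' @return data.frame: \code{predictor}, \code{beta}, \code{p} (and
#'   \code{p_adj} when requested).
#' @export
dissimilarity_regressions <- function(outcome, predictors,
                                      bonferroni = FALSE) {
  if (length(outcome) != nrow(predictors))
    stop("`outcome` and `predictors` must align by subject")
  if (length(outcome) < 5) stop("need at least 5 subjects")
  res <- data.frame(predictor = names(predictors), beta = NA_real_,
                    p = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(predictors)) {
    fit <- stats::lm(outcome ~ predictors[[i]])
    sm <- stats::summary.lm(fit)$coefficients
    res$beta[i] <- sm[2, 1]
    res$p[i] <- sm[2, 4]
  }
  if (bonferroni) res$p_adj <- pmin(1, res$p * nrow(res))
  res
}

#' Rank-based group tests
#'
#' Mann-Whitney U (two groups), Kruskal-Wallis (>= 2 groups), or Dunn's
#' pairwise post-hoc z tests with Bonferroni adjustment (>= 3 groups), all
#' tie-corrected and two-sided.
#'
#' @param values numeric vector.
#' @param groups grouping factor aligned with \code{values}.
#' @param test one of \code{"mann_whitney"}, \code{"kruskal_wallis"},
#'   \code{"dunn"}.
#' @return for \code{mann_whitney}: list with \code{U} (first group) and
#'   \code{p_value}; for \code{kruskal_wallis}: list with \code{H},
#'   \code{df}, \code{p_value}; for \code{dunn}: the pairwise data.frame.
#' @export
rank_tests <- function(values, groups,
                       test = c("mann_whitney", "kruskal_wallis", "dunn")) {
  test <- match.arg(test)
  groups <- factor(groups)
  groups <- droplevels(groups)
  if (any(table(groups) == 0) || nlevels(groups) < 2) stop("empty group")
  if (test == "mann_whitney") {
    if (nlevels(groups) != 2) stop("mann_whitney needs exactly 2 groups")
    a <- values[groups == levels(groups)[1]]
    b <- values[groups == levels(groups)[2]]
    if (length(unique(values)) == 1L)
      return(list(U = length(a) * length(b) / 2, p_value = 1))
    wt <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
    return(list(U = unname(wt$statistic), p_value = wt$p.value))
  }
  if (test == "kruskal_wallis") {
    if (length(unique(values)) == 1L)
      return(list(H = 0, df = nlevels(groups) - 1, p_value = 1))
    kw <- stats::kruskal.test(values, groups)
    return(list(H = unname(kw$statistic), df = unname(kw$parameter),
                p_value = kw$p.value))
  }
  if (nlevels(groups) < 3) stop("dunn post-hoc needs >= 3 groups")
  dunn_test(values, groups)
}
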