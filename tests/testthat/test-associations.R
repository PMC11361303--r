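test_that("log ratios are pseudocounted and named-genus checked", {
  v <- matrix(c(10, 100, 5, 5, 0, 0), 2,
              dimnames = list(c("Prevotella", "Bacteroides"),
                              c("s1", "s2", "s3")))
  ft <- feature_table(v, "taxa", "raw")
  r <- log_ratio(ft, "Prevotella", "Bacteroides", c = 1)
  expect_equal(unname(r["s1"]), log10(11 / 101))
  expect_equal(unname(r["s2"]), 0)  # equal counts
  expect_equal(unname(r["s3"]), 0)  # both zero, pseudocount saves it
  expect_error(log_ratio(ft, "Blautia", "Bacteroides"), "Blautia")
  expect_error(log_ratio(ft, "Prevotella", "Bacteroides", c = 0),
               "positive")
})

make_assoc_fixture <- function(n = 500, m = 200, planted = 0, seed = 1) {
  set.seed(seed)
  ids <- sprintf("s%04d", seq_len(n))
  y <- rnorm(n); names(y) <- ids
  feats <- matrix(rnorm(m * n), m, n,
                  dimnames = list(sprintf("met%03d", seq_len(m)), ids))
  if (planted > 0)
    for (j in seq_len(planted))
      feats[j, ] <- y + rnorm(n, 0, 0.2)
  cov <- data.frame(sample_id = ids,
                    sex = sample(c("F", "M"), n, TRUE),
                    bmi = rnorm(n, 23, 3),
                    timepoint = factor(sample(1:3, n, TRUE)))
  list(y = y, feats = feature_table(feats, "metabolome", "pareto_log"),
       cov = cov)
}

test_that("null features are calibrated and planted signals detected", {
  fx <- make_assoc_fixture(n = 500, m = 200, planted = 3, seed = 2)
  res <- adjusted_feature_associations(fx$y, fx$feats, fx$cov)
  expect_identical(nrow(res), 200L)
  expect_equal(res$p_adj, pmin(1, res$p * 200))
  sig <- res$feature_id[res$p_adj < 0.05]
  expect_true(all(sprintf("met%03d", 1:3) %in% sig))
  expect_true(all(res$rho[match(sprintf("met%03d", 1:3), res$feature_id)] >
                    0.9))
  null_part <- res[-(1:3), ]
  expect_true(all(abs(null_part$rho) < 0.2))
  expect_lt(abs(mean(null_part$p < 0.05) - 0.05), 0.03)
  expect_true(all(null_part$p_adj[null_part$p > 0.5] == 1))
})

test_that("Bonferroni adjustment and rank-deficiency guards behave", {
  fx <- make_assoc_fixture(n = 60, m = 10, seed = 3)
  res <- adjusted_feature_associations(fx$y, fx$feats, fx$cov)
  expect_equal(res$p_adj, pmin(1, res$p * 10))
  # duplicated covariate columns alias each other
  bad <- fx$cov
  bad$bmi2 <- bad$bmi
  expect_error(adjusted_feature_associations(fx$y, fx$feats, bad),
               "alias")
})

test_that("residual-residual Spearman reduces to plain Spearman without covariates", {
  fx <- make_assoc_fixture(n = 80, m = 5, seed = 4)
  const_cov <- data.frame(sample_id = fx$cov$sample_id, site = "campus")
  expect_message(
    res <- adjusted_feature_associations(fx$y, fx$feats, const_cov),
    "constant")
  plain <- apply(fx$feats$values, 1,
                 function(f) cor(fx$y, f[names(fx$y)], method = "spearman"))
  expect_equal(res$rho, unname(plain[res$feature_id]), tolerance = 1e-10)
})

test_that("sequential explained variance respects order and exact fits", {
  set.seed(5)
  n <- 300
  g <- factor(sample(letters[1:4], n, TRUE))
  y <- as.numeric(g == "a")  # y exactly a one-hot function of g
  ev <- suppressWarnings(explained_variance(y, data.frame(state = g)))
  expect_equal(ev$pct_variance[ev$predictor == "state"], 100,
               tolerance = 1e-9)
  expect_equal(ev$pct_variance[ev$predictor == "Residuals"], 0,
               tolerance = 1e-9)

  # balanced orthogonal two-factor design: shares order-invariant
  f1 <- factor(rep(c("u", "v"), each = 50))
  f2 <- factor(rep(rep(c("x", "y"), each = 25), 2))
  yy <- rnorm(100)
  e12 <- explained_variance(yy, data.frame(a = f1, b = f2))
  e21 <- explained_variance(yy, data.frame(b = f2, a = f1))
  expect_equal(e12$pct_variance[e12$predictor == "a"],
               e21$pct_variance[e21$predictor == "a"], tolerance = 1e-9)
  expect_lte(sum(e12$pct_variance[e12$predictor != "Residuals"]), 100)
  expect_equal(sum(e12$pct_variance), 100, tolerance = 1e-9)
})

test_that("an equal-variance state effect explains about half the variance", {
  set.seed(6)
  n <- 2000
  state <- factor(sample(1:4, n, TRUE))
  eff <- c(-1.2, -0.4, 0.4, 1.2)[state]  # variance ~ 0.8^2... scaled below
  eff <- eff / sd(eff)                   # unit-variance state effect
  y <- eff + rnorm(n)
  ev <- explained_variance(y, data.frame(state = state))
  expect_lt(abs(ev$pct_variance[ev$predictor == "state"] - 50), 3)
})

test_that("per-subject dissimilarity regressions return univariable betas", {
  set.seed(7)
  x <- rnorm(50)
  out <- suppressWarnings(
    dissimilarity_regressions(2 * x, data.frame(pred = x)))
  expect_equal(out$beta, 2, tolerance = 1e-9)
  expect_lt(out$p, 1e-12)

  null <- dissimilarity_regressions(rnorm(500),
                                    data.frame(a = rnorm(500),
                                               b = rnorm(500)),
                                    bonferroni = TRUE)
  expect_true(all(abs(null$beta) < 0.2))
  expect_true(all(null$p_adj >= null$p))
  expect_error(dissimilarity_regressions(rnorm(3),
                                         data.frame(a = rnorm(3))), "5")
})

test_that("a stabilizing genus gets a negative dissimilarity effect", {
  co <- generate_cohort(slim_cfg(n_subjects = 120, seed = 23,
                                 stabilizer_genus = "Faecalibacterium"))
  dm <- distance_matrix(relabund_transform(co$taxa), "bray_curtis")
  pp <- partition_dissimilarity(dm, study_meta(co))
  clr <- clr_transform(co$taxa)
  subj <- study_meta(co)$subject_id[match(colnames(clr$values),
                                          study_meta(co)$sample_id)]
  mean_clr <- tapply(clr$values["Faecalibacterium", ], subj, mean)
  sm <- pp$subject_median
  out <- dissimilarity_regressions(
    sm$sqrt_median_intra,
    data.frame(Faecalibacterium = as.numeric(
      mean_clr[sm$subject_id])))
  expect_lt(out$beta, 0)
  expect_lt(out$p, 0.05)
})

test_that("rank tests cover Mann-Whitney, Kruskal-Wallis and Dunn", {
  # complete separation: U = 0 for the first group
  mw <- rank_tests(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3),
                   "mann_whitney")
  expect_equal(mw$U, 0)
  # identical groups: p = 1 under the tie convention
  tied <- rank_tests(rep(1, 6), rep(c("a", "b"), each = 3), "mann_whitney")
  expect_equal(tied$p_value, 1)
  kw <- rank_tests(1:9, rep(c("a", "b", "c"), each = 3), "kruskal_wallis")
  expect_equal(kw$H, 7.2, tolerance = 1e-12)
  dn <- rank_tests(1:9, rep(c("a", "b", "c"), each = 3), "dunn")
  expect_identical(nrow(dn), 3L)
  expect_true(all(dn$p_adj <= 1))
  expect_error(rank_tests(1:4, rep("a", 4), "mann_whitney"), "group")
  expect_error(rank_tests(1:4, rep(c("a", "b"), 2), "dunn"), "3 groups")
})
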