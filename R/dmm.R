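#' Dirichlet-multinomial log pmf
#'
#' Log probability of an integer count vector under a Dirichlet-multinomial
#' (multivariate Polya) distribution with parameter \code{alpha}. The
#' multinomial coefficient is included, so the values form a proper pmf over
#' all count vectors with the same total.
#'
#' @param counts nonnegative integer vector with positive total.
#' @param alpha strictly positive parameter vector, same length.
#' @return the log pmf value (scalar).
#' @export
dm_log_likelihood <- function(counts, alpha) {
  if (length(counts) != length(alpha))
    stop("`counts` and `alpha` must have the same length")
  if (any(alpha <= 0)) stop("`alpha` must be strictly positive")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("`counts` must be nonnegative integers")
  n <- sum(counts)
  if (n <= 0) stop("`counts` must have a positive total")
  a <- sum(alpha)
  lgamma(a) - lgamma(n + a) +
    sum(lgamma(counts + alpha) - lgamma(alpha)) +
    lgamma(n + 1) - sum(lgamma(counts + 1))
}

# Log pmf for every row of a samples x features count matrix, one column per
# component of `alphas` (K x G matrix). Returns S x K matrix.
dm_loglik_matrix <- function(x, alphas) {
  n <- rowSums(x)
  base <- lgamma(n + 1) - rowSums(lgamma(x + 1))
  out <- matrix(0, nrow(x), nrow(alphas))
  for (k in seq_len(nrow(alphas))) {
    a <- alphas[k, ]
    A <- sum(a)
    out[, k] <- lgamma(A) - lgamma(n + A) +
      rowSums(lgamma(sweep(x, 2, a, "+"))) - sum(lgamma(a)) + base
  }
  out
}

log_row_softmax <- function(m) {
  mx <- apply(m, 1, max)
  w <- exp(m - mx)
  w / rowSums(w)
}

# Negative log posterior of the mixture in log-alpha space:
#   -sum_s log sum_k pi_k f_k(x_s)  (f includes the multinomial coefficient)
#   - log prior: alpha_kj ~ Exponential(nu), flat Dirichlet(1,...,1) on pi,
#   - log-alpha Jacobian sum_kj log alpha_kj.
dmm_neg_log_posterior <- function(x, weights, alphas, nu) {
  lf <- dm_loglik_matrix(x, alphas)
  lw <- sweep(lf, 2, log(weights), "+")
  mx <- apply(lw, 1, max)
  ll <- sum(mx + log(rowSums(exp(lw - mx))))
  lprior <- sum(log(nu) - nu * alphas) + lgamma(length(weights))
  ljac <- sum(log(alphas))
  -(ll + lprior + ljac)
}

# One responsibility-weighted penalized fixed-point pass for one component's
# alpha vector (Minka-style, with the Exponential(nu) prior and the
# log-alpha Jacobian folded into the stationarity condition).
alpha_fixed_point <- function(x, r, alpha, nu, inner = 3, floor = 1e-10) {
  n <- rowSums(x)
  for (it in seq_len(inner)) {
    A <- sum(alpha)
    num <- colSums(r * (digamma(sweep(x, 2, alpha, "+")) -
                          matrix(digamma(alpha), nrow(x), length(alpha),
                                 byrow = TRUE)))
    den <- sum(r * (digamma(n + A) - digamma(A)))
    alpha <- pmax((alpha * num + 1) / (den + nu), floor)
  }
  alpha
}

#' Fit a Dirichlet multinomial mixture by EM
#'
#' Maximum a posteriori EM for a K-component Dirichlet-multinomial mixture
#' over genus-level counts. Each alpha element carries a weak
#' Exponential(\code{nu}) prior and the mixture weights a flat Dirichlet
#' prior; estimation is carried out in log-alpha space so the posterior mode
#' matches the Laplace evidence construction in
#' [laplace_neg_log_evidence()]. The E-step computes responsibilities, the
#' M-step updates weights in closed form and alphas by a penalized
#' fixed-point pass with backtracking, which makes the negative log
#' posterior non-increasing across iterations.
#'
#' @param t raw, core-filtered taxa \code{feature_table}.
#' @param K number of mixture components; must be below the sample count.
#' @param seed integer seed (initialization and restarts).
#' @param tol relative change in negative log posterior declaring
#'   convergence, default 1e-6.
#' @param max_iter EM iteration cap, default 1000.
#' @param n_restarts number of initializations (first is k-means on CLR
#'   proportions, the rest random responsibilities), default 5.
#' @param nu rate of the Exponential prior on alpha elements, default 0.1.
#' @return an object of class \code{dmm_fit} with elements \code{K},
#'   \code{weights}, \code{alphas} (K x features), \code{responsibilities}
#'   (samples x K), \code{nll_trace} (negative log posterior per iteration
#'   of the winning run), \code{neg_log_posterior}, \code{converged},
#'   \code{n_iter}, \code{nu}, \code{seed}.
#' @export
fit_dmm <- function(t, K, seed, tol = 1e-6, max_iter = 1000, n_restarts = 5,
                    nu = 0.1) {
  stopifnot(inherits(t, "feature_table"))
  x <- base::t(t$values)  # samples x features
  if (any(rowSums(x) <= 0)) stop("every sample must have a positive total")
  if (nrow(x) <= K) stop("need more samples than mixture components")
  if (K < 1) stop("K must be >= 1")
  best <- NULL
  with_rng_seed(seed, {
    for (rs in seq_len(n_restarts)) {
      r0 <- dmm_init_resp(x, K, kmeans_init = (rs == 1))
      run <- dmm_em_run(x, r0, nu, tol, max_iter)
      if (is.null(best) || run$neg_log_posterior < best$neg_log_posterior)
        best <- run
      if (K == 1) break  # restarts are identical for a single component
    }
  })
  best$seed <- seed
  best$nu <- nu
  best$sample_ids <- colnames(t$values)
  best$feature_ids <- rownames(t$values)
  rownames(best$responsibilities) <- best$sample_ids
  colnames(best$alphas) <- best$feature_ids
  class(best) <- "dmm_fit"
  best
}

# Initial responsibilities: k-means on CLR proportions, or random Dirichlet.
dmm_init_resp <- function(x, K, kmeans_init) {
  S <- nrow(x)
  if (K == 1) return(matrix(1, S, 1))
  if (kmeans_init) {
    p <- log(x + 1)
    p <- p - rowMeans(p)
    km <- tryCatch(stats::kmeans(p, centers = K, nstart = 3),
                   error = function(e) NULL)
    if (!is.null(km)) {
      r <- matrix(0.1 / (K - 1), S, K)
      r[cbind(seq_len(S), km$cluster)] <- 0.9
      return(r)
    }
  }
  g <- matrix(stats::rexp(S * K), S, K)
  g / rowSums(g)
}

dmm_em_run <- function(x, r, nu, tol, max_iter) {
  S <- nrow(x); G <- ncol(x); K <- ncol(r)
  # M-step from initial responsibilities
  weights <- colMeans(r)
  alphas <- matrix(0, K, G)
  for (k in seq_len(K)) {
    m <- colSums(r[, k] * (x / rowSums(x))) / sum(r[, k])
    alphas[k, ] <- pmax(m, 1e-6) * 10  # moment-flavored start, scale ~10
    alphas[k, ] <- alpha_fixed_point(x, r[, k], alphas[k, ], nu, inner = 5)
  }
  nlp <- dmm_neg_log_posterior(x, weights, alphas, nu)
  trace <- nlp
  converged <- FALSE
  reinit_used <- rep(FALSE, K)
  iter <- 0
  for (iter in seq_len(max_iter)) {
    # E-step
    lf <- dm_loglik_matrix(x, alphas)
    r <- log_row_softmax(sweep(lf, 2, log(weights), "+"))
    # empty-component handling: re-initialize once, then drop
    wk <- colMeans(r)
    empty <- which(wk < 1e-8)
    if (length(empty)) {
      for (k in empty) {
        if (!reinit_used[k]) {
          r[, k] <- stats::runif(S, 0.05, 0.15)
          r <- r / rowSums(r)
          reinit_used[k] <- TRUE
        }
      }
      wk <- colMeans(r)
      dead <- which(wk < 1e-8 & reinit_used)
      if (length(dead)) {
        warning("dropping ", length(dead), " empty mixture component(s)")
        keep <- setdiff(seq_len(K), dead)
        r <- r[, keep, drop = FALSE] / rowSums(r[, keep, drop = FALSE])
        alphas <- alphas[keep, , drop = FALSE]
        reinit_used <- reinit_used[keep]
        K <- length(keep)
        nlp <- Inf  # objective changed dimension; reset reference
      }
    }
    # M-step
    new_w <- colMeans(r)
    new_a <- alphas
    for (k in seq_len(K))
      new_a[k, ] <- alpha_fixed_point(x, r[, k], alphas[k, ], nu, inner = 3)
    new_nlp <- dmm_neg_log_posterior(x, new_w, new_a, nu)
    # Backtrack the alpha step (in log space) if the objective worsened;
    # the weight update alone is exact and cannot worsen it.
    tries <- 0
    while (is.finite(nlp) && new_nlp > nlp + 1e-9 && tries < 12) {
      new_a <- exp((log(new_a) + log(alphas)) / 2)
      new_nlp <- dmm_neg_log_posterior(x, new_w, new_a, nu)
      tries <- tries + 1
    }
    if (is.finite(nlp) && new_nlp > nlp) {
      new_a <- alphas
      new_nlp <- dmm_neg_log_posterior(x, new_w, new_a, nu)
    }
    rel <- if (is.finite(nlp)) abs(nlp - new_nlp) / (abs(nlp) + 1e-12) else Inf
    weights <- new_w; alphas <- new_a
    trace <- c(trace, new_nlp)
    done <- is.finite(nlp) && rel < tol
    nlp <- new_nlp
    if (done) { converged <- TRUE; break }
  }
  lf <- dm_loglik_matrix(x, alphas)
  r <- log_row_softmax(sweep(lf, 2, log(weights), "+"))
  list(K = K, weights = weights, alphas = alphas, responsibilities = r,
       nll_trace = trace, neg_log_posterior = nlp,
       converged = converged, n_iter = iter)
}

#' @export
print.dmm_fit <- function(x, ...) {
  cat(sprintf(
    "dmm_fit: K=%d, %d samples, %d features, -log posterior %.2f (%s, %d iter)\n",
    x$K, nrow(x$responsibilities), ncol(x$alphas), x$neg_log_posterior,
    if (x$converged) "converged" else "max iterations", x$n_iter))
  invisible(x)
}

#' Laplace approximation to the negative log model evidence
#'
#' Approximates the negative log marginal likelihood of a fitted DMM at its
#' posterior mode, in log-alpha space: negative log posterior at the mode,
#' minus \code{d/2 * log(2*pi)}, plus half the log-determinant of the
#' Hessian, with \code{d = K*G + (K-1)} free parameters. The alpha-block
#' Hessian uses the responsibility-weighted (complete-data) curvature, the
#' standard construction for mixture evidence at the mode; the weight block
#' is exact given the component densities. A non-positive-definite block is
#' jittered by 1e-8 on the diagonal (reported via message).
#'
#' @param fit a \code{dmm_fit}.
#' @param t the \code{feature_table} the fit was computed on.
#' @return scalar negative log evidence (lower is better).
#' @export
laplace_neg_log_evidence <- function(fit, t) {
  stopifnot(inherits(fit, "dmm_fit"), inherits(t, "feature_table"))
  x <- base::t(t$values)
  K <- fit$K; G <- ncol(x)
  alphas <- fit$alphas; weights <- fit$weights; nu <- fit$nu
  r <- fit$responsibilities
  n <- rowSums(x)
  d <- K * G + (K - 1)
  logdet <- 0
  for (k in seq_len(K)) {
    a <- alphas[k, ]; A <- sum(a); rk <- r[, k]
    xa <- sweep(x, 2, a, "+")
    # weighted gradient of the log-likelihood part wrt alpha
    g <- colSums(rk * (digamma(xa) -
                         matrix(digamma(a), nrow(x), G, byrow = TRUE)))
    g <- g - sum(rk * (digamma(n + A) - digamma(A)))
    # negative Hessian of the weighted log-likelihood wrt alpha:
    #   diag_j sum_s r_sk [psi'(a_j) - psi'(x_sj + a_j)]
    #   - (sum_s r_sk [psi'(A) - psi'(n_s + A)]) * 1 1'
    diag_part <- colSums(rk * (matrix(trigamma(a), nrow(x), G, byrow = TRUE) -
                                 trigamma(xa)))
    c_all <- sum(rk * (trigamma(A) - trigamma(n + A)))
    H <- matrix(-c_all, G, G)
    diag(H) <- diag(H) + diag_part
    # to log-alpha space: H_theta = (a a') * H_alpha + diag(-a * g),
    # plus the Exponential prior curvature diag(nu * a); the Jacobian term
    # -sum(theta) has zero curvature.
    Ht <- H * tcrossprod(a) + diag(-a * g + nu * a, G)
    logdet <- logdet + safe_log_det(Ht)
  }
  if (K > 1) {
    # weight block over the first K-1 free simplex coordinates, exact given
    # the component densities: H_ab = sum_s u_sa u_sb with
    # u_sa = r_sa / pi_a - r_sK / pi_K.
    u <- sweep(r[, -K, drop = FALSE], 2, weights[-K], "/") -
      r[, K] / weights[K]
    logdet <- logdet + safe_log_det(crossprod(u))
  }
  nlp <- dmm_neg_log_posterior(x, weights, alphas, nu)
  nlp - 0.5 * d * log(2 * pi) + 0.5 * logdet
}

safe_log_det <- function(m) {
  ch <- tryCatch(chol(m), error = function(e) NULL)
  if (is.null(ch)) {
    message("laplace evidence: non-PD Hessian block, adding 1e-8 jitter")
    ch <- chol(m + diag(1e-8, nrow(m)))
  }
  2 * sum(log(diag(ch)))
}

#' Select the number of community types by Laplace evidence
#'
#' Fits a DMM for each candidate K and returns the fit minimizing the
#' Laplace negative log evidence; ties within 1e-6 resolve to the smaller
#' K. The full evidence-versus-K table is attached as attribute
#' \code{"evidence_table"}.
#'
#' @param t raw, core-filtered taxa \code{feature_table}.
#' @param k_range candidate component counts, default \code{1:7}.
#' @param seed integer seed.
#' @inheritParams fit_dmm
#' @return the winning \code{dmm_fit}, with the evidence table attached.
#' @export
select_k <- function(t, k_range = 1:7, seed = 1, tol = 1e-6, max_iter = 1000,
                     n_restarts = 5, nu = 0.1) {
  fits <- vector("list", length(k_range))
  ev <- numeric(length(k_range))
  for (i in seq_along(k_range)) {
    fits[[i]] <- fit_dmm(t, k_range[i], seed = seed + i - 1, tol = tol,
                         max_iter = max_iter, n_restarts = n_restarts,
                         nu = nu)
    ev[i] <- laplace_neg_log_evidence(fits[[i]], t)
  }
  tab <- data.frame(K = k_range, neg_log_posterior =
                      vapply(fits, function(f) f$neg_log_posterior, 0),
                    laplace = ev,
                    converged = vapply(fits, function(f) f$converged, TRUE))
  best <- which(ev <= min(ev) + 1e-6)[1]  # ties resolve to smaller K
  out <- fits[[best]]
  attr(out, "evidence_table") <- tab
  out
}

#' Assign each sample its community type
#'
#' Argmax responsibility per sample; exact ties resolve to the lowest
#' component index and are reported via message.
#'
#' @param fit a \code{dmm_fit}.
#' @return data.frame with \code{sample_id}, \code{state} (integer label)
#'   and \code{posterior} (maximum responsibility).
#' @export
assign_types <- function(fit) {
  stopifnot(inherits(fit, "dmm_fit"))
  r <- fit$responsibilities
  lab <- max.col(r, ties.method = "first")
  post <- r[cbind(seq_len(nrow(r)), lab)]
  n_tie <- sum(apply(r, 1, function(z) sum(z == max(z)) > 1))
  if (n_tie) message("assign_types: ", n_tie, " tie(s) broken to lowest index")
  data.frame(sample_id = rownames(r), state = lab, posterior = post,
             stringsAsFactors = FALSE)
}

#' Match estimated state labels to reference labels
#'
#' Searches all label permutations (K up to 8) and returns the one
#' maximizing agreement with a reference labeling — the standard fix for
#' label switching when scoring mixture recovery against ground truth.
#'
#' @param est integer estimated labels.
#' @param truth reference labels, same length.
#' @return list with \code{accuracy}, the best \code{permutation} (index k
#'   in \code{est} maps to \code{permutation[k]}), and \code{relabelled}.
#' @export
match_state_labels <- function(est, truth) {
  stopifnot(length(est) == length(truth))
  truth <- as.integer(factor(truth))
  est <- as.integer(factor(est))
  K <- max(est, truth)
  if (K > 8) stop("label matching supports up to 8 states")
  perms <- all_permutations(K)
  best_acc <- -1; best_p <- seq_len(K)
  for (i in seq_len(nrow(perms))) {
    acc <- mean(perms[i, est] == truth)
    if (acc > best_acc) { best_acc <- acc; best_p <- perms[i, ] }
  }
  list(accuracy = best_acc, permutation = best_p,
       relabelled = best_p[est])
}

all_permutations <- function(K) {
  if (K == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(K - 1)
  out <- matrix(0L, nrow(sub) * K, K)
  row <- 1
  for (i in seq_len(nrow(sub))) {
    for (pos in seq_len(K)) {
      out[row, ] <- append(sub[i, ], K, after = pos - 1)
      row <- row + 1
    }
  }
  out
}
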