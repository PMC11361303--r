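#' Configuration for the synthetic longitudinal cohort
#'
#' Defaults emulate a dormitory cohort sampled at the start, middle and end
#' of an academic year: 93 subjects x 3 timepoints, four community states
#' with baseline proportions 38/21/22/12 over 93, and first-order Markov
#' state dynamics with a stay probability of 0.72 (so the chance of keeping
#' the baseline state across both steps is 0.72^2, i.e. roughly half the
#' subjects shift at least once). Genus counts are Dirichlet-multinomial
#' within state; the function layer is a noisy nonnegative linear mixing of
#' taxa; the metabolome layer has designed per-feature intraclass
#' correlations and replicate QC pools.
#'
#' @param n_subjects number of subjects, default 93.
#' @param n_timepoints samples per subject, default 3.
#' @param n_states number of community states, default 4.
#' @param baseline_probs initial state probabilities, default
#'   \code{c(38, 21, 22, 12) / 93}.
#' @param stay_prob per-step probability of keeping the current state,
#'   default 0.72 (1 gives a frozen chain); off-diagonal mass is uniform
#'   unless \code{transition_matrix} is supplied.
#' @param transition_matrix optional full row-stochastic
#'   \code{n_states x n_states} matrix overriding \code{stay_prob}.
#' @param n_genera number of genera, default 60 (minimum 8).
#' @param concentration total Dirichlet concentration per state, default 50
#'   (a free scale parameter: smaller means more within-state
#'   overdispersion).
#' @param depth_log_mean,depth_log_sd natural-log mean and sd of per-sample
#'   sequencing depth; defaults \code{log(5000)} and 0.3 keep simulations
#'   quick, while \code{log(40000)} mirrors typical amplicon depths.
#' @param n_pathways function-layer features, default 120.
#' @param loading_noise_sd natural-log sd of the multiplicative noise on the
#'   function layer, default 0.3.
#' @param n_metabolites metabolome features, default 200.
#' @param metabolome_icc_range range the per-metabolite true ICC is drawn
#'   from, default \code{c(0.3, 0.9)}.
#' @param metabolome_total_var total log10-scale variance per metabolite,
#'   default 0.04 (split between subject and residual by the drawn ICC).
#' @param n_qc_pools replicate QC pool injections, default 5.
#' @param qc_cv coefficient of variation of QC pool replicates, default 0.05.
#' @param stabilizer_genus optional genus name; when set, subjects with a
#'   higher propensity for that genus get a higher stay probability,
#'   planting a negative association between its CLR abundance and
#'   within-subject compositional change.
#' @param seed integer seed, default 1.
#' @return a validated list of class \code{cohort_config}.
#' @export
cohort_config <- function(n_subjects = 93, n_timepoints = 3, n_states = 4,
                          baseline_probs = c(38, 21, 22, 12) / 93,
                          stay_prob = 0.72, transition_matrix = NULL,
                          n_genera = 60, concentration = 50,
                          depth_log_mean = log(5000), depth_log_sd = 0.3,
                          n_pathways = 120, loading_noise_sd = 0.3,
                          n_metabolites = 200,
                          metabolome_icc_range = c(0.3, 0.9),
                          metabolome_total_var = 0.04,
                          n_qc_pools = 5, qc_cv = 0.05,
                          stabilizer_genus = NULL, seed = 1) {
  if (abs(sum(baseline_probs) - 1) > 1e-12)
    stop("`baseline_probs` must sum to 1")
  if (any(baseline_probs < 0)) stop("`baseline_probs` must be nonnegative")
  if (length(baseline_probs) != n_states)
    stop("`baseline_probs` must have one entry per state")
  if (stay_prob <= 0 || stay_prob > 1)
    stop("`stay_prob` must lie in (0, 1]")
  if (!is.null(transition_matrix)) {
    if (!all(dim(transition_matrix) == c(n_states, n_states)) ||
        any(transition_matrix < 0) ||
        any(abs(rowSums(transition_matrix) - 1) > 1e-9))
      stop("`transition_matrix` must be row-stochastic n_states x n_states")
  }
  structure(as.list(environment()), class = "cohort_config")
}

#' Default per-state Dirichlet parameters
#'
#' Builds four alpha vectors over \code{G} genera, each dominated by a
#' distinct marker genus: two Bacteroides-like markers (for the two
#' Bacteroides-led states), one Blautia-like and one Prevotella-like. The
#' dominant marker's expected relative abundance exceeds three times any
#' non-marker genus.
#'
#' @param G number of genera, at least 8.
#' @param concentration total concentration (sum of each alpha vector).
#' @return a 4 x G matrix of strictly positive alphas with genus names
#'   (\code{Bacteroides}, \code{Phocaeicola}, \code{Blautia},
#'   \code{Prevotella}, \code{Faecalibacterium}, then \code{genus_06}...).
#' @export
default_state_alphas <- function(G, concentration = 50) {
  if (G < 8) stop("need at least 8 genera to place the marker blocks")
  genera <- c("Bacteroides", "Phocaeicola", "Blautia", "Prevotella",
              "Faecalibacterium",
              sprintf("genus_%02d", seq_len(max(G - 5, 0)) + 5))[seq_len(G)]
  markers <- 1:4
  rest <- setdiff(seq_len(G), markers)
  w <- matrix(0, 4, G)
  # non-marker genera are capped at 0.08 expected share so the dominant
  # marker always exceeds 3x any of them; any leftover mass goes to the
  # dominant marker (matters only for small G)
  rest_w <- min(0.55 / length(rest), 0.08)
  for (s in 1:4) {
    w[s, markers] <- 0.05
    w[s, rest] <- rest_w
    w[s, markers[s]] <- 0.30 + (0.55 - rest_w * length(rest))
  }
  alphas <- w * concentration
  colnames(alphas) <- genera
  rownames(alphas) <- c("Bact1", "Bact2", "Blau", "Prev")
  alphas
}

#' Generate a synthetic three-layer longitudinal cohort
#'
#' Simulates subject state trajectories from a first-order Markov chain,
#' genus counts from the per-state Dirichlet-multinomial, a function layer
#' as a noisy nonnegative linear mixing of the taxa relative abundances,
#' and a metabolome layer with designed per-feature ICCs plus replicate QC
#' pools. Deterministic for a fixed seed.
#'
#' @param cfg a [cohort_config()].
#' @return list with \code{taxa}, \code{fun}, \code{metabolome}
#'   (\code{feature_table}s; the metabolome includes the QC pool columns),
#'   \code{meta} (sample metadata data.frame) and \code{truth} (state
#'   trajectories, state alphas, loading matrix, true metabolite ICCs).
#' @export
generate_cohort <- function(cfg = cohort_config()) {
  stopifnot(inherits(cfg, "cohort_config"))
  S <- cfg$n_subjects; T <- cfg$n_timepoints; K <- cfg$n_states
  G <- cfg$n_genera
  alphas <- default_state_alphas(G, cfg$concentration)[seq_len(K), ,
                                                       drop = FALSE]
  genera <- colnames(alphas)
  out <- with_rng_seed(cfg$seed, {
    subj <- sprintf("S%03d", seq_len(S))
    # optional stabilizer propensity shifts both the genus alpha and the
    # per-subject stay probability
    f_prop <- rep(0, S)
    stab_idx <- NULL
    if (!is.null(cfg$stabilizer_genus)) {
      stab_idx <- match(cfg$stabilizer_genus, genera)
      if (is.na(stab_idx)) stop("unknown stabilizer genus: ",
                                cfg$stabilizer_genus)
      f_prop <- stats::runif(S, -1, 1)
    }
    stay_i <- pmin(pmax(cfg$stay_prob + 0.25 * f_prop, 0.02), 0.98)
    # Markov trajectories
    traj <- matrix(0L, S, T, dimnames = list(subj, NULL))
    traj[, 1] <- sample.int(K, S, replace = TRUE, prob = cfg$baseline_probs)
    for (tt in seq_len(T - 1)) {
      for (i in seq_len(S)) {
        cur <- traj[i, tt]
        if (!is.null(cfg$transition_matrix)) {
          traj[i, tt + 1] <- sample.int(K, 1,
                                        prob = cfg$transition_matrix[cur, ])
        } else {
          p <- rep((1 - stay_i[i]) / (K - 1), K)
          p[cur] <- stay_i[i]
          traj[i, tt + 1] <- sample.int(K, 1, prob = p)
        }
      }
    }
    samp <- as.vector(outer(subj, seq_len(T),
                            function(s, tt) sprintf("%s_T%d", s, tt)))
    n_samp <- S * T
    # taxa counts
    depth <- pmax(round(stats::rlnorm(n_samp, cfg$depth_log_mean,
                                      cfg$depth_log_sd)), 100)
    taxa <- matrix(0L, G, n_samp, dimnames = list(genera, samp))
    rel <- matrix(0, G, n_samp, dimnames = list(genera, samp))
    for (tt in seq_len(T)) for (i in seq_len(S)) {
      j <- (tt - 1) * S + i
      a <- alphas[traj[i, tt], ]
      if (!is.null(stab_idx))
        a[stab_idx] <- a[stab_idx] * exp(1.5 * f_prop[i])
      p <- stats::rgamma(G, shape = a, rate = 1)
      p <- p / sum(p)
      rel[, j] <- p
      taxa[, j] <- as.integer(stats::rmultinom(1, depth[j], p))
    }
    # function layer: relative abundances x nonnegative loadings, scaled,
    # with multiplicative lognormal noise
    P <- cfg$n_pathways
    L <- matrix(0, G, P, dimnames = list(genera, sprintf("PWY_%03d",
                                                         seq_len(P))))
    for (pw in seq_len(P)) {
      src <- sample.int(G, 8)
      L[src, pw] <- stats::rgamma(8, shape = 2, rate = 1)
    }
    L <- sweep(L, 2, colSums(L), "/")
    fun <- crossprod(L, rel) * 1e5 *
      matrix(exp(stats::rnorm(P * n_samp, 0, cfg$loading_noise_sd)),
             P, n_samp)
    dimnames(fun) <- list(colnames(L), samp)
    # metabolome: lognormal with subject random effect sized by the ICC
    M <- cfg$n_metabolites
    met_icc <- stats::runif(M, cfg$metabolome_icc_range[1],
                            cfg$metabolome_icc_range[2])
    met_mu <- stats::runif(M, 3, 6)
    var_b <- met_icc * cfg$metabolome_total_var
    var_w <- (1 - met_icc) * cfg$metabolome_total_var
    b <- matrix(stats::rnorm(M * S, 0, sqrt(var_b)), M, S)
    met <- matrix(0, M, n_samp,
                  dimnames = list(sprintf("met_%03d", seq_len(M)), samp))
    for (tt in seq_len(T)) for (i in seq_len(S)) {
      j <- (tt - 1) * S + i
      met[, j] <- 10 ^ (met_mu + b[, i] +
                          stats::rnorm(M, 0, sqrt(var_w)))
    }
    # QC pools: replicate draws around the global metabolite mean
    qc_ids <- sprintf("QC_%d", seq_len(cfg$n_qc_pools))
    gm <- rowMeans(met)
    qc <- matrix(pmax(gm * (1 + stats::rnorm(M * cfg$n_qc_pools, 0,
                                             cfg$qc_cv)), 0),
                 M, cfg$n_qc_pools, dimnames = list(rownames(met), qc_ids))
    # metadata
    sex <- sample(c("F", "M"), S, replace = TRUE, prob = c(0.65, 0.35))
    race <- sample(c("White", "Hispanic", "Asian", "Other"), S,
                   replace = TRUE, prob = c(0.45, 0.25, 0.2, 0.1))
    bmi <- round(stats::rnorm(S, 23, 3), 1)
    gpa <- round(pmin(pmax(stats::rnorm(S, 3.07, 0.73), 0), 4.33), 2)
    meta <- data.frame(
      sample_id = samp,
      subject_id = rep(subj, times = T),
      timepoint = rep(seq_len(T), each = S),
      collection_day = rep((seq_len(T) - 1) * 120, each = S) +
        sample.int(14, n_samp, replace = TRUE) - 1,
      sex = rep(sex, times = T),
      race_ethnicity = rep(race, times = T),
      bmi = rep(bmi, times = T),
      gpa = rep(gpa, times = T),
      is_qc_pool = FALSE,
      stringsAsFactors = FALSE)
    meta_qc <- data.frame(
      sample_id = qc_ids, subject_id = "QC_POOL", timepoint = NA_integer_,
      collection_day = NA_integer_, sex = NA_character_,
      race_ethnicity = NA_character_, bmi = NA_real_, gpa = NA_real_,
      is_qc_pool = TRUE, stringsAsFactors = FALSE)
    list(
      taxa = feature_table(taxa, "taxa", "raw"),
      fun = feature_table(fun, "function", "raw"),
      metabolome = feature_table(cbind(met, qc), "metabolome", "raw"),
      meta = validate_metadata(rbind(meta, meta_qc)),
      truth = list(trajectories = traj, state_alphas = alphas,
                   loading_matrix = L, metabolite_icc = met_icc,
                   metabolite_mu = met_mu, stay_prob_subject = stay_i,
                   stabilizer_propensity = f_prop, config = cfg,
                   seed = cfg$seed))
  })
  out
}
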