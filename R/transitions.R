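#' Construct a trajectory set
#'
#' @param states integer or character matrix, one row per subject (rownames
#'   = subject ids) and one ordered column per timepoint.
#' @param levels the full state label set; defaults to the sorted unique
#'   states observed.
#' @return object of class \code{trajectories}.
#' @export
trajectories <- function(states, levels = NULL) {
  if (!is.matrix(states)) stop("`states` must be a subjects x timepoints matrix")
  if (is.null(rownames(states))) stop("`states` needs subject ids as rownames")
  if (is.null(levels)) levels <- sort(unique(as.vector(states)))
  if (!all(states %in% levels)) stop("state outside the declared level set")
  structure(list(states = states, levels = levels), class = "trajectories")
}

#' @export
print.trajectories <- function(x, ...) {
  cat(sprintf("trajectories: %d subjects x %d timepoints, %d states\n",
              nrow(x$states), ncol(x$states), length(x$levels)))
  invisible(x)
}

n_transitions <- function(trajs) nrow(trajs$states) * (ncol(trajs$states) - 1)

# all ordered (from, to) transition pairs as a 2-column matrix
transition_pairs <- function(trajs) {
  s <- trajs$states
  Tn <- ncol(s)
  from <- as.vector(s[, -Tn, drop = FALSE])
  to <- as.vector(s[, -1, drop = FALSE])
  cbind(from = from, to = to)
}

#' Build per-subject state trajectories from assignments
#'
#' Joins community-type assignments to sample metadata and keeps subjects
#' with exactly one assigned sample at every timepoint; incomplete subjects
#' are excluded and reported via message.
#'
#' @param assign data.frame from [assign_types()] (\code{sample_id},
#'   \code{state}).
#' @param meta sample metadata with \code{sample_id}, \code{subject_id},
#'   \code{timepoint}.
#' @param timepoints the required ordered timepoint set; defaults to the
#'   sorted unique non-QC timepoints in \code{meta}.
#' @return a \code{trajectories} object.
#' @export
build_trajectories <- function(assign, meta, timepoints = NULL) {
  meta <- validate_metadata(meta)
  meta <- meta[!meta$is_qc_pool, , drop = FALSE]
  if (is.null(timepoints)) timepoints <- sort(unique(meta$timepoint))
  m <- merge(assign, meta[, c("sample_id", "subject_id", "timepoint")],
             by = "sample_id")
  m <- m[m$timepoint %in% timepoints, , drop = FALSE]
  key <- paste(m$subject_id, m$timepoint)
  if (anyDuplicated(key))
    stop("duplicate (subject, timepoint) assignment: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  subjects <- sort(unique(m$subject_id))
  st <- matrix(NA, length(subjects), length(timepoints),
               dimnames = list(subjects, NULL))
  idx <- cbind(match(m$subject_id, subjects), match(m$timepoint, timepoints))
  st[idx] <- m$state
  complete <- rowSums(is.na(st)) == 0
  if (any(!complete))
    message("build_trajectories: excluding ", sum(!complete),
            " incomplete subject(s): ",
            paste(subjects[!complete], collapse = ", "))
  if (!any(complete)) stop("no subject has a complete trajectory")
  trajectories(st[complete, , drop = FALSE],
               levels = sort(unique(assign$state)))
}

#' Classify subjects as stable or shifted
#'
#' A subject is stable iff all its states are identical; otherwise shifted.
#'
#' @param trajs a \code{trajectories} object.
#' @return data.frame with \code{subject_id} and \code{class}
#'   (\code{"stable-in-<state>"} or \code{"shifted"}); per-class counts are
#'   attached as attribute \code{"counts"}.
#' @export
classify_stability <- function(trajs) {
  stopifnot(inherits(trajs, "trajectories"))
  s <- trajs$states
  stable <- apply(s, 1, function(z) all(z == z[1]))
  cls <- ifelse(stable, paste0("stable-in-", s[, 1]), "shifted")
  out <- data.frame(subject_id = rownames(s), class = cls,
                    stringsAsFactors = FALSE)
  attr(out, "counts") <- table(cls)
  out
}

#' Expected transition probabilities under the prevalence null
#'
#' Default mode \code{"cross_pairing"}: the number of possible A-to-B
#' transitions is \code{sum_t n_A(t) * n_B(t+1)} over consecutive timepoint
#' pairs, where \code{n_X(t)} counts subjects in state X at time t, divided
#' by the total number of possible transitions \code{sum_t N_t * N_(t+1)}.
#' This accounts for the unequal distribution of samples across community
#' types. Mode \code{"pooled_marginal"}: \code{P(A -> B) = f_A * f_B} with
#' \code{f} the pooled state frequency over all samples.
#'
#' @param trajs a \code{trajectories} object.
#' @param mode \code{"cross_pairing"} (default) or \code{"pooled_marginal"}.
#' @return K x K matrix of probabilities summing to 1, states in the order
#'   of \code{trajs$levels}.
#' @export
expected_transition_probabilities <- function(trajs,
                                              mode = c("cross_pairing",
                                                       "pooled_marginal")) {
  stopifnot(inherits(trajs, "trajectories"))
  mode <- match.arg(mode)
  lv <- trajs$levels
  K <- length(lv)
  s <- trajs$states
  Tn <- ncol(s)
  if (Tn < 2) stop("need at least one consecutive timepoint pair")
  P <- matrix(0, K, K, dimnames = list(lv, lv))
  if (mode == "cross_pairing") {
    total <- 0
    for (tt in seq_len(Tn - 1)) {
      na <- table(factor(s[, tt], levels = lv))
      nb <- table(factor(s[, tt + 1], levels = lv))
      P <- P + outer(as.numeric(na), as.numeric(nb))
      total <- total + sum(na) * sum(nb)
    }
    P <- P / total
  } else {
    f <- table(factor(as.vector(s), levels = lv))
    f <- as.numeric(f) / sum(f)
    P <- outer(f, f)
    dimnames(P) <- list(lv, lv)
  }
  P
}

#' Transition goodness-of-fit against the prevalence null
#'
#' Tallies observed transitions over all subjects and consecutive
#' timepoints, derives expected frequencies from
#' [expected_transition_probabilities()], and reports the chi-square
#' goodness-of-fit statistic over all K^2 ordered categories (df = K^2 - 1),
#' Pearson standardized residuals (O - E)/sqrt(E), and flags for residuals
#' beyond +/-1.96. Cells with expected frequency below 1 are flagged as
#' unreliable.
#'
#' @param trajs a \code{trajectories} object.
#' @param expected_mode passed to [expected_transition_probabilities()].
#' @return object of class \code{transition_tally}: \code{table}
#'   (data.frame: from, to, observed, expected_prob, expected, residual,
#'   significant, low_expected), \code{statistic}, \code{df},
#'   \code{p_value}, \code{total_transitions}.
#' @export
transition_chisq <- function(trajs, expected_mode = "cross_pairing") {
  stopifnot(inherits(trajs, "trajectories"))
  lv <- trajs$levels
  K <- length(lv)
  pairs <- transition_pairs(trajs)
  total <- nrow(pairs)
  if (total < 1) stop("need at least one transition")
  O <- table(factor(pairs[, 1], levels = lv), factor(pairs[, 2], levels = lv))
  O <- matrix(as.numeric(O), K, K, dimnames = list(lv, lv))
  P <- expected_transition_probabilities(trajs, expected_mode)
  if (all(P == 0)) stop("expected probabilities are all zero")
  E <- P * total
  resid <- ifelse(E > 0, (O - E) / sqrt(E), NA_real_)
  cells <- E > 0
  stat <- sum((O[cells] - E[cells])^2 / E[cells])
  df <- K^2 - 1
  tab <- data.frame(from = rep(lv, times = K), to = rep(lv, each = K),
                    observed = as.vector(O), expected_prob = as.vector(P),
                    expected = as.vector(E), residual = as.vector(resid),
                    significant = as.vector(abs(resid) > 1.96),
                    low_expected = as.vector(E < 1),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 total_transitions = total, expected_mode = expected_mode),
            class = "transition_tally")
}

#' @export
print.transition_tally <- function(x, ...) {
  cat(sprintf(
    "transition_tally: %d transitions, X2=%.2f (df=%d), p=%.3g [%s null]\n",
    x$total_transitions, x$statistic, x$df, x$p_value, x$expected_mode))
  invisible(x)
}

#' Median dissimilarity per transition category
#'
#' For each ordered (from, to) category, the median dissimilarity between
#' each subject's source and destination samples, summarizing the
#' compositional change each kind of transition entails. Empty categories
#' are reported with NA.
#'
#' @param trajs a \code{trajectories} object.
#' @param dm a \code{distance_matrix} covering every trajectory sample.
#' @param meta sample metadata mapping (subject, timepoint) to sample ids.
#' @return data.frame: from, to, n, median_dissimilarity.
#' @export
transition_dissimilarity <- function(trajs, dm, meta) {
  stopifnot(inherits(trajs, "trajectories"), inherits(dm, "distance_matrix"))
  meta <- validate_metadata(meta)
  meta <- meta[!meta$is_qc_pool, , drop = FALSE]
  s <- trajs$states
  lv <- trajs$levels
  Tn <- ncol(s)
  timepoints <- sort(unique(meta$timepoint))[seq_len(Tn)]
  lookup <- function(subject, tp) {
    id <- meta$sample_id[meta$subject_id == subject & meta$timepoint == tp]
    if (length(id) != 1 || !(id %in% rownames(dm$matrix)))
      stop("sample for subject ", subject, " timepoint ", tp,
           " missing from the distance matrix")
    id
  }
  rows <- list()
  for (i in seq_len(nrow(s))) for (tt in seq_len(Tn - 1)) {
    a <- lookup(rownames(s)[i], timepoints[tt])
    b <- lookup(rownames(s)[i], timepoints[tt + 1])
    rows[[length(rows) + 1]] <- data.frame(
      from = s[i, tt], to = s[i, tt + 1], d = dm$matrix[a, b],
      stringsAsFactors = FALSE)
  }
  obs <- do.call(rbind, rows)
  grid <- expand.grid(from = lv, to = lv, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid$n <- 0L
  grid$median_dissimilarity <- NA_real_
  for (g in seq_len(nrow(grid))) {
    sel <- obs$from == grid$from[g] & obs$to == grid$to[g]
    grid$n[g] <- sum(sel)
    if (any(sel)) grid$median_dissimilarity[g] <- stats::median(obs$d[sel])
  }
  grid
}

#' Empirical Markov transition matrix
#'
#' Maximum-likelihood row-normalized transition counts; states with no
#' outgoing transitions get a uniform row and are flagged in the attribute
#' \code{"uniform_rows"}.
#'
#' @param trajs a \code{trajectories} object.
#' @return K x K row-stochastic matrix.
#' @export
empirical_markov <- function(trajs) {
  stopifnot(inherits(trajs, "trajectories"))
  lv <- trajs$levels
  pairs <- transition_pairs(trajs)
  if (nrow(pairs) < 1) stop("need at least one transition")
  O <- table(factor(pairs[, 1], levels = lv), factor(pairs[, 2], levels = lv))
  O <- matrix(as.numeric(O), length(lv), length(lv),
              dimnames = list(lv, lv))
  rs <- rowSums(O)
  uniform <- rs == 0
  P <- O / ifelse(rs == 0, 1, rs)
  P[uniform, ] <- 1 / length(lv)
  attr(P, "uniform_rows") <- lv[uniform]
  P
}
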