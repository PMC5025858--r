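# The nine-regressor trial GLM on sliding-window firing rates, the
# observational prediction-error contrasts, and cluster-based permutation
# inference on mean coefficient t-statistic time-courses.

#' Build the nine-regressor trial design matrix
#'
#' One row per card trial event, nine columns: the main effect of each
#' player role (self, obs1, obs2) and, for each role, the expected value of
#' the chosen deck and the signed amount won or lost as parametric
#' modulators. Modulators are mean-centred within their trial type so that
#' the main-effect columns capture trial-type means, are structurally zero
#' outside their trial type, and by default are scaled to unit variance so
#' that contrasts mixing amount (dollars) and expected value (probability)
#' columns weight both parts equally. The observational contrasts ride
#' along as an attribute: observed EV (sum of the two observed-EV
#' modulators), observed amount (sum of the two observed-amount modulators)
#' and observed PE = amount - EV.
#'
#' @param trials learner-augmented trial table with columns \code{player},
#'   \code{amount} and \code{chosen_ev}.
#' @param standardize scale each modulator column to unit SD within its
#'   trial type (default TRUE; t-statistics of single regressors are
#'   invariant to this, contrasts across regressors are balanced by it).
#' @return numeric matrix (trials x 9) of class \code{ob_design} with
#'   attributes \code{contrasts} (named list of length-9 vectors) and
#'   \code{players}.
#' @export
build_design_matrix <- function(trials, standardize = TRUE) {
  if (!"chosen_ev" %in% names(trials) || anyNA(trials$chosen_ev))
    stop("missing learner expected values (chosen_ev) for some events")
  roles <- c("self", "obs1", "obs2")
  if (!all(trials$player %in% roles)) stop("unknown player role in trials")
  n <- nrow(trials)
  X <- matrix(0, n, 9)
  colnames(X) <- c("self_main", "self_ev", "self_amount",
                   "obs1_main", "obs1_ev", "obs1_amount",
                   "obs2_main", "obs2_ev", "obs2_amount")
  for (k in seq_along(roles)) {
    sel <- trials$player == roles[k]
    j <- (k - 1) * 3
    X[sel, j + 1] <- 1
    X[sel, j + 2] <- trials$chosen_ev[sel] - mean(trials$chosen_ev[sel])
    X[sel, j + 3] <- trials$amount[sel] - mean(trials$amount[sel])
    if (standardize) for (jj in j + 2:3) {
      s <- stats::sd(X[sel, jj])
      if (s > 0) X[sel, jj] <- X[sel, jj] / s
    }
  }
  cv <- function(cols) { v <- numeric(9); v[cols] <- 1; v }
  contrasts <- list(obs_ev = cv(c(5, 8)),
                    obs_amount = cv(c(6, 9)),
                    obs_pe = cv(c(6, 9)) - cv(c(5, 8)))
  structure(X, contrasts = contrasts, players = trials$player,
            class = c("ob_design", "matrix", "array"))
}

# multi-bin OLS: coefficients, per-regressor and per-contrast t time-courses
ols_tcourses <- function(X, Y, contrasts = list()) {
  n <- nrow(X); p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("rank-deficient design; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  XtXi <- chol2inv(chol(crossprod(X)))
  A <- XtXi %*% t(X)
  B <- A %*% Y
  E <- Y - X %*% B
  s2 <- colSums(E * E) / (n - p)
  tmat <- B / sqrt(outer(diag(XtXi), s2))
  rownames(tmat) <- colnames(X)
  ct <- lapply(contrasts, function(cvec) {
    num <- drop(crossprod(cvec, B))
    num / sqrt(drop(t(cvec) %*% XtXi %*% cvec) * s2)
  })
  list(t = tmat, contrast_t = ct, df = n - p, B = B)
}

#' Sliding-window GLM of firing rate on the trial design
#'
#' Ordinary least squares of the per-trial rate estimate at every window
#' position on the nine-column design, over the peri-outcome span, yielding
#' t-statistic time-courses for every regressor and for the observational
#' contrasts.
#'
#' @param rm a \code{rate_matrix} aligned to the outcome.
#' @param design an \code{ob_design} whose rows align with the trials of
#'   \code{rm}.
#' @param span window-center span analysed, ms.
#' @return list with \code{t} (9 x bins), \code{contrast_t} (named list of
#'   time-courses), \code{df}, \code{centers}.
#' @export
fit_sliding_glm <- function(rm, design, span = c(-1000, 1500)) {
  stopifnot(inherits(rm, "rate_matrix"))
  if (nrow(design) != nrow(rm$rate))
    stop("design rows do not align with rate matrix trials")
  sel <- rm$centers >= span[1] & rm$centers <= span[2]
  fit <- ols_tcourses(unclass(design)[, , drop = FALSE],
                      rm$rate[, sel, drop = FALSE],
                      attr(design, "contrasts"))
  fit$centers <- rm$centers[sel]
  fit
}

# permuted-label contrast t-courses: trial labels are shuffled by permuting
# the rows of the rate matrix, the design stays fixed
permuted_tcourses <- function(rm, design, span = c(-1000, 1500),
                              n_perm = 100, seed = 1L,
                              courses = c("obs_ev", "obs_amount", "obs_pe",
                                          "self_amount")) {
  set.seed(as.integer(seed))
  sel <- rm$centers >= span[1] & rm$centers <= span[2]
  X <- unclass(design)
  Y <- rm$rate[, sel, drop = FALSE]
  n <- nrow(X); p <- ncol(X)
  XtXi <- chol2inv(chol(crossprod(X)))
  cons <- attr(design, "contrasts")
  cons$self_amount <- { v <- numeric(9); v[3] <- 1; v }
  cons <- cons[courses]
  cden <- vapply(cons, function(cvec) drop(t(cvec) %*% XtXi %*% cvec),
                 numeric(1))
  cmat <- do.call(rbind, cons)          # n_contrast x p
  # shuffling trial labels is equivalent to row-permuting the design;
  # Y'Y per bin is permutation invariant, so each permutation costs one
  # small cross-product instead of touching the rate matrix
  Y2 <- colSums(Y * Y)
  out <- lapply(cons, function(...) matrix(NA_real_, n_perm, ncol(Y)))
  for (r in seq_len(n_perm)) {
    Xp <- X[sample.int(n), , drop = FALSE]
    XtY <- crossprod(Xp, Y)             # p x bins
    B <- XtXi %*% XtY
    s2 <- pmax(Y2 - colSums(XtY * B), 0) / (n - p)
    num <- cmat %*% B
    for (k in seq_along(cons))
      out[[k]][r, ] <- num[k, ] / sqrt(cden[k] * s2)
  }
  out
}

# signed cluster masses of a thresholded time-course: maximal runs of
# consecutive supra-threshold values, mass = sum of the values in the run
cluster_masses <- function(tv, threshold) {
  scan <- function(mask, vals) {
    if (!any(mask)) return(data.frame(start = integer(0), end = integer(0),
                                      mass = numeric(0)))
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    k <- which(r$values)
    data.frame(start = starts[k], end = ends[k],
               mass = vapply(k, function(i) sum(vals[starts[i]:ends[i]]),
                             numeric(1)))
  }
  list(pos = scan(tv > threshold, tv), neg = scan(tv < -threshold, tv))
}

# extreme cluster masses of a course (0 when no cluster); cumsum-based for
# speed inside the permutation loop
extreme_masses <- function(tv, threshold) {
  cs <- cumsum(tv)
  run_extreme <- function(mask, take_max) {
    if (!any(mask)) return(0)
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    k <- r$values
    masses <- cs[ends[k]] - cs[starts[k]] + tv[starts[k]]
    if (take_max) max(masses) else min(masses)
  }
  c(pos = run_extreme(tv > threshold, TRUE),
    neg = run_extreme(tv < -threshold, FALSE))
}

#' Cluster-based permutation test on mean t-statistic time-courses
#'
#' The observed statistic is the mean, across the units of the test set, of
#' a contrast's t-statistic time-course. Values above +threshold (below
#' -threshold) are grouped into clusters of consecutive bins whose summed
#' value is the cluster mass. The null distribution is built by repeatedly
#' drawing the same number of units, with replacement, from the area's unit
#' pool and taking one random trial-label permutation per drawn unit; each
#' draw contributes its most extreme positive and negative cluster mass.
#' A cluster is significant when its mass lies outside the 99th percentile
#' of the sign-matched null (P < 0.01).
#'
#' @param observed units x bins matrix of contrast t-courses for the test
#'   set.
#' @param perm_pool list over pool units of n_perm x bins matrices of
#'   permuted-label t-courses (from \code{\link{permuted_tcourses}}).
#' @param n_shuffle null draws (the full-scale analysis uses 10,000).
#' @param threshold cluster-forming threshold on the mean t-course.
#' @param alpha significance level (clusters outside the 1 - alpha
#'   percentile of the sign-matched null).
#' @param seed integer seed.
#' @return object of class \code{cluster_test}: \code{mean_course},
#'   \code{clusters} (start/end bin, signed mass, significance flag),
#'   \code{null_pos}/\code{null_neg} extreme-mass distributions,
#'   \code{threshold}.
#' @export
cluster_permutation_test <- function(observed, perm_pool, n_shuffle = 1000,
                                     threshold = 0.2, alpha = 0.01,
                                     seed = 1L) {
  if (n_shuffle < 100)
    warning("n_shuffle < 100: null percentile will be unstable")
  set.seed(as.integer(seed))
  n_units <- nrow(observed)
  n_pool <- length(perm_pool)
  n_perm <- nrow(perm_pool[[1]])
  n_bins <- ncol(observed)
  P <- do.call(rbind, perm_pool)        # (n_pool * n_perm) x bins
  n_rows <- nrow(P)
  null_pos <- numeric(n_shuffle); null_neg <- numeric(n_shuffle)
  # draw all unit/permutation indices, then form the null mean courses in
  # chunks as count-matrix products (counts handle replacement duplicates)
  u <- matrix(sample.int(n_pool, n_shuffle * n_units, replace = TRUE),
              n_shuffle, n_units)
  r <- matrix(sample.int(n_perm, n_shuffle * n_units, replace = TRUE),
              n_shuffle, n_units)
  rowid <- (u - 1L) * n_perm + r
  chunk <- max(1L, min(n_shuffle, floor(4e6 / n_rows)))
  s0 <- 1L
  while (s0 <= n_shuffle) {
    s1 <- min(s0 + chunk - 1L, n_shuffle)
    ns <- s1 - s0 + 1L
    flat <- rep.int(seq_len(ns), n_units) +
      (as.vector(rowid[s0:s1, ]) - 1L) * ns
    counts <- matrix(tabulate(flat, nbins = ns * n_rows), ns, n_rows)
    M <- (counts %*% P) / n_units
    for (k in seq_len(ns)) {
      em <- extreme_masses(M[k, ], threshold)
      null_pos[s0 + k - 1L] <- em["pos"]; null_neg[s0 + k - 1L] <- em["neg"]
    }
    s0 <- s1 + 1L
  }
  mean_course <- colMeans(observed)
  cm <- cluster_masses(mean_course, threshold)
  q_pos <- stats::quantile(null_pos, 1 - alpha, names = FALSE)
  q_neg <- stats::quantile(null_neg, alpha, names = FALSE)
  clusters <- rbind(
    if (nrow(cm$pos)) cbind(cm$pos, sign = "pos",
                            significant = cm$pos$mass > q_pos),
    if (nrow(cm$neg)) cbind(cm$neg, sign = "neg",
                            significant = cm$neg$mass < q_neg))
  if (is.null(clusters))
    clusters <- data.frame(start = integer(0), end = integer(0),
                           mass = numeric(0), sign = character(0),
                           significant = logical(0))
  structure(list(mean_course = mean_course, clusters = clusters,
                 null_pos = null_pos, null_neg = null_neg,
                 crit_pos = q_pos, crit_neg = q_neg,
                 threshold = threshold, alpha = alpha,
                 n_shuffle = n_shuffle, n_units = n_units),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("Cluster permutation test: %d units, %d shuffles, threshold +/- %.2f\n",
              x$n_units, x$n_shuffle, x$threshold))
  if (nrow(x$clusters)) print(x$clusters, row.names = FALSE, digits = 4)
  else cat("  no supra-threshold clusters\n")
  invisible(x)
}

# does any significant cluster of the given sign overlap a window (bin
# indices resolved against centers)?
significant_in_window <- function(ct, centers, window, sign) {
  cl <- ct$clusters
  cl <- cl[cl$significant & cl$sign == sign, , drop = FALSE]
  if (!nrow(cl)) return(FALSE)
  any(vapply(seq_len(nrow(cl)), function(i) {
    tspan <- centers[c(cl$start[i], cl$end[i])]
    tspan[2] >= window[1] && tspan[1] <= window[2]
  }, logical(1)))
}

#' Assemble a cohort of unit-level GLM results
#'
#' Convenience builder running the full per-unit chain for a set of spike
#' trains: outcome-aligned sliding-window rates, the nine-regressor design
#' from the unit's session, the sliding GLM, and a pool of permuted-label
#' contrast t-courses for the cluster tests.
#'
#' @param spike_trains list of \code{spike_train} objects (with
#'   \code{session_id}).
#' @param sessions named list of learner-augmented trial tables (must carry
#'   \code{chosen_ev}), keyed by session id.
#' @param span full PSTH span, ms.
#' @param glm_span GLM span, ms.
#' @param n_perm permuted-label courses per unit.
#' @param seed integer seed.
#' @return list of class \code{glm_cohort}; per unit: \code{area},
#'   \code{rate_matrix}, \code{glm} fit, \code{perms}, \code{trials}
#'   metadata.
#' @export
sliding_glm_cohort <- function(spike_trains, sessions, span = c(-3000, 2000),
                               glm_span = c(-1000, 1500), n_perm = 100,
                               seed = 1L) {
  units <- lapply(seq_along(spike_trains), function(i) {
    st <- spike_trains[[i]]
    tt <- sessions[[st$session_id]]
    if (is.null(tt)) stop("no session table for unit ", st$unit_id)
    rm <- compute_psth(st, tt$t_outcome, span = span)
    X <- build_design_matrix(tt)
    glm_fit <- fit_sliding_glm(rm, X, span = glm_span)
    perms <- permuted_tcourses(rm, X, span = glm_span, n_perm = n_perm,
                               seed = derive_seed(seed, i))
    list(unit_id = st$unit_id, area = st$area, rate_matrix = rm,
         design = X, glm = glm_fit, perms = perms,
         trials = tt[, c("player", "outcome", "amount", "round", "game")],
         pe = tt$pe_amount)
  })
  names(units) <- vapply(units, `[[`, "", "unit_id")
  structure(units, class = "glm_cohort")
}

# units x bins matrix of one contrast/regressor course across cohort units
cohort_courses <- function(cohort, course) {
  t(vapply(cohort, function(u) {
    if (course == "self_amount") u$glm$t["self_amount", ]
    else u$glm$contrast_t[[course]]
  }, numeric(length(cohort[[1]]$glm$centers))))
}

# units whose course has at least one bin in `window` exceeding the
# one-sided critical t at level alpha in the stated direction
select_units_by_contrast <- function(cohort, course, window, direction = 1,
                                     alpha = 0.025) {
  centers <- cohort[[1]]$glm$centers
  sel <- centers >= window[1] & centers <= window[2]
  crit <- stats::qt(1 - alpha, df = cohort[[1]]$glm$df)
  courses <- cohort_courses(cohort, course)
  apply(courses[, sel, drop = FALSE] * direction, 1, function(x) any(x > crit))
}

#' Observed-amount selection and self-amount cluster test
#'
#' Selects units whose observed-amount contrast is significantly positive in
#' at least one window position of the post-outcome response window
#' (one-sided P < alpha_sel, Bonferroni-corrected over the two coefficient
#' signs), then runs the cluster permutation test on the self-amount
#' regressor within the selected set (for which no selection bias exists).
#'
#' @param cohort a \code{glm_cohort}.
#' @param area area label to analyse.
#' @param response_window post-outcome selection window, ms.
#' @param alpha_sel per-bin selection level (default 0.05/2).
#' @param n_shuffle,threshold,alpha_cluster cluster-test settings.
#' @param seed integer seed.
#' @return list with \code{selected} unit ids, \code{n_selected}, and
#'   \code{self_amount} cluster test (NULL when nothing is selected).
#' @export
select_and_test_amount_coding <- function(cohort, area,
                                          response_window = c(300, 900),
                                          alpha_sel = 0.05 / 2,
                                          n_shuffle = 1000, threshold = 0.2,
                                          alpha_cluster = 0.01, seed = 1L) {
  pool <- cohort[vapply(cohort, `[[`, "", "area") == area]
  if (!length(pool)) stop("no units in area ", area)
  sel <- select_units_by_contrast(pool, "obs_amount", response_window,
                                  direction = 1, alpha = alpha_sel)
  if (!any(sel))
    return(list(area = area, selected = character(0), n_selected = 0L,
                self_amount = NULL))
  test_set <- pool[sel]
  obs <- cohort_courses(test_set, "self_amount")
  perm_pool <- lapply(pool, function(u) u$perms$self_amount)
  ct <- cluster_permutation_test(obs, perm_pool, n_shuffle = n_shuffle,
                                 threshold = threshold,
                                 alpha = alpha_cluster, seed = seed)
  list(area = area, selected = names(test_set), n_selected = length(test_set),
       self_amount = ct, centers = pool[[1]]$glm$centers)
}

#' Tripartite observational prediction-error test
#'
#' The temporal-difference signature test: units are selected for a positive
#' observed-expected-value contrast in at least one window position of the
#' choice period (one-sided P < alpha_sel), which leaves the post-outcome
#' tests unbiased; within the selected set, cluster permutation tests then
#' ask for a significant positive observed-amount cluster and a significant
#' negative observed-EV cluster in the post-outcome response window, whose
#' combination is the full prediction-error signal (amount minus expected
#' value).
#'
#' @param cohort a \code{glm_cohort}.
#' @param area area label.
#' @param choice_window selection window before outcome, ms.
#' @param response_window post-outcome window the clusters must reach, ms.
#' @param alpha_sel per-bin selection level (default 0.05/2).
#' @param n_shuffle,threshold,alpha_cluster cluster-test settings.
#' @param seed integer seed.
#' @return list with the selected unit ids and, for each of
#'   \code{amount}, \code{ev} and \code{pe}, the cluster test plus a flag
#'   (\code{amount_positive}, \code{ev_negative}, \code{pe_positive}) saying
#'   whether a significant cluster of the expected sign overlaps the
#'   response window.
#' @export
tripartite_pe_test <- function(cohort, area, choice_window = c(-900, -300),
                               response_window = c(300, 900),
                               alpha_sel = 0.05 / 2, n_shuffle = 1000,
                               threshold = 0.2, alpha_cluster = 0.01,
                               seed = 1L) {
  pool <- cohort[vapply(cohort, `[[`, "", "area") == area]
  if (!length(pool)) stop("no units in area ", area)
  sel <- select_units_by_contrast(pool, "obs_ev", choice_window,
                                  direction = 1, alpha = alpha_sel)
  out <- list(area = area, selected = names(pool)[sel],
              n_selected = sum(sel), centers = pool[[1]]$glm$centers)
  if (!any(sel)) {
    out[c("amount", "ev", "pe")] <- list(NULL)
    out$amount_positive <- out$ev_negative <- out$pe_positive <- FALSE
    return(out)
  }
  test_set <- pool[sel]
  centers <- pool[[1]]$glm$centers
  run <- function(course, k) {
    cluster_permutation_test(cohort_courses(test_set, course),
                             lapply(pool, function(u) u$perms[[course]]),
                             n_shuffle = n_shuffle, threshold = threshold,
                             alpha = alpha_cluster,
                             seed = derive_seed(seed, k))
  }
  out$amount <- run("obs_amount", 1L)
  out$ev <- run("obs_ev", 2L)
  out$pe <- run("obs_pe", 3L)
  out$amount_positive <- significant_in_window(out$amount, centers,
                                               response_window, "pos")
  out$ev_negative <- significant_in_window(out$ev, centers,
                                           response_window, "neg")
  out$pe_positive <- significant_in_window(out$pe, centers,
                                           response_window, "pos")
  out
}

#' Quartile prediction-error check
#'
#' A model-linearity-free check of PE coding: observed trials are split at
#' the quartiles of the model-derived PE, and a unit is flagged when, at
#' some window position of the response period, the mean rate of the upper
#' quartile minus its s.e.m. exceeds the mean of the lower quartile plus its
#' s.e.m. The chance rate of this event is estimated empirically from
#' PE-label shuffles (configurable override), and the population count of
#' flagged units is tested against it with a binomial test.
#'
#' @param rm a \code{rate_matrix} (observed trials).
#' @param pe per-trial PE values aligned with \code{rm}.
#' @param response_window ms.
#' @return logical flag for the unit.
#' @export
quartile_pe_check <- function(rm, pe, response_window = c(300, 900)) {
  if (length(pe) != nrow(rm$rate)) stop("pe length does not match trials")
  if (stats::sd(pe) == 0) stop("constant PE: quartiles undefined")
  if (length(pe) < 8) stop("need at least 8 trials for quartile split")
  qs <- stats::quantile(pe, c(0.25, 0.75))
  lo <- which(pe <= qs[1]); hi <- which(pe >= qs[2])
  sel <- rm$centers >= response_window[1] & rm$centers <= response_window[2]
  Ru <- rm$rate[hi, sel, drop = FALSE]; Rl <- rm$rate[lo, sel, drop = FALSE]
  mu <- colMeans(Ru); ml <- colMeans(Rl)
  su <- apply(Ru, 2, stats::sd) / sqrt(nrow(Ru))
  sl <- apply(Rl, 2, stats::sd) / sqrt(nrow(Rl))
  any(mu - su > ml + sl)
}

#' @rdname quartile_pe_check
#' @param cohort a \code{glm_cohort} (the PE values stored per unit are
#'   used, restricted to observed trials).
#' @param null_rate chance flag rate; NULL (default) estimates it from
#'   \code{n_null} PE shuffles per unit.
#' @param n_null shuffles per unit for the empirical null rate.
#' @param seed integer seed.
#' @return for the population version, a list with per-unit flags, the
#'   estimated null rate, and the binomial test p-value.
#' @export
quartile_pe_population <- function(cohort, response_window = c(300, 900),
                                   null_rate = NULL, n_null = 100,
                                   seed = 1L) {
  set.seed(as.integer(seed))
  flags <- logical(length(cohort))
  null_flags <- numeric(0)
  for (i in seq_along(cohort)) {
    u <- cohort[[i]]
    obs_idx <- which(u$trials$player != "self")
    rm_obs <- u$rate_matrix
    rm_obs$rate <- rm_obs$rate[obs_idx, , drop = FALSE]
    pe <- u$pe[obs_idx]
    flags[i] <- quartile_pe_check(rm_obs, pe, response_window)
    if (is.null(null_rate)) {
      nf <- vapply(seq_len(n_null), function(b)
        quartile_pe_check(rm_obs, sample(pe), response_window), logical(1))
      null_flags <- c(null_flags, mean(nf))
    }
  }
  p0 <- if (is.null(null_rate)) mean(null_flags) else null_rate
  p0 <- min(max(p0, 1e-6), 1 - 1e-6)
  bt <- stats::binom.test(sum(flags), length(flags), p = p0,
                          alternative = "greater")
  list(flags = flags, n_flagged = sum(flags), null_rate = p0,
       binom_p = bt$p.value)
}

#' Prediction-error tercile summary
#'
#' Mean response-period rate in each tercile of the model-derived PE, with a
#' monotonicity indicator. Ties at tercile boundaries are broken by stable
#' trial order.
#'
#' @param rm a \code{rate_matrix}.
#' @param pe per-trial PE values.
#' @param response_window ms.
#' @return list with \code{means} (length 3), \code{monotone}
#'   ("increasing", "decreasing" or "none").
#' @export
pe_tercile_summary <- function(rm, pe, response_window = c(300, 900)) {
  n <- nrow(rm$rate)
  if (length(pe) != n) stop("pe length does not match trials")
  if (n < 9) stop("need at least 3 trials per tercile")
  ord <- order(pe, seq_along(pe))    # stable in trial order on ties
  terc <- cut(seq_len(n), breaks = 3, labels = FALSE)
  wm <- window_mean(rm, response_window)[ord]
  means <- tapply(wm, terc, mean)
  mono <- if (all(diff(means) > 0)) "increasing"
  else if (all(diff(means) < 0)) "decreasing" else "none"
  list(means = as.numeric(means), monotone = mono)
}

#' Model-free early versus late win comparison
#'
#' Within each game and player, wins in the first two rounds ("early",
#' on average less expected) are compared with wins in the last two rounds
#' ("late", more expected); the middle round enters neither class. For each
#' unit the mean response-period rate for late wins is subtracted from that
#' for early wins, separately for the low and high amount so identical
#' outcomes are compared, then averaged over amounts. Group t-tests are run
#' per trial class (observed one-tailed positive: an observational PE
#' predicts stronger firing to less-expected wins) and paired between
#' classes.
#'
#' @param cohort a \code{glm_cohort}.
#' @param response_window ms.
#' @return list with \code{per_unit} (unit, self_diff, obs_diff),
#'   \code{group} (t and p for observed > 0, self two-sided, paired
#'   observed vs self), and a log of skipped cells.
#' @export
model_free_early_late <- function(cohort, response_window = c(300, 900)) {
  log <- character(0)
  rows <- lapply(seq_along(cohort), function(i) {
    u <- cohort[[i]]
    wm <- window_mean(u$rate_matrix, response_window)
    tt <- u$trials
    diff_for <- function(is_self) {
      sel_class <- if (is_self) tt$player == "self" else tt$player != "self"
      diffs <- c()
      for (amt in sort(unique(abs(tt$amount)))) {
        early <- sel_class & tt$outcome == "win" & abs(tt$amount) == amt &
          tt$round %in% c(1, 2)
        late <- sel_class & tt$outcome == "win" & abs(tt$amount) == amt &
          tt$round %in% c(4, 5)
        if (!any(early) || !any(late)) {
          log <<- c(log, sprintf("unit %s: no %s $%d early or late wins",
                                 u$unit_id,
                                 if (is_self) "self" else "observed", amt))
          next
        }
        diffs <- c(diffs, mean(wm[early]) - mean(wm[late]))
      }
      if (length(diffs)) mean(diffs) else NA_real_
    }
    data.frame(unit = u$unit_id, self_diff = diff_for(TRUE),
               obs_diff = diff_for(FALSE))
  })
  per_unit <- do.call(rbind, rows)
  gt <- function(x, alternative) {
    x <- x[is.finite(x)]
    if (length(x) < 2) return(c(t = NA, p = NA))
    tt <- stats::t.test(x, alternative = alternative)
    c(t = unname(tt$statistic), p = tt$p.value)
  }
  paired_ok <- is.finite(per_unit$self_diff) & is.finite(per_unit$obs_diff)
  paired <- if (sum(paired_ok) >= 2)
    stats::t.test(per_unit$obs_diff[paired_ok],
                  per_unit$self_diff[paired_ok], paired = TRUE)
  group <- list(observed = gt(per_unit$obs_diff, "greater"),
                self = gt(per_unit$self_diff, "two.sided"),
                paired = if (!is.null(paired))
                  c(t = unname(paired$statistic), p = paired$p.value))
  list(per_unit = per_unit, group = group, log = log)
}
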