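# Event-aligned firing-rate estimation and population response measures.
# All rate estimates use a moving-average window of 300 ms advanced in 10 ms
# steps; time stamps are window centers in ms relative to the alignment
# event, and each window is half-open [center - w/2, center + w/2).

#' Sliding-window peri-event firing rates
#'
#' For each event, spike counts in a moving window (default 300 ms, stepped
#' by 10 ms) divided by the window length give the rate estimate at each
#' window center. Windows are half-open so a spike on an edge is counted in
#' exactly one window position.
#'
#' @param spikes a \code{spike_train} or a numeric vector of spike times in
#'   seconds.
#' @param events event times in seconds (e.g. outcome onsets).
#' @param span numeric pair: first and last window center in ms relative to
#'   the event.
#' @param window window length, ms.
#' @param step step size, ms.
#' @return object of class \code{rate_matrix}: list with \code{rate}
#'   (trials x bins, Hz), \code{centers} (ms), \code{window}, \code{step},
#'   \code{unit_id}.
#' @export
compute_psth <- function(spikes, events, span = c(-3000, 2000),
                         window = 300, step = 10) {
  times <- if (inherits(spikes, "spike_train")) spikes$times else spikes
  unit_id <- if (inherits(spikes, "spike_train")) spikes$unit_id else NA
  if (!length(events)) stop("empty event list")
  times_ms <- sort(times) * 1000
  centers <- seq(span[1], span[2], by = step)
  half <- window / 2
  eps <- 1e-7
  lo <- centers - half
  hi <- centers + half
  ev_ms <- events * 1000
  # counts in [lo, hi) for every (event, center) pair via two global
  # searches on the sorted spike train
  n_hi <- matrix(findInterval(outer(ev_ms, hi - eps, "+"), times_ms),
                 nrow = length(ev_ms))
  n_lo <- matrix(findInterval(outer(ev_ms, lo - eps, "+"), times_ms),
                 nrow = length(ev_ms))
  rate <- (n_hi - n_lo) / (window / 1000)
  structure(list(rate = rate, centers = centers, window = window,
                 step = step, unit_id = unit_id),
            class = "rate_matrix")
}

# per-trial mean rate over window centers within [win[1], win[2]] (ms)
window_mean <- function(rm, win) {
  sel <- rm$centers >= win[1] & rm$centers <= win[2]
  rowMeans(rm$rate[, sel, drop = FALSE])
}

#' Bootstrap response-strength score (h-coefficient stand-in)
#'
#' A bootstrap-based standardised response-magnitude score used by the unit
#' selection criteria: the per-trial difference in mean rate between the
#' post- and pre-outcome windows is resampled over trials, and the score is
#' the mean over bootstrap replicates of the standardised effect
#' (mean difference / SD of differences). It serves as the pluggable
#' response-strength criterion; the thresholds applied to it are
#' configuration options of \code{\link{select_outcome_responsive}}.
#'
#' @param rm a \code{rate_matrix} aligned to outcome.
#' @param pre,post window bounds in ms.
#' @param n_boot bootstrap replicates.
#' @param seed integer seed.
#' @return scalar score (0 when the differences have no variance).
#' @export
h_coefficient <- function(rm, pre = c(-900, -300), post = c(300, 900),
                          n_boot = 200, seed = 1L) {
  set.seed(as.integer(seed))
  d <- window_mean(rm, post) - window_mean(rm, pre)
  if (stats::sd(d) == 0) return(0)
  n <- length(d)
  reps <- vapply(seq_len(n_boot), function(b) {
    db <- d[sample.int(n, n, replace = TRUE)]
    s <- stats::sd(db)
    if (s == 0) 0 else mean(db) / s
  }, numeric(1))
  mean(reps)
}

#' Select outcome-responsive units
#'
#' A unit is selected if it satisfies at least one of three conservative
#' criteria comparing the post-outcome window (300 to 900 ms) to the
#' pre-outcome window (-900 to -300 ms): (1) one-tailed paired t-test
#' p < 0.01 for an increase; (2) p < 0.05 together with a response-strength
#' score of at least 1; or (3) a response-strength score of at least 1.5.
#' The score is the bootstrap standardised response magnitude of
#' \code{\link{h_coefficient}}; its thresholds are exposed as arguments.
#'
#' @param rate_list named list of \code{rate_matrix} objects, one per unit,
#'   aligned to outcome.
#' @param pre,post comparison windows, ms.
#' @param p1 criterion-1 p threshold.
#' @param p2,h1 criterion-2 thresholds.
#' @param h2 criterion-3 score threshold.
#' @param seed seed for the bootstrap score.
#' @return data.frame with one row per unit: the p-value, score, per
#'   criterion flags, \code{selected} union flag, and an \code{excluded}
#'   flag with reason for zero-variance units.
#' @export
select_outcome_responsive <- function(rate_list, pre = c(-900, -300),
                                      post = c(300, 900), p1 = 0.01,
                                      p2 = 0.05, h1 = 1, h2 = 1.5,
                                      seed = 1L) {
  rows <- lapply(seq_along(rate_list), function(i) {
    rm <- rate_list[[i]]
    a <- window_mean(rm, pre); b <- window_mean(rm, post)
    if (stats::sd(b - a) == 0) {
      return(data.frame(unit = names(rate_list)[i] %||% i, p = NA_real_,
                        h = 0, crit1 = FALSE, crit2 = FALSE, crit3 = FALSE,
                        selected = FALSE, excluded = "zero-variance response"))
    }
    p <- stats::t.test(b, a, paired = TRUE,
                       alternative = "greater")$p.value
    h <- h_coefficient(rm, pre, post, seed = derive_seed(seed, i))
    c1 <- p < p1; c2 <- p < p2 && h >= h1; c3 <- h >= h2
    data.frame(unit = names(rate_list)[i] %||% i, p = p, h = h,
               crit1 = c1, crit2 = c2, crit3 = c3,
               selected = c1 || c2 || c3, excluded = "")
  })
  do.call(rbind, rows)
}

# Gaussian smoothing along the time axis; sd in ms
smooth_course <- function(x, sd_ms, step) {
  if (sd_ms <= 0) return(x)
  half <- ceiling(3 * sd_ms / step)
  k <- stats::dnorm(seq(-half, half) * step, sd = sd_ms)
  k <- k / sum(k)
  n <- length(x)
  xp <- c(rep(x[1], half), x, rep(x[n], half))
  stats::filter(xp, k, sides = 2)[(half + 1):(half + n)]
}

#' Bootstrapped mean response envelopes, onset and amplitude
#'
#' Resamples units with replacement, smooths each replicate's mean rate
#' course with a Gaussian kernel, and measures on every replicate the
#' response amplitude (peak above the pre-choice baseline) and the onset
#' time at which the envelope first reaches half of that peak after the
#' alignment event. Point estimates and percentile confidence intervals are
#' taken over the replicate distribution.
#'
#' @param rate_list list of \code{rate_matrix} objects (one per unit).
#' @param n_boot bootstrap replicates (the full-scale analysis uses 10,000).
#' @param smooth_sd Gaussian smoothing SD, ms.
#' @param baseline_win baseline window, ms (pre-choice, -3000 to -1000).
#' @param search_win window searched for the peak and onset, ms.
#' @param ci confidence level.
#' @param seed integer seed.
#' @return list with \code{envelope} (smoothed grand mean), \code{onset_ms},
#'   \code{amplitude} (each with point estimate and CI), \code{flat}
#'   (TRUE when no replicate peak rose above baseline) and \code{centers}.
#' @export
bootstrap_envelope <- function(rate_list, n_boot = 1000, smooth_sd = 50,
                               baseline_win = c(-3000, -1000),
                               search_win = c(0, 2000), ci = 0.95,
                               seed = 1L) {
  if (length(rate_list) < 2) stop("need at least 2 units")
  set.seed(as.integer(seed))
  centers <- rate_list[[1]]$centers
  step <- rate_list[[1]]$step
  unit_means <- t(vapply(rate_list, function(rm) colMeans(rm$rate),
                         numeric(length(centers))))
  base_sel <- centers >= baseline_win[1] & centers <= baseline_win[2]
  search_sel <- centers >= search_win[1] & centers <= search_win[2]
  measure <- function(mcourse) {
    sm <- smooth_course(mcourse, smooth_sd, step)
    base <- mean(sm[base_sel])
    peak <- max(sm[search_sel])
    amp <- peak - base
    onset <- NA_real_
    if (amp > 0) {
      half_level <- base + amp / 2
      k <- which(search_sel & sm >= half_level)
      if (length(k)) onset <- centers[k[1]]
    }
    c(onset = onset, amplitude = amp)
  }
  n_units <- nrow(unit_means)
  reps <- t(vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n_units, n_units, replace = TRUE)
    measure(colMeans(unit_means[idx, , drop = FALSE]))
  }, numeric(2)))
  obs <- measure(colMeans(unit_means))
  qs <- c((1 - ci) / 2, 1 - (1 - ci) / 2)
  flat <- all(!is.finite(reps[, "onset"])) || obs["amplitude"] <= 0
  list(envelope = as.numeric(smooth_course(colMeans(unit_means),
                                           smooth_sd, step)),
       centers = centers,
       onset_ms = list(estimate = unname(obs["onset"]),
                       ci = unname(stats::quantile(reps[, "onset"], qs,
                                                   na.rm = TRUE))),
       amplitude = list(estimate = unname(obs["amplitude"]),
                        ci = unname(stats::quantile(reps[, "amplitude"], qs))),
       flat = flat, n_boot = n_boot)
}

#' Win/lose mean response difference time-courses
#'
#' Per unit, the absolute difference between mean win-trial and mean
#' lose-trial rates at every time point, baseline-corrected by subtracting
#' its own mean over the pre-outcome window. A trial-bootstrap upper bound
#' on the pre-outcome course gives per-unit exceedance flags; the fraction
#' of units exceeding the bound after outcome is tested against the nominal
#' rate by a binomial test.
#'
#' @param rate_list list of \code{rate_matrix} objects.
#' @param labels_list list of "win"/"lose" character vectors, one per unit,
#'   aligned with the trials of each rate matrix.
#' @param pre_win baseline window, ms.
#' @param post_win exceedance window, ms.
#' @param n_boot bootstrap replicates per unit.
#' @param q bound quantile (0.95).
#' @param seed integer seed.
#' @return list with \code{course} (units x bins matrix), \code{exceeds}
#'   (per-unit flag), \code{fraction}, \code{binom_p}, \code{centers}.
#' @export
mean_response_difference <- function(rate_list, labels_list,
                                     pre_win = c(-1500, 0),
                                     post_win = c(0, 2000),
                                     n_boot = 500, q = 0.95, seed = 1L) {
  set.seed(as.integer(seed))
  centers <- rate_list[[1]]$centers
  pre_sel <- centers >= pre_win[1] & centers <= pre_win[2]
  post_sel <- centers > post_win[1] & centers <= post_win[2]
  one_course <- function(R, lab) {
    if (!all(c("win", "lose") %in% lab)) stop("missing win or lose label")
    d <- abs(colMeans(R[lab == "win", , drop = FALSE]) -
               colMeans(R[lab == "lose", , drop = FALSE]))
    d - mean(d[pre_sel])
  }
  courses <- matrix(NA_real_, length(rate_list), length(centers))
  exceeds <- logical(length(rate_list))
  for (u in seq_along(rate_list)) {
    R <- rate_list[[u]]$rate; lab <- labels_list[[u]]
    courses[u, ] <- one_course(R, lab)
    boot_pre <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(nrow(R), nrow(R), replace = TRUE)
      lb <- lab[idx]
      if (!all(c("win", "lose") %in% lb)) return(NA_real_)
      max(one_course(R[idx, , drop = FALSE], lb)[pre_sel])
    }, numeric(1))
    bound <- stats::quantile(boot_pre, q, na.rm = TRUE)
    exceeds[u] <- any(courses[u, post_sel] > bound)
  }
  frac <- mean(exceeds)
  bp <- stats::binom.test(sum(exceeds), length(exceeds), p = 1 - q,
                          alternative = "greater")$p.value
  list(course = courses, exceeds = exceeds, fraction = frac,
       binom_p = bp, centers = centers)
}

#' Cross-task correlation of response differences
#'
#' Tests whether the same units carry the win/lose response difference in
#' different trial types: across units, the product-moment correlation of
#' baseline-corrected difference courses between each pair of trial types,
#' per time point and averaged over a predefined response window.
#'
#' @param diff_by_type named list (e.g. self, observed, slot) of
#'   units x bins matrices as produced by
#'   \code{\link{mean_response_difference}} on the same unit set.
#' @param centers bin centers, ms.
#' @param window response window for the scatter statistic, ms.
#' @param alpha per-pair significance level (Bonferroni-corrected over the
#'   three pairings by default).
#' @return data.frame with one row per pairing: window-averaged r, two-sided
#'   p, significance flag; the per-bin correlation courses are in the
#'   \code{"courses"} attribute.
#' @export
response_difference_correlation <- function(diff_by_type, centers,
                                            window = c(300, 900),
                                            alpha = 0.01 / 3) {
  types <- names(diff_by_type)
  n_units <- nrow(diff_by_type[[1]])
  if (n_units < 3) stop("need at least 3 units")
  for (m in diff_by_type)
    if (nrow(m) != n_units) stop("unit sets differ between trial types")
  win_sel <- centers >= window[1] & centers <= window[2]
  pairs <- utils::combn(types, 2)
  courses <- list()
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- diff_by_type[[pairs[1, k]]]; b <- diff_by_type[[pairs[2, k]]]
    courses[[paste(pairs[, k], collapse = "_vs_")]] <<-
      vapply(seq_along(centers), function(j) stats::cor(a[, j], b[, j]),
             numeric(1))
    am <- rowMeans(a[, win_sel, drop = FALSE])
    bm <- rowMeans(b[, win_sel, drop = FALSE])
    ct <- stats::cor.test(am, bm)
    data.frame(pair = paste(pairs[, k], collapse = "_vs_"),
               r = unname(ct$estimate), p = ct$p.value,
               significant = ct$p.value < alpha)
  })
  out <- do.call(rbind, rows)
  attr(out, "courses") <- courses
  out
}
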