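# Behavioural statistics: choice and choice-time models on model-derived
# terms, lagged-outcome and lagged-PE choice regressions exploiting the
# (self, obs1, obs2) round structure, descriptive choice-time tests, and
# group-level inference across subjects.

# one-sample t-test across per-subject coefficients, one-tailed in the
# stated direction (+1: greater than zero, -1: less, 0: two-sided)
group_ttest <- function(betas_by_subject, directions) {
  terms <- colnames(betas_by_subject)
  out <- data.frame(term = terms, mean_beta = NA_real_, t = NA_real_,
                    df = NA_integer_, p = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_along(terms)) {
    b <- betas_by_subject[, j]
    b <- b[is.finite(b)]
    n <- length(b)
    if (n < 2) next
    tt <- mean(b) / (stats::sd(b) / sqrt(n))
    dirn <- directions[j]
    p <- if (dirn > 0) stats::pt(tt, n - 1, lower.tail = FALSE)
    else if (dirn < 0) stats::pt(tt, n - 1)
    else 2 * stats::pt(-abs(tt), n - 1)
    out$mean_beta[j] <- mean(b); out$t[j] <- tt
    out$df[j] <- n - 1L; out$p[j] <- p
  }
  out
}

make_regression_result <- function(per_subject, directions, model, notes = NULL) {
  wide <- stats::reshape(per_subject[, c("subject", "term", "beta")],
                         idvar = "subject", timevar = "term",
                         direction = "wide")
  mat <- as.matrix(wide[, -1, drop = FALSE])
  colnames(mat) <- sub("^beta\\.", "", colnames(mat))
  mat <- mat[, unique(per_subject$term), drop = FALSE]
  structure(list(per_subject = per_subject,
                 group = group_ttest(mat, directions),
                 directions = directions, model = model, notes = notes),
            class = "ob_regression")
}

#' @export
print.ob_regression <- function(x, ...) {
  cat("Group regression result (", x$model, "), ",
      length(unique(x$per_subject$subject)), " subjects\n", sep = "")
  print(x$group, row.names = FALSE, digits = 4)
  if (length(x$notes)) cat("notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

self_trials <- function(data) data[data$player == "self", , drop = FALSE]

#' Choice model: expected-value difference and entropy
#'
#' Per subject, a logistic regression of the probability of choosing the
#' left deck on the model-derived left-minus-right expected-value difference
#' and the choice entropy; coefficients are changes in the natural log odds.
#' Group-level inference is a one-sample t-test across subject coefficients,
#' one-tailed positive for the EV difference (value-guided choice) and for
#' entropy in the configured direction.
#'
#' @param data learner-augmented trial table (the \code{$trials} of a
#'   \code{\link{reversal_learner}}, possibly several subjects row-bound),
#'   needing columns \code{subject_id}, \code{player}, \code{chosen_deck},
#'   \code{ev_left}, \code{ev_right}, \code{ce}.
#' @param ce_direction one-tailed direction for the entropy term (+1, -1 or
#'   0 for two-sided).
#' @return an \code{ob_regression}: per-subject coefficient table and group
#'   t statistics.
#' @export
fit_choice_model <- function(data, ce_direction = 1) {
  d <- self_trials(data)
  d$evdiff <- d$ev_left - d$ev_right
  d$y <- as.numeric(d$chosen_deck == "left")
  rows <- list(); notes <- character(0)
  for (s in unique(d$subject_id)) {
    ds <- d[d$subject_id == s, ]
    for (tm in c("evdiff", "ce"))
      if (stats::sd(ds[[tm]]) == 0)
        stop("predictor '", tm, "' is constant for subject ", s)
    fit <- suppressWarnings(
      stats::glm(y ~ evdiff + ce, family = stats::binomial(), data = ds))
    cf <- summary(fit)$coefficients
    if (any(abs(cf[-1, "Estimate"]) > 15 & cf[-1, "Std. Error"] > 15)) {
      notes <- c(notes, paste0("subject ", s,
                               ": separation suspected, excluded"))
      next
    }
    rows[[s]] <- data.frame(subject = s, term = rownames(cf),
                            beta = cf[, "Estimate"],
                            se = cf[, "Std. Error"], n = nrow(ds),
                            row.names = NULL)
  }
  if (!length(rows)) stop("no subject could be fitted")
  per_subject <- do.call(rbind, rows)
  if (length(notes)) warning(paste(notes, collapse = "; "))
  make_regression_result(per_subject,
                         directions = c(0, 1, ce_direction),
                         model = "logistic: choose-left ~ EVdiff + CE",
                         notes = notes)
}

#' Choice-time model: expected-value difference and entropy
#'
#' Per subject, a multiple linear regression of self-trial choice times on
#' the EV difference and the choice entropy; positive coefficients indicate
#' relative slowing. Rows with non-positive or missing choice times are
#' dropped (count recorded in the notes). Group inference is one-tailed
#' positive for entropy (decisions the model calls harder are slower).
#'
#' @inheritParams fit_choice_model
#' @return an \code{ob_regression}.
#' @export
fit_choice_time_model <- function(data) {
  d <- self_trials(data)
  bad <- !is.finite(d$choice_time) | d$choice_time <= 0
  notes <- if (any(bad)) paste0(sum(bad), " non-positive/missing choice times dropped")
  d <- d[!bad, ]
  d$evdiff <- d$ev_left - d$ev_right
  rows <- list()
  for (s in unique(d$subject_id)) {
    ds <- d[d$subject_id == s, ]
    fit <- stats::lm(choice_time ~ evdiff + ce, data = ds)
    cf <- summary(fit)$coefficients
    rows[[s]] <- data.frame(subject = s, term = rownames(cf),
                            beta = cf[, "Estimate"],
                            se = cf[, "Std. Error"], n = nrow(ds),
                            row.names = NULL)
  }
  make_regression_result(do.call(rbind, rows), directions = c(0, 0, 1),
                         model = "linear: CT ~ EVdiff + CE", notes = notes)
}

# lagged design around each self trial; history never crosses a session
# boundary. Returns NULL if no eligible trial.
lagged_design <- function(ds, n_lags, value_fun) {
  rows <- list()
  for (sid in unique(ds$session_id)) {
    dd <- ds[ds$session_id == sid, ]
    self_idx <- which(dd$player == "self")
    self_idx <- self_idx[self_idx > n_lags]
    if (!length(self_idx)) next
    for (t in self_idx) {
      x <- numeric(2 * n_lags)
      for (j in seq_len(n_lags)) {
        v <- value_fun(dd, t - j)
        if (dd$chosen_deck[t - j] == "left") x[j] <- v
        else x[n_lags + j] <- v
      }
      rows[[length(rows) + 1L]] <-
        c(y = as.numeric(dd$chosen_deck[t] == "left"), x)
    }
  }
  if (!length(rows)) return(NULL)
  m <- do.call(rbind, rows)
  colnames(m) <- c("y", paste0("L", seq_len(n_lags)),
                   paste0("R", seq_len(n_lags)))
  as.data.frame(m)
}

# per-lag evidence contrast: (left coefficient - right coefficient) / 2
lag_aggregates <- function(cf, n_lags, self_lags, obs_lags) {
  bl <- cf[paste0("L", seq_len(n_lags))]
  br <- cf[paste0("R", seq_len(n_lags))]
  per_lag <- (bl - br) / 2
  c(self = mean(per_lag[self_lags]), observed = mean(per_lag[obs_lags]))
}

#' Lagged-outcome choice regression
#'
#' Predicts the current self choice of the left deck from the win/no-win
#' outcomes (win = 1, no win = 0, separately for left- and right-deck
#' choices) of the previous six trials. Under the fixed (self, obs1, obs2)
#' round order, lags t-3 and t-6 are the subject's own previous outcomes and
#' lags t-1, t-2, t-4, t-5 are observed ones; the per-lag evidence effect
#' (left coefficient minus right coefficient, halved) is averaged within
#' each class and tested across subjects (one-tailed positive: outcomes
#' favouring a deck increase its choice odds). Fitted as a linear
#' probability model by default, with a logistic variant.
#'
#' @inheritParams fit_choice_model
#' @param family "linear" (as stated for the analysis) or "logistic".
#' @return an \code{ob_regression} with terms \code{self} and
#'   \code{observed}.
#' @export
lagged_outcome_regression <- function(data, family = c("linear", "logistic")) {
  family <- match.arg(family)
  rows <- list(); notes <- character(0)
  for (s in unique(data$subject_id)) {
    ds <- data[data$subject_id == s, ]
    dm <- lagged_design(ds, 6L,
                        function(dd, i) as.numeric(dd$outcome[i] == "win"))
    if (is.null(dm) || nrow(dm) < 15) {
      notes <- c(notes, paste0("subject ", s, ": too little history, skipped"))
      next
    }
    fit <- if (family == "linear") stats::lm(y ~ ., data = dm)
    else suppressWarnings(stats::glm(y ~ ., data = dm,
                                     family = stats::binomial()))
    cf <- stats::coef(fit)
    if (anyNA(cf)) {
      notes <- c(notes, paste0("subject ", s,
                               ": collinear lagged outcomes, excluded"))
      next
    }
    agg <- lag_aggregates(cf, 6L, self_lags = c(3L, 6L),
                          obs_lags = c(1L, 2L, 4L, 5L))
    rows[[s]] <- data.frame(subject = s, term = names(agg), beta = agg,
                            se = NA_real_, n = nrow(dm), row.names = NULL)
  }
  if (!length(rows)) stop("no subject had sufficient lag history")
  make_regression_result(do.call(rbind, rows), directions = c(1, 1),
                         model = paste0("lagged-outcome (", family, ")"),
                         notes = notes)
}

#' Lagged prediction-error choice regression
#'
#' As \code{\link{lagged_outcome_regression}} but with the model-derived
#' prediction errors (amount obtained minus dollar-scaled chosen expected
#' value) of the three most recent trials as predictors: lag t-3 carries the
#' most recent self-experienced PE and lags t-1, t-2 the two most recent
#' observed PEs.
#'
#' @inheritParams fit_choice_model
#' @param pe_column which PE coding to use as predictor.
#' @return an \code{ob_regression} with terms \code{self} and
#'   \code{observed}.
#' @export
lagged_pe_regression <- function(data, pe_column = c("pe_amount", "pe_binary")) {
  pe_column <- match.arg(pe_column)
  if (!pe_column %in% names(data))
    stop("missing learner output column '", pe_column, "'")
  rows <- list(); notes <- character(0)
  for (s in unique(data$subject_id)) {
    ds <- data[data$subject_id == s, ]
    if (stats::sd(ds[[pe_column]]) == 0)
      stop("prediction errors are identically constant for subject ", s)
    dm <- lagged_design(ds, 3L, function(dd, i) dd[[pe_column]][i])
    if (is.null(dm) || nrow(dm) < 10) {
      notes <- c(notes, paste0("subject ", s, ": too little history, skipped"))
      next
    }
    fit <- stats::lm(y ~ ., data = dm)
    cf <- stats::coef(fit)
    if (anyNA(cf)) {
      notes <- c(notes, paste0("subject ", s, ": collinear PEs, excluded"))
      next
    }
    agg <- lag_aggregates(cf, 3L, self_lags = 3L, obs_lags = c(1L, 2L))
    rows[[s]] <- data.frame(subject = s, term = names(agg), beta = agg,
                            se = NA_real_, n = nrow(dm), row.names = NULL)
  }
  if (!length(rows)) stop("no subject had sufficient lag history")
  make_regression_result(do.call(rbind, rows), directions = c(1, 1),
                         model = "lagged-PE (linear)", notes = notes)
}

# deck indicated by a trial's outcome: the chosen deck after a win, the
# other deck after a loss
indicated_deck <- function(chosen, outcome) {
  ifelse(outcome == "win", chosen,
         ifelse(chosen == "left", "right", "left"))
}

# length of the run of consecutive immediately preceding trials whose
# outcomes coherently indicate the same deck
coherence_streak <- function(dd) {
  n <- nrow(dd)
  ind <- indicated_deck(dd$chosen_deck, dd$outcome)
  streak <- integer(n)
  for (t in seq_len(n)) {
    k <- 0L
    while (t - k - 1L >= 1L && ind[t - k - 1L] == ind[t - 1L]) k <- k + 1L
    streak[t] <- if (t == 1L) 0L else k
  }
  streak
}

#' Descriptive choice-time tests
#'
#' The battery of model-free choice-time contrasts: better versus worse
#' deck, self trials following an observed win versus loss, left versus
#' right side (all two-tailed t-tests), a Spearman rank correlation of
#' choice time with the number of coherent immediately preceding outcomes,
#' and one-way ANOVAs of choice time across rounds 1-5 and rounds 2-5.
#' Trials are pooled across subjects by default (per-subject mode averages
#' the statistics over subjects is not provided; pooling matches the trial
#' counts such analyses report).
#'
#' @inheritParams fit_choice_model
#' @return data.frame with one row per test: statistic, p-value, cell sizes.
#'   Tests with an empty cell are skipped and recorded in the
#'   \code{"log"} attribute.
#' @export
rt_descriptive_tests <- function(data) {
  # annotate each trial with the outcome of the immediately preceding
  # observed trial and with the coherent-outcome streak, session by session
  data <- data[order(data$session_id, data$t_outcome), ]
  data$prev_obs_outcome <- NA_character_
  data$streak <- NA_integer_
  for (sid in unique(data$session_id)) {
    idx <- which(data$session_id == sid)
    pl <- data$player[idx]
    po <- rep(NA_character_, length(idx))
    k <- which(seq_along(idx) > 1 & pl == "self" &
                 c("", pl[-length(pl)]) != "self")
    po[k] <- data$outcome[idx[k - 1L]]
    data$prev_obs_outcome[idx] <- po
    data$streak[idx] <- coherence_streak(data[idx, ])
  }
  d <- self_trials(data)
  d <- d[is.finite(d$choice_time) & d$choice_time > 0, ]
  res <- list(); log <- character(0)
  add <- function(test, statistic, p, n1, n2 = NA_integer_) {
    res[[length(res) + 1L]] <<- data.frame(test = test, statistic = statistic,
                                           p = p, n1 = n1, n2 = n2)
  }
  two_cell_t <- function(name, a, b) {
    if (length(a) < 2 || length(b) < 2) {
      log <<- c(log, paste0(name, ": empty or singleton cell, skipped"))
      return(invisible())
    }
    tt <- stats::t.test(a, b)
    add(name, unname(tt$statistic), tt$p.value, length(a), length(b))
  }
  two_cell_t("better_vs_worse_deck",
             d$choice_time[d$chosen_deck == d$good_deck],
             d$choice_time[d$chosen_deck != d$good_deck])
  two_cell_t("after_observed_win_vs_loss",
             d$choice_time[!is.na(d$prev_obs_outcome) &
                             d$prev_obs_outcome == "win"],
             d$choice_time[!is.na(d$prev_obs_outcome) &
                             d$prev_obs_outcome == "lose"])
  two_cell_t("left_vs_right",
             d$choice_time[d$chosen_deck == "left"],
             d$choice_time[d$chosen_deck == "right"])

  st <- d$streak; ctv <- d$choice_time
  if (length(unique(st)) > 1) {
    sp <- suppressWarnings(stats::cor.test(ctv, st, method = "spearman"))
    add("coherence_spearman", unname(sp$estimate), sp$p.value, length(ctv))
  } else log <- c(log, "coherence_spearman: degenerate streaks, skipped")

  for (rng in list(c(1, 5), c(2, 5))) {
    dd <- d[d$round >= rng[1] & d$round <= rng[2], ]
    if (length(unique(dd$round)) > 1) {
      a <- summary(stats::aov(choice_time ~ factor(round), data = dd))[[1]]
      add(sprintf("anova_rounds_%d_%d", rng[1], rng[2]),
          a[["F value"]][1], a[["Pr(>F)"]][1], nrow(dd))
    }
  }
  out <- do.call(rbind, res)
  attr(out, "log") <- log
  out
}

#' Write a regression result as tidy CSV plus a JSON group summary
#'
#' @param x an \code{ob_regression}.
#' @param csv_path,json_path output paths.
#' @export
write_regression_result <- function(x, csv_path, json_path) {
  stopifnot(inherits(x, "ob_regression"))
  utils::write.csv(x$per_subject, csv_path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(model = x$model, group = x$group,
                            notes = x$notes),
                       json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(x)
}
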