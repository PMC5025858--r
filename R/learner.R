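#' Fit the grid Bayesian reversal-learning observer to a trial table
#'
#' Propagates the joint grid belief over the reward contingency q and the
#' reversal hazard v through every card trial of each session, in
#' chronological order, treating self-experienced and observed trials
#' identically (the observer learns from all outcomes). At each game
#' boundary (default mode) the belief passes through the reversal-mixture
#' transition with the hazard marginalised over its own grid; per-trial
#' hazard and hazard-free modes are available. Expected values, choice
#' entropy and prediction errors are evaluated from the prior belief of each
#' trial, i.e. before that trial's outcome enters the posterior. The belief
#' is never reset between games within a session; it is re-initialised at
#' session boundaries.
#'
#' @param trials trial table (one or more sessions) as produced by
#'   \code{\link{generate_session}}; rows must be in chronological order
#'   within each session.
#' @param n_q,n_v grid resolutions for q and v.
#' @param hazard when the reversal transition applies: \code{"boundary"}
#'   (game boundaries only, the task's ground truth), \code{"per_trial"}
#'   (every trial), or \code{"none"} (static contingency; used for
#'   conjugate-oracle checks).
#' @param pe_scale dollar scale of the amount-coded prediction error.
#' @return an object of class \code{reversal_learner} with components
#'   \code{trials} (the input table augmented with \code{ev_left},
#'   \code{ev_right}, \code{chosen_ev}, \code{ce}, \code{pe_binary},
#'   \code{pe_amount}, \code{posterior_mean_q}), \code{final_belief} (per
#'   session), and the grid configuration.
#' @examples
#' sess <- generate_session(seed = 1)
#' fit <- reversal_learner(sess)
#' fit
#' head(residuals(fit))
#' @export
reversal_learner <- function(trials, n_q = 101L, n_v = 21L,
                             hazard = c("boundary", "per_trial", "none"),
                             pe_scale = 55) {
  hazard <- match.arg(hazard)
  needed <- c("session_id", "game", "trial_in_game", "player", "chosen_deck",
              "outcome", "amount", "t_outcome")
  missing_cols <- setdiff(needed, names(trials))
  if (length(missing_cols))
    stop("trial table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  n <- nrow(trials)
  ev_left <- ev_right <- chosen_ev <- ce <- pmq <- numeric(n)
  final_beliefs <- list()

  sessions <- unique(trials$session_id)
  for (sid in sessions) {
    idx <- which(trials$session_id == sid)
    tt <- trials[idx, ]
    if (is.unsorted(tt$t_outcome, strictly = TRUE))
      stop("out-of-order event timestamps in session ", sid)
    belief <- init_belief(n_q, n_v)
    prev_game <- tt$game[1]
    for (k in seq_along(idx)) {
      i <- idx[k]
      if (hazard == "per_trial" && k > 1L) {
        belief <- belief_transition(belief, at_opportunity = TRUE)
      } else if (hazard == "boundary" && tt$game[k] != prev_game) {
        belief <- belief_transition(belief, at_opportunity = TRUE)
      }
      prev_game <- tt$game[k]
      ev <- expected_value(belief)
      ev_left[i] <- ev["left"]; ev_right[i] <- ev["right"]
      chosen_ev[i] <- if (tt$chosen_deck[k] == "left") ev["left"] else ev["right"]
      ce[i] <- choice_entropy(ev)
      belief <- belief_update(belief, tt$chosen_deck[k], tt$outcome[k])
      pmq[i] <- expected_value(belief)["left"]
    }
    final_beliefs[[sid]] <- belief
  }

  out <- trials
  out$ev_left <- ev_left
  out$ev_right <- ev_right
  out$chosen_ev <- chosen_ev
  out$ce <- ce
  out$pe_binary <- prediction_error(trials$outcome, trials$amount, chosen_ev,
                                    coding = "binary")
  out$pe_amount <- prediction_error(trials$outcome, trials$amount, chosen_ev,
                                    coding = "amount", scale = pe_scale)
  out$posterior_mean_q <- pmq

  structure(list(trials = out, final_belief = final_beliefs,
                 grid = c(n_q = as.integer(n_q), n_v = as.integer(n_v)),
                 hazard = hazard, pe_scale = pe_scale, tau = NULL,
                 call = match.call()),
            class = "reversal_learner")
}

#' @export
print.reversal_learner <- function(x, ...) {
  cat("Grid Bayesian reversal-learning observer\n")
  cat(sprintf("  %d trials in %d session(s); grid %d x %d; hazard mode '%s'\n",
              nrow(x$trials), length(x$final_belief),
              x$grid["n_q"], x$grid["n_v"], x$hazard))
  if (!is.null(x$tau))
    cat(sprintf("  fitted softmax temperature tau = %.4f (logLik %.2f)\n",
                x$tau, x$tau_fit$logLik))
  invisible(x)
}

#' @export
summary.reversal_learner <- function(object, ...) {
  tr <- object$trials
  s <- data.frame(session_id = unique(tr$session_id))
  s$n_trials <- as.integer(table(tr$session_id)[s$session_id])
  s$mean_ce <- tapply(tr$ce, tr$session_id, mean)[s$session_id]
  s$mean_chosen_ev <- tapply(tr$chosen_ev, tr$session_id, mean)[s$session_id]
  out <- list(sessions = s, hazard = object$hazard, tau = object$tau,
              grid = object$grid)
  class(out) <- "summary.reversal_learner"
  out
}

#' @export
print.summary.reversal_learner <- function(x, ...) {
  cat("Reversal-learning observer summary (hazard mode '", x$hazard, "')\n",
      sep = "")
  print(x$sessions, row.names = FALSE)
  if (!is.null(x$tau)) cat(sprintf("fitted tau = %.4f\n", x$tau))
  invisible(x)
}

#' @export
coef.reversal_learner <- function(object, ...) {
  if (is.null(object$tau))
    stop("no fitted parameters; run fit_temperature() first")
  c(tau = object$tau)
}

#' @export
logLik.reversal_learner <- function(object, ...) {
  if (is.null(object$tau))
    stop("no fitted temperature; run fit_temperature() first")
  ll <- object$tau_fit$logLik
  attr(ll, "df") <- 1L
  attr(ll, "nobs") <- object$tau_fit$n
  class(ll) <- "logLik"
  ll
}

#' Residuals of the reversal-learning observer
#'
#' The observer's residual on a trial is its reward prediction error:
#' outcome minus chosen expected value (binary coding) or signed amount
#' minus the dollar-scaled expected value (amount coding).
#'
#' @param object a \code{reversal_learner}.
#' @param type "binary" or "amount".
#' @param ... unused.
#' @export
residuals.reversal_learner <- function(object, type = c("binary", "amount"),
                                       ...) {
  type <- match.arg(type)
  if (type == "binary") object$trials$pe_binary else object$trials$pe_amount
}

#' Predict choice probabilities from a fitted observer
#'
#' @param object a \code{reversal_learner}.
#' @param type \code{"choice_prob"} for softmax left-deck probabilities
#'   (requires a temperature, fitted or supplied), or \code{"ev"} for the
#'   expected-value pair.
#' @param tau optional temperature overriding the fitted one.
#' @param ... unused.
#' @export
predict.reversal_learner <- function(object, type = c("choice_prob", "ev"),
                                     tau = NULL, ...) {
  type <- match.arg(type)
  tr <- object$trials
  if (type == "ev")
    return(data.frame(ev_left = tr$ev_left, ev_right = tr$ev_right))
  tau <- if (is.null(tau)) object$tau else tau
  if (is.null(tau)) stop("supply tau or fit it with fit_temperature()")
  stats::plogis((tr$ev_left - tr$ev_right) / tau)
}

#' Simulate choices from a fitted observer
#'
#' Draws softmax self-trial choices at the object's (or a supplied)
#' temperature, holding the expected-value trajectory fixed.
#'
#' @param object a \code{reversal_learner}.
#' @param nsim number of simulated choice vectors.
#' @param seed integer seed.
#' @param tau optional temperature.
#' @param ... unused.
#' @return a data.frame with one column per simulation of "left"/"right"
#'   choices for the self trials.
#' @export
simulate.reversal_learner <- function(object, nsim = 1, seed = NULL,
                                      tau = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  tau <- if (is.null(tau)) object$tau else tau
  if (is.null(tau)) stop("supply tau or fit it with fit_temperature()")
  tr <- object$trials[object$trials$player == "self", ]
  p <- stats::plogis((tr$ev_left - tr$ev_right) / tau)
  out <- replicate(nsim, ifelse(stats::runif(length(p)) < p, "left", "right"),
                   simplify = FALSE)
  names(out) <- paste0("sim_", seq_len(nsim))
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Plot the observer's expected-value trajectory
#'
#' @param x a \code{reversal_learner}.
#' @param session_id which session to plot (default the first).
#' @param ... passed to \code{plot}.
#' @export
plot.reversal_learner <- function(x, session_id = NULL, ...) {
  tr <- x$trials
  sid <- if (is.null(session_id)) tr$session_id[1] else session_id
  tr <- tr[tr$session_id == sid, ]
  idx <- seq_len(nrow(tr))
  graphics::plot(idx, tr$ev_left, type = "l", ylim = c(0, 1),
                 xlab = "trial", ylab = "EV(left deck)",
                 main = paste("Session", sid), ...)
  truth <- ifelse(tr$good_deck == "left",
                  attr(tr, "p_good") %||% 0.7, 1 - (attr(tr, "p_good") %||% 0.7))
  graphics::lines(idx, truth, lty = 2, col = "grey50")
  graphics::abline(v = idx[tr$trial_in_game == 1], col = "grey85")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Maximum-likelihood softmax temperature
#'
#' Fits the subject-specific softmax temperature tau by maximising the
#' likelihood of the observed self-trial choices given the model-derived
#' expected values (which are computed without reference to tau). The
#' one-dimensional search is run on log(tau) over a bounded interval from
#' multiple starting brackets; boundary solutions and flat likelihoods are
#' flagged in the diagnostics.
#'
#' @param object a \code{reversal_learner}, or a data.frame with columns
#'   \code{ev_left}, \code{ev_right}, \code{chosen_deck}.
#' @param choices optional character vector of "left"/"right" self choices
#'   overriding the ones in the trial table (e.g. simulated choices).
#' @param bounds search bounds for tau.
#' @param ... unused.
#' @return for a \code{reversal_learner} input, the object with \code{$tau}
#'   and \code{$tau_fit} filled in; otherwise the fit list itself
#'   (\code{tau}, \code{logLik}, \code{n}, \code{convergence},
#'   \code{at_lower}, \code{at_upper}, \code{flat}).
#' @export
fit_temperature <- function(object, choices = NULL,
                            bounds = c(1e-3, 1e3), ...) {
  if (inherits(object, "reversal_learner")) {
    tr <- object$trials[object$trials$player == "self", ]
  } else {
    tr <- object
  }
  if (!is.null(choices)) {
    if (length(choices) != nrow(tr))
      stop("choices length does not match the number of self trials")
    tr$chosen_deck <- choices
  }
  if (nrow(tr) < 10L)
    stop("need at least 10 self choices to fit the temperature")
  dv <- tr$ev_left - tr$ev_right
  y <- as.numeric(tr$chosen_deck == "left")

  nll <- function(log_tau) {
    p <- stats::plogis(dv / exp(log_tau))
    -sum(y * log(pmax(p, 1e-12)) + (1 - y) * log(pmax(1 - p, 1e-12)))
  }
  lb <- log(bounds[1]); ub <- log(bounds[2])
  # multiple bracketed restarts guard against plateaus near the bounds
  brackets <- list(c(lb, ub), c(lb, 0.5 * (lb + ub)), c(0.5 * (lb + ub), ub))
  best <- NULL
  for (br in brackets) {
    o <- stats::optimize(nll, interval = br, tol = 1e-8)
    if (is.null(best) || o$objective < best$objective) best <- o
  }
  tau_hat <- exp(best$minimum)
  nll_grid <- vapply(seq(lb, ub, length.out = 25), nll, numeric(1))
  flat <- diff(range(nll_grid)) < 1e-6 * max(1, abs(best$objective))
  fit <- list(tau = tau_hat, logLik = -best$objective, n = length(y),
              convergence = TRUE,
              at_lower = best$minimum < lb + 1e-3,
              at_upper = best$minimum > ub - 1e-3,
              flat = flat)
  if (inherits(object, "reversal_learner")) {
    object$tau <- tau_hat
    object$tau_fit <- fit
    object
  } else fit
}

#' Write / read learner output CSV
#'
#' One row per trial keyed by session and trial index, with the
#' model-derived quantities used by the behavioural and neural analyses.
#'
#' @param learner a \code{reversal_learner} or its \code{$trials} table.
#' @param path file path.
#' @export
write_learner_output <- function(learner, path) {
  tr <- if (inherits(learner, "reversal_learner")) learner$trials else learner
  cols <- c("session_id", "ev_left", "ev_right", "chosen_ev", "ce",
            "pe_binary", "pe_amount", "posterior_mean_q")
  missing_cols <- setdiff(cols, names(tr))
  if (length(missing_cols))
    stop("learner output missing columns: ",
         paste(missing_cols, collapse = ", "))
  out <- data.frame(session_id = tr$session_id,
                    trial_index = stats::ave(seq_len(nrow(tr)),
                                             tr$session_id,
                                             FUN = seq_along))
  out <- cbind(out, tr[, cols[-1]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_learner_output
#' @export
read_learner_output <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
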