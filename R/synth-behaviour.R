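#' Behavioural simulation parameters
#'
#' Parameters of the synthetic subject: softmax temperature driving self
#' choices, and a linear-Gaussian choice-time model
#' \code{ct = intercept + entropy_slope * CE + round1_extra * 1\{round 1\} +
#' noise}, truncated below at \code{ct_floor} seconds.
#'
#' @param tau softmax temperature.
#' @param ct_intercept baseline choice time, seconds.
#' @param ct_entropy_slope slowing per bit of choice entropy, seconds/bit.
#' @param ct_round1_extra additional slowing on the first round of a game,
#'   seconds.
#' @param ct_noise_sd Gaussian choice-time noise, seconds.
#' @param ct_floor truncation floor, seconds.
#' @return list of class \code{behaviour_params}.
#' @export
behaviour_params <- function(tau = 0.2, ct_intercept = 0.8,
                             ct_entropy_slope = 0.4, ct_round1_extra = 0.3,
                             ct_noise_sd = 0.3, ct_floor = 0.15) {
  if (tau <= 0) stop("tau must be positive")
  if (ct_noise_sd <= 0) stop("ct_noise_sd must be positive")
  structure(list(tau = tau, ct_intercept = ct_intercept,
                 ct_entropy_slope = ct_entropy_slope,
                 ct_round1_extra = ct_round1_extra,
                 ct_noise_sd = ct_noise_sd, ct_floor = ct_floor),
            class = "behaviour_params")
}

#' Simulate closed-loop subject behaviour on a session
#'
#' Replays a generated session with the subject in the loop: the grid belief
#' is propagated over all trials; on each self trial the deck choice is drawn
#' from the softmax of the current expected values at temperature \code{tau},
#' and the outcome and amount are re-drawn under the session's ground-truth
#' contingency for the chosen deck. Observed trials keep the session-defined
#' choices and outcomes. Choice times for self trials follow the
#' linear-Gaussian entropy model of \code{\link{behaviour_params}}.
#'
#' @param session trial table from \code{\link{generate_session}} (its
#'   \code{"config"} attribute supplies the deck contingency and amounts).
#' @param params a \code{\link{behaviour_params}}.
#' @param seed integer seed.
#' @param n_q,n_v belief grid resolution.
#' @param hazard hazard mode passed to the belief transition (see
#'   \code{\link{reversal_learner}}).
#' @return list with \code{trials} (the session with self choices/outcomes
#'   replaced and a \code{choice_time} column, NA on observed trials),
#'   \code{learner} (a \code{reversal_learner} fitted to the realised
#'   trials), and \code{params}.
#' @export
simulate_behaviour <- function(session, params = behaviour_params(),
                               seed = 1L, n_q = 101L, n_v = 21L,
                               hazard = c("boundary", "per_trial", "none")) {
  hazard <- match.arg(hazard)
  stopifnot(inherits(params, "behaviour_params"))
  config <- attr(session, "config")
  if (is.null(config)) config <- task_config()
  set.seed(as.integer(seed))

  tr <- session
  n <- nrow(tr)
  ct <- rep(NA_real_, n)
  belief <- init_belief(n_q, n_v)
  prev_game <- tr$game[1]
  for (k in seq_len(n)) {
    if (hazard == "per_trial" && k > 1L) {
      belief <- belief_transition(belief, TRUE)
    } else if (hazard == "boundary" && tr$game[k] != prev_game) {
      belief <- belief_transition(belief, TRUE)
    }
    prev_game <- tr$game[k]
    ev <- expected_value(belief)
    if (tr$player[k] == "self") {
      p_left <- stats::plogis((ev["left"] - ev["right"]) / params$tau)
      tr$chosen_deck[k] <- if (stats::runif(1) < p_left) "left" else "right"
      p_win <- if (tr$chosen_deck[k] == tr$good_deck[k]) config$p_good else
        1 - config$p_good
      win <- stats::runif(1) < p_win
      tr$outcome[k] <- if (win) "win" else "lose"
      mag <- sample(config$amounts, 1L)
      tr$amount[k] <- if (win) mag else -mag
      ce_k <- choice_entropy(ev)
      ct[k] <- params$ct_intercept + params$ct_entropy_slope * ce_k +
        params$ct_round1_extra * (tr$round[k] == 1) +
        stats::rnorm(1, 0, params$ct_noise_sd)
      ct[k] <- max(ct[k], params$ct_floor)
    }
    belief <- belief_update(belief, tr$chosen_deck[k], tr$outcome[k])
  }
  tr$choice_time <- ct
  attr(tr, "config") <- config
  learner <- reversal_learner(tr, n_q = n_q, n_v = n_v, hazard = hazard)
  list(trials = tr, learner = learner, params = params)
}
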