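#' Task configuration for the observational card game
#'
#' Builds and validates the parameter set of the two-deck card game and the
#' slot machine. Defaults reproduce the study task: 12 games of 5 rounds,
#' each round played by the subject (self) followed by two observed players;
#' one deck pays out with probability 0.7, the other with 0.3; the good deck
#' flips at each game boundary with probability 0.5; win/lose amounts are
#' $10 or $100, equiprobable; the slot machine wins with probability 0.5,
#' doubling the running total on a win and halving it on a loss.
#'
#' @param n_games number of games per session.
#' @param rounds_per_game rounds per game; each round is one self trial
#'   followed by two observed trials.
#' @param p_good win probability of the good deck (must exceed 0.5).
#' @param p_reversal probability that the good deck flips at a game boundary.
#' @param amounts positive payout magnitudes in dollars.
#' @param slot_p_win win probability of the slot machine.
#' @param highlight_s seconds the chosen card is highlighted before the
#'   outcome appears.
#' @param outcome_s seconds the outcome stays on screen.
#' @param choice_s nominal presentation-to-choice latency used to lay out the
#'   session clock (self choice times are modelled separately).
#' @param iti_s inter-trial interval in seconds.
#' @return a list of class \code{task_config}.
#' @examples
#' cfg <- task_config()
#' cfg$n_games * cfg$rounds_per_game * 3  # 180 card trials
#' @export
task_config <- function(n_games = 12L, rounds_per_game = 5L,
                        p_good = 0.7, p_reversal = 0.5,
                        amounts = c(10, 100), slot_p_win = 0.5,
                        highlight_s = 1.0, outcome_s = 3.0,
                        choice_s = 1.5, iti_s = 1.5) {
  n_games <- as.integer(n_games)
  rounds_per_game <- as.integer(rounds_per_game)
  if (is.na(n_games) || n_games < 1L)
    stop("configuration error: n_games must be a positive integer")
  if (is.na(rounds_per_game) || rounds_per_game < 1L)
    stop("configuration error: rounds_per_game must be a positive integer")
  if (!is.numeric(p_good) || p_good <= 0.5 || p_good >= 1)
    stop("configuration error: p_good must lie in (0.5, 1)")
  if (!is.numeric(p_reversal) || p_reversal < 0 || p_reversal > 1)
    stop("configuration error: p_reversal must lie in [0, 1]")
  if (!is.numeric(slot_p_win) || slot_p_win <= 0 || slot_p_win >= 1)
    stop("configuration error: slot_p_win must lie in (0, 1)")
  if (any(amounts <= 0)) stop("configuration error: amounts must be positive")
  structure(list(n_games = n_games, rounds_per_game = rounds_per_game,
                 players = c("self", "obs1", "obs2"),
                 p_good = p_good, p_reversal = p_reversal,
                 amounts = sort(amounts), slot_p_win = slot_p_win,
                 highlight_s = highlight_s, outcome_s = outcome_s,
                 choice_s = choice_s, iti_s = iti_s),
            class = "task_config")
}

#' @export
print.task_config <- function(x, ...) {
  cat("Card-game task configuration\n")
  cat(sprintf("  %d games x %d rounds x %d players = %d card trials\n",
              x$n_games, x$rounds_per_game, length(x$players),
              x$n_games * x$rounds_per_game * length(x$players)))
  cat(sprintf("  decks %.2f / %.2f, reversal p = %.2f at game boundaries\n",
              x$p_good, 1 - x$p_good, x$p_reversal))
  cat(sprintf("  amounts $%s, slot p(win) = %.2f\n",
              paste(x$amounts, collapse = " / $"), x$slot_p_win))
  invisible(x)
}

# canonical column order of the trial table CSV interface
trial_table_columns <- c("subject_id", "session_id", "game", "round",
                         "trial_in_game", "player", "chosen_deck", "outcome",
                         "amount", "good_deck", "t_present", "t_choice",
                         "t_outcome", "t_offset")

# deck-choice policies for observed (and default self) players.
# "uniform" picks left/right equiprobably; "variance_seeking" alternates decks
# deterministically in a balanced schedule, emulating confederates designed to
# spread outcomes and amounts over trials.
policy_choice <- function(policy, trial_counter) {
  switch(policy,
         uniform = if (stats::runif(1) < 0.5) "left" else "right",
         variance_seeking = if (trial_counter %% 2L == 0L) "left" else "right",
         stop("unknown policy: ", policy))
}

#' Generate one card-game session
#'
#' Simulates a full session of the card game: the good deck is drawn uniformly
#' for the first game and flips with probability \code{p_reversal} at every
#' subsequent game boundary; each trial's deck choice comes from the player's
#' policy, the win/lose outcome is Bernoulli with the chosen deck's payout
#' probability, and the magnitude is drawn equiprobably from
#' \code{config$amounts} (signed by the outcome). Event times (presentation,
#' choice/highlight onset, outcome onset, outcome offset) are laid out on a
#' session clock in seconds; the highlight precedes the outcome by exactly
#' \code{highlight_s} and the outcome stays on for \code{outcome_s}.
#'
#' @param config a \code{\link{task_config}}.
#' @param seed integer seed; identical seed and config give a bit-identical
#'   session.
#' @param observed_policy deck-choice policy of the two observed players.
#' @param self_policy deck-choice policy of the subject used at generation
#'   time (closed-loop softmax behaviour is layered on by
#'   \code{\link{simulate_behaviour}}).
#' @param subject_id,session_id identifiers stamped into the trial table.
#' @return a data.frame of 180 trials (under the default config) with the
#'   canonical trial-table columns; attribute \code{"config"} carries the
#'   generating configuration.
#' @seealso \code{\link{generate_slot_session}}, \code{\link{write_trials}}
#' @export
generate_session <- function(config = task_config(), seed = 1L,
                             observed_policy = c("uniform", "variance_seeking"),
                             self_policy = "uniform",
                             subject_id = "S01", session_id = "S01_sess01") {
  stopifnot(inherits(config, "task_config"))
  observed_policy <- match.arg(observed_policy)
  set.seed(as.integer(seed))
  n_players <- length(config$players)
  n_trials <- config$n_games * config$rounds_per_game * n_players

  good <- character(config$n_games)
  good[1] <- if (stats::runif(1) < 0.5) "left" else "right"
  if (config$n_games > 1L) {
    for (g in 2:config$n_games) {
      flip <- stats::runif(1) < config$p_reversal
      good[g] <- if (flip) setdiff(c("left", "right"), good[g - 1L]) else good[g - 1L]
    }
  }

  game <- rep(seq_len(config$n_games),
              each = config$rounds_per_game * n_players)
  round <- rep(rep(seq_len(config$rounds_per_game), each = n_players),
               times = config$n_games)
  trial_in_game <- rep(seq_len(config$rounds_per_game * n_players),
                       times = config$n_games)
  player <- rep(config$players, times = config$n_games * config$rounds_per_game)

  chosen <- character(n_trials)
  outcome <- character(n_trials)
  amount <- numeric(n_trials)
  for (i in seq_len(n_trials)) {
    pol <- if (player[i] == "self") self_policy else observed_policy
    chosen[i] <- policy_choice(pol, i)
    p_win <- if (chosen[i] == good[game[i]]) config$p_good else 1 - config$p_good
    win <- stats::runif(1) < p_win
    outcome[i] <- if (win) "win" else "lose"
    mag <- sample(config$amounts, 1L)
    amount[i] <- if (win) mag else -mag
  }

  trial_span <- config$choice_s + config$highlight_s + config$outcome_s +
    config$iti_s
  t_present <- (seq_len(n_trials) - 1L) * trial_span
  t_choice <- t_present + config$choice_s
  t_outcome <- t_choice + config$highlight_s
  t_offset <- t_outcome + config$outcome_s

  out <- data.frame(subject_id = subject_id, session_id = session_id,
                    game = game, round = round,
                    trial_in_game = trial_in_game, player = player,
                    chosen_deck = chosen, outcome = outcome, amount = amount,
                    good_deck = good[game],
                    t_present = t_present, t_choice = t_choice,
                    t_outcome = t_outcome, t_offset = t_offset,
                    stringsAsFactors = FALSE)
  attr(out, "config") <- config
  out
}

#' Generate a slot-machine session
#'
#' Each trial wins with probability \code{config$slot_p_win}; a win doubles
#' the running total and a loss halves it, so a non-negative starting total
#' can never go below zero.
#'
#' @param config a \code{\link{task_config}}.
#' @param n_trials number of slot trials (the study average was about 80).
#' @param starting_total non-negative starting amount in dollars.
#' @param seed integer seed.
#' @param t_start session-clock time of the first slot outcome, seconds.
#' @param trial_spacing_s seconds between consecutive slot outcomes.
#' @return data.frame with columns trial, outcome, total (after the trial),
#'   t_outcome.
#' @export
generate_slot_session <- function(config = task_config(), n_trials = 80L,
                                  starting_total = 100, seed = 1L,
                                  t_start = 0, trial_spacing_s = 7) {
  stopifnot(inherits(config, "task_config"))
  n_trials <- as.integer(n_trials)
  if (is.na(n_trials) || n_trials < 1L) stop("n_trials must be >= 1")
  if (starting_total < 0) stop("starting_total must be non-negative")
  set.seed(as.integer(seed))
  win <- stats::runif(n_trials) < config$slot_p_win
  total <- numeric(n_trials)
  cur <- starting_total
  for (i in seq_len(n_trials)) {
    cur <- if (win[i]) 2 * cur else cur / 2
    total[i] <- cur
  }
  data.frame(trial = seq_len(n_trials),
             outcome = ifelse(win, "win", "lose"),
             total = total,
             t_outcome = t_start + (seq_len(n_trials) - 1L) * trial_spacing_s)
}

#' Write / read a trial table CSV
#'
#' Fixed-header CSV, one row per trial, times in seconds with a decimal
#' point and no locale grouping.
#'
#' @param trials trial table as produced by \code{\link{generate_session}}.
#' @param path file path.
#' @return \code{read_trials} returns the trial table data.frame.
#' @export
write_trials <- function(trials, path) {
  missing_cols <- setdiff(trial_table_columns, names(trials))
  if (length(missing_cols))
    stop("trial table is missing columns: ", paste(missing_cols, collapse = ", "))
  utils::write.csv(trials[, c(trial_table_columns,
                              setdiff(names(trials), trial_table_columns))],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(trial_table_columns, names(out))
  if (length(missing_cols))
    stop("file ", path, " is missing columns: ",
         paste(missing_cols, collapse = ", "))
  out
}
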