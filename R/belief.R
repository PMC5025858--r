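# Grid belief over the reward contingency q (deck "left" pays out with
# probability q) and the reversal hazard v. The belief is a joint probability
# mass over a q x v lattice; all learner computations marginalise this mass.
# Grid masses carry trapezoidal quadrature weights so that expectations over
# the lattice match the continuous integrals to second order in the spacing
# (an equal-weight endpoint grid would bias posterior means at first order).

trapezoid_weights <- function(x) {
  n <- length(x)
  w <- rep(1, n)
  w[c(1, n)] <- 0.5
  w / sum(w)
}

#' Initialise a uniform grid belief
#'
#' The belief state is a joint probability mass over support points for the
#' reward contingency q (probability that the left deck wins) and the
#' reversal hazard v. Both grids span [0, 1]; the q grid must be symmetric
#' about 0.5 so that a reversal is an exact mirror operation on the lattice.
#' The prior is a uniform density over the joint grid, represented with
#' trapezoidal quadrature weights, giving a marginal mean of q of exactly
#' 0.5.
#'
#' @param n_q number of q support points (default 101, i.e. 0.01 spacing).
#' @param n_v number of v support points (default 21).
#' @return object of class \code{grid_belief}: list with \code{q}, \code{v}
#'   and the joint \code{mass} matrix (rows index q).
#' @export
init_belief <- function(n_q = 101L, n_v = 21L) {
  n_q <- as.integer(n_q); n_v <- as.integer(n_v)
  if (is.na(n_q) || n_q < 2L || is.na(n_v) || n_v < 2L)
    stop("grid sizes must be >= 2")
  q <- seq(0, 1, length.out = n_q)
  v <- seq(0, 1, length.out = n_v)
  mass <- outer(trapezoid_weights(q), trapezoid_weights(v))
  structure(list(q = q, v = v, mass = mass), class = "grid_belief")
}

belief_check <- function(belief) {
  if (!inherits(belief, "grid_belief")) stop("not a grid_belief")
  tot <- sum(belief$mass)
  if (abs(tot - 1) > 1e-8) stop("belief mass is not normalised")
  invisible(belief)
}

#' Reversal transition of a grid belief
#'
#' Turns the posterior of the previous trial into the prior of the current
#' trial. At a reversal opportunity, for each hazard value v the mass over q
#' becomes a mixture of itself and its mirror image:
#' \code{(1 - v) * m(q) + v * m(1 - q)}. Away from reversal opportunities the
#' belief passes through unchanged. An explicit hazard can override the grid
#' (\code{v_override}), which is used by tests and by the hazard-free mode.
#'
#' @param belief a \code{grid_belief}.
#' @param at_opportunity logical; is this trial a reversal opportunity?
#' @param v_override optional scalar hazard applied uniformly instead of the
#'   belief's own v grid.
#' @return the transitioned \code{grid_belief}.
#' @export
belief_transition <- function(belief, at_opportunity = TRUE,
                              v_override = NULL) {
  belief_check(belief)
  if (!at_opportunity) return(belief)
  m <- belief$mass
  flipped <- m[rev(seq_along(belief$q)), , drop = FALSE]
  v <- if (is.null(v_override)) rep(belief$v, each = nrow(m)) else v_override
  vmat <- matrix(v, nrow(m), ncol(m))
  m2 <- (1 - vmat) * m + vmat * flipped
  belief$mass <- m2 / sum(m2)
  belief
}

#' Bayesian outcome update of a grid belief
#'
#' One observed trial fully determines the contingency evidence: a win on the
#' left deck (equivalently a loss on the right deck) has likelihood q, and
#' the complementary observations have likelihood 1 - q. The posterior is the
#' normalised product of likelihood and prior, independently for every hazard
#' column.
#'
#' @param belief a \code{grid_belief}.
#' @param deck "left" or "right", the chosen deck.
#' @param outcome "win" or "lose".
#' @return the updated \code{grid_belief}.
#' @export
belief_update <- function(belief, deck, outcome) {
  belief_check(belief)
  if (!deck %in% c("left", "right")) stop("deck must be 'left' or 'right'")
  if (!outcome %in% c("win", "lose")) stop("outcome must be 'win' or 'lose'")
  left_win_evidence <- (deck == "left") == (outcome == "win")
  lik <- if (left_win_evidence) belief$q else 1 - belief$q
  m <- belief$mass * lik
  tot <- sum(m)
  if (tot <= 0) stop("zero total likelihood: belief degenerate at the boundary")
  belief$mass <- m / tot
  belief
}

#' Expected deck values from a grid belief
#'
#' The expected value of the left deck is the marginal posterior mean of q;
#' the right deck's value is its complement.
#'
#' @param belief a \code{grid_belief}.
#' @return named numeric vector \code{c(left = , right = )}.
#' @export
expected_value <- function(belief) {
  belief_check(belief)
  ev_left <- sum(rowSums(belief$mass) * belief$q)
  c(left = ev_left, right = 1 - ev_left)
}

# marginal posterior mean of the hazard v
posterior_mean_v <- function(belief) {
  sum(colSums(belief$mass) * belief$v)
}

#' Choice entropy of a two-deck value pair
#'
#' Shannon entropy, in bits, of the normalised two-deck win-probability
#' distribution; 1 bit when both decks look equal, 0 bits under certainty
#' (0 log 0 is taken as 0).
#'
#' @param ev numeric pair of expected values summing to 1.
#' @return entropy in bits.
#' @examples
#' choice_entropy(c(0.5, 0.5))  # 1
#' choice_entropy(c(0.7, 0.3))  # 0.8813
#' @export
choice_entropy <- function(ev) {
  if (length(ev) != 2L || any(ev < -1e-12) || any(ev > 1 + 1e-12))
    stop("ev must be a pair of probabilities")
  if (abs(sum(ev) - 1) > 1e-6) stop("ev pair must sum to 1")
  p <- pmin(pmax(ev, 0), 1)
  terms <- ifelse(p > 0, -p * log2(p), 0)
  sum(terms)
}

#' Softmax choice probability for the left deck
#'
#' @param ev numeric pair (left, right) of expected values.
#' @param tau positive softmax temperature; larger values flatten the choice
#'   probabilities towards 0.5.
#' @return probability of choosing the left deck, computed overflow-safely.
#' @examples
#' choice_probability(c(0.7, 0.3), tau = 0.1)  # 1 / (1 + exp(-4))
#' @export
choice_probability <- function(ev, tau) {
  if (!is.numeric(tau) || tau <= 0) stop("tau must be positive")
  if (length(ev) != 2L) stop("ev must be a pair")
  stats::plogis((ev[1] - ev[2]) / tau)
}

#' Reward prediction error
#'
#' Binary coding: outcome (1 for a win, 0 for a loss) minus the chosen
#' expected value, so delta lies in [-1, 1]. Amount coding: the signed dollar
#' amount obtained minus the chosen expected value put on the dollar scale,
#' \code{chosen_ev * scale}, where the default scale 55 is the mean winning
#' magnitude of the $10/$100 task.
#'
#' @param outcome "win" or "lose" (vectorised).
#' @param amount signed dollar amount obtained.
#' @param chosen_ev expected value of the chosen deck, in [0, 1].
#' @param coding "binary" or "amount".
#' @param scale dollar scale applied to the expected value under amount
#'   coding.
#' @return numeric prediction error(s).
#' @export
prediction_error <- function(outcome, amount, chosen_ev,
                             coding = c("binary", "amount"), scale = 55) {
  coding <- match.arg(coding)
  if (any(chosen_ev < 0 | chosen_ev > 1)) stop("chosen_ev must be in [0, 1]")
  if (!all(outcome %in% c("win", "lose"))) stop("unknown outcome label")
  if (coding == "binary") as.numeric(outcome == "win") - chosen_ev
  else amount - chosen_ev * scale
}
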