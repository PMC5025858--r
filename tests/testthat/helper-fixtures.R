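# Shared fixtures, built once per test run. Everything is generated in code
# under fixed seeds; nothing is read from disk.

fx <- new.env()

# one default session with closed-loop behaviour and learner output
fx_behaviour <- function() {
  if (is.null(fx$beh)) {
    sess <- generate_session(seed = 101)
    fx$beh <- simulate_behaviour(sess, behaviour_params(), seed = 102)
  }
  fx$beh
}

# a small multi-subject behavioural cohort (6 subjects x 2 sessions)
fx_cohort_trials <- function() {
  if (is.null(fx$cohort)) {
    tabs <- list()
    for (s in 1:6) {
      for (k in 1:2) {
        sid <- sprintf("S%02d_sess%02d", s, k)
        sess <- generate_session(seed = 500 + 10 * s + k,
                                 subject_id = sprintf("S%02d", s),
                                 session_id = sid)
        beh <- simulate_behaviour(sess, behaviour_params(),
                                  seed = 700 + 10 * s + k)
        tabs[[sid]] <- beh$learner$trials
      }
    }
    fx$cohort <- do.call(rbind, tabs)
  }
  fx$cohort
}

# deterministic spike train: one spike at a fixed offset after each event
fx_spike_at <- function(events, offset_s) sort(events + offset_s)

# small unit-level GLM fixture: psth + design for one simulated unit
fx_unit_fit <- function(profile = "null", betas = list(), seed = 301) {
  beh <- fx_behaviour()
  tt <- beh$learner$trials
  m <- spike_model("u_fx", "rACC", profile, baseline = 2.3, betas = betas)
  st <- simulate_unit(m, tt, seed = seed)
  rm <- compute_psth(st, tt$t_outcome)
  X <- build_design_matrix(tt)
  list(trials = tt, rm = rm, X = X, fit = fit_sliding_glm(rm, X))
}

# small mixed neural cohort: 6 tripartite + 8 null rACC units and 5 AMY
# same-sign amount coders, one shared session, lean permutation pools
fx_neural_cohort <- function() {
  if (is.null(fx$ncohort)) {
    beh <- fx_behaviour()
    tt <- beh$learner$trials
    sessions <- list()
    sessions[[tt$session_id[1]]] <- tt
    specs <- c(rep("trip", 6), rep("null", 8), rep("amy", 5))
    trains <- lapply(seq_along(specs), function(i) {
      m <- switch(specs[i],
        trip = spike_model(sprintf("u%02d", i), "rACC", "tripartite_PE",
                           baseline = 2.3,
                           betas = list(ev_choice = 12, amount = 12,
                                        ev_outcome = 20, amount_self = -6,
                                        main = 4)),
        null = spike_model(sprintf("u%02d", i), "rACC", "null",
                           baseline = 2.3),
        amy = spike_model(sprintf("u%02d", i), "AMY", "amount",
                          baseline = 2.3,
                          betas = list(amount = 8, amount_self = 8,
                                       main = 2)))
      st <- simulate_unit(m, tt, seed = 4000 + 13 * i)
      st$session_id <- tt$session_id[1]
      st
    })
    fx$ncohort <- sliding_glm_cohort(trains, sessions, n_perm = 40,
                                     seed = 4999)
  }
  fx$ncohort
}
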