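# deterministic sub-seed derivation: one root seed, streams by counter
derive_seed <- function(root, k) {
  as.integer((as.double(root) + 104729 * as.double(k)) %% 2147483647)
}

#' Specification of a synthetic single unit
#'
#' Defines the firing-rate model of one simulated neuron: a constant
#' baseline plus event-locked half-cosine response bumps whose gains are set
#' by the coding profile. Profiles:
#' \describe{
#'   \item{null}{baseline only (plus an optional outcome-locked main
#'     response).}
#'   \item{outcome}{gain \code{outcome} times the outcome sign (+1 win, -1
#'     loss) at outcome, all card trials.}
#'   \item{shadenfreude}{as \code{outcome} but with the sign flipped on
#'     observed trials (fires for self wins and observed losses).}
#'   \item{amount}{gain \code{amount} times the signed amount (in units of
#'     $100) at outcome on observed trials, and \code{amount_self} likewise
#'     on self trials; same-sign gains give an amygdala-like unit, an
#'     opposite-sign \code{amount_self} an rACC-like unit.}
#'   \item{tripartite_PE}{the temporal-difference signature on observed
#'     trials: \code{ev_choice} times the (centred) expected value at the
#'     observed choice, plus \code{amount} times the amount and minus
#'     \code{ev_outcome} times the expected value after the outcome.}
#' }
#'
#' @param unit_id unit identifier.
#' @param area area label, e.g. "AMY", "rmPFC", "rACC".
#' @param profile coding profile, see Details.
#' @param baseline baseline rate, Hz (study-scale means are about 2-2.5 Hz).
#' @param betas named list of gains in Hz per unit regressor; recognised
#'   names: \code{main}, \code{outcome}, \code{amount}, \code{amount_self},
#'   \code{ev_choice}, \code{ev_outcome}.
#' @param kernel_onset,kernel_dur response-kernel onset latency and duration
#'   in seconds (default bump spans 0.25-0.85 s after its event).
#' @param refractory_s dead time imposed after each spike, seconds.
#' @return list of class \code{spike_model}.
#' @export
spike_model <- function(unit_id, area = "rACC",
                        profile = c("null", "outcome", "amount",
                                    "tripartite_PE", "shadenfreude"),
                        baseline = 2.3, betas = list(),
                        kernel_onset = 0.25, kernel_dur = 0.6,
                        refractory_s = 0.002) {
  profile <- match.arg(profile)
  if (baseline < 0) stop("baseline rate must be non-negative")
  defaults <- list(main = 0, outcome = 0, amount = 0, amount_self = 0,
                   ev_choice = 0, ev_outcome = 0)
  defaults[names(betas)] <- betas
  structure(list(unit_id = unit_id, area = area, profile = profile,
                 baseline = baseline, betas = defaults,
                 kernel_onset = kernel_onset, kernel_dur = kernel_dur,
                 refractory_s = refractory_s),
            class = "spike_model")
}

# half-cosine response bump, peak 1, support [onset, onset + dur]
response_kernel <- function(u, onset, dur) {
  out <- numeric(length(u))
  inside <- u >= onset & u <= onset + dur
  out[inside] <- 0.5 * (1 - cos(2 * pi * (u[inside] - onset) / dur))
  out
}

# per-trial event gains implied by a coding profile; modulators are centred
# within trial type so planted responses do not move the mean rate
profile_gains <- function(model, trials) {
  b <- model$betas
  n <- nrow(trials)
  g_choice <- numeric(n)   # gain of the bump locked to the choice highlight
  g_outcome <- rep(b$main, n)  # gain of the bump locked to the outcome
  is_obs <- trials$player != "self"
  sgn <- ifelse(trials$outcome == "win", 1, -1)
  amt <- trials$amount / 100
  ev <- trials$chosen_ev
  if (is.null(ev) && model$profile %in% c("tripartite_PE"))
    stop("tripartite_PE profile needs learner expected values in the trials")
  center <- function(x, grp) x - stats::ave(x, grp, FUN = mean)
  if (model$profile == "outcome") {
    g_outcome <- g_outcome + b$outcome * sgn
  } else if (model$profile == "shadenfreude") {
    g_outcome <- g_outcome + b$outcome * sgn * ifelse(is_obs, -1, 1)
  } else if (model$profile == "amount") {
    g_outcome <- g_outcome + ifelse(is_obs, b$amount, b$amount_self) * amt
  } else if (model$profile == "tripartite_PE") {
    evc <- center(ev, trials$player)
    g_choice <- g_choice + ifelse(is_obs, b$ev_choice * evc, 0)
    g_outcome <- g_outcome +
      ifelse(is_obs, b$amount * amt - b$ev_outcome * evc,
             b$amount_self * amt)
  }
  list(choice = g_choice, outcome = g_outcome)
}

#' Simulate an inhomogeneous Poisson spike train for one unit
#'
#' The rate function is the unit baseline plus event-locked half-cosine
#' bumps with trial-specific gains set by the coding profile; the rate is
#' clipped at zero before sampling. Spikes are drawn per time bin
#' (\code{dt}) as Poisson counts and jittered uniformly within the bin; a
#' short refractory dead time then removes near-coincident spikes.
#'
#' @param model a \code{\link{spike_model}}.
#' @param trials trial table; if the profile needs expected values the table
#'   must carry a \code{chosen_ev} column (e.g. the \code{$trials} of a
#'   \code{\link{reversal_learner}}).
#' @param seed integer seed.
#' @param t_end session duration in seconds (default: last offset + 5 s).
#' @param dt sampling resolution in seconds.
#' @return list of class \code{spike_train}: \code{unit_id}, \code{area},
#'   strictly increasing spike \code{times} in seconds.
#' @export
simulate_unit <- function(model, trials, seed = 1L, t_end = NULL,
                          dt = 0.005) {
  stopifnot(inherits(model, "spike_model"))
  if (is.null(t_end)) t_end <- max(trials$t_offset) + 5
  set.seed(as.integer(seed))
  grid_t <- seq(0, t_end, by = dt)
  rate <- rep(model$baseline, length(grid_t))
  gains <- profile_gains(model, trials)
  add_bump <- function(rate, t_event, gain) {
    if (gain == 0) return(rate)
    i0 <- floor((t_event + model$kernel_onset) / dt) + 1
    i1 <- ceiling((t_event + model$kernel_onset + model$kernel_dur) / dt) + 1
    idx <- max(1, i0):min(length(rate), i1)
    rate[idx] <- rate[idx] +
      gain * response_kernel(grid_t[idx] - t_event,
                             model$kernel_onset, model$kernel_dur)
    rate
  }
  for (k in seq_len(nrow(trials))) {
    rate <- add_bump(rate, trials$t_choice[k], gains$choice[k])
    rate <- add_bump(rate, trials$t_outcome[k], gains$outcome[k])
  }
  rate <- pmax(rate, 0)
  counts <- stats::rpois(length(rate), rate * dt)
  reps <- counts > 0
  times <- rep(grid_t[reps], counts[reps]) +
    stats::runif(sum(counts), 0, dt)
  times <- sort(times)
  if (model$refractory_s > 0 && length(times) > 1) {
    keep <- c(TRUE, diff(times) >= model$refractory_s)
    times <- times[keep]
  }
  structure(list(unit_id = model$unit_id, area = model$area, times = times),
            class = "spike_train")
}

#' Generate a complete synthetic cohort on disk
#'
#' Simulates a multi-subject dataset mirroring the study's shape: sessions
#' are distributed round-robin over subjects, each session is generated by
#' the task engine with closed-loop softmax behaviour, and every unit in the
#' population specification is simulated against one session. Trial tables,
#' learner outputs and spike times are written as CSV, with a JSON manifest
#' listing files, seeds and checksums; re-running with the same seed gives
#' byte-identical files.
#'
#' @param dir output directory (created if needed).
#' @param n_subjects number of subjects (study: 10).
#' @param n_sessions total sessions (study: 31).
#' @param units data.frame with columns \code{area}, \code{profile},
#'   \code{n}, and optionally \code{beta} (scalar multiplier on the
#'   profile's default planted gains) and \code{self_sign} (sign of the
#'   self-trial amount loading for the \code{amount} profile: +1 gives
#'   amygdala-like same-sign coding, -1 rACC-like opposite-sign coding);
#'   NULL for a behaviour-only cohort.
#' @param params \code{\link{behaviour_params}} of the simulated subjects.
#' @param config \code{\link{task_config}}.
#' @param seed root seed; all per-session and per-unit streams are derived
#'   from it by counter.
#' @param baseline baseline firing rate for simulated units, Hz.
#' @return invisibly, the manifest list.
#' @export
generate_cohort <- function(dir, n_subjects = 10L, n_sessions = 31L,
                            units = NULL, params = behaviour_params(),
                            config = task_config(), seed = 1L,
                            baseline = 2.3) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  subj <- sprintf("S%02d", rep(seq_len(n_subjects), length.out = n_sessions))
  files <- list()
  session_ids <- character(n_sessions)
  for (i in seq_len(n_sessions)) {
    sid <- sprintf("%s_sess%02d", subj[i], i)
    session_ids[i] <- sid
    sess <- generate_session(config, seed = derive_seed(seed, i),
                             subject_id = subj[i], session_id = sid)
    beh <- simulate_behaviour(sess, params, seed = derive_seed(seed, 1000 + i))
    tf <- file.path(dir, paste0(sid, "_trials.csv"))
    lf <- file.path(dir, paste0(sid, "_learner.csv"))
    write_trials(beh$trials, tf)
    write_learner_output(beh$learner, lf)
    files[[sid]] <- list(trials = basename(tf), learner = basename(lf))
  }
  unit_rows <- NULL
  if (!is.null(units) && nrow(units) > 0 && sum(units$n) > 0) {
    uid <- 0L
    spikes <- vector("list", sum(units$n))
    for (r in seq_len(nrow(units))) {
      for (j in seq_len(units$n[r])) {
        uid <- uid + 1L
        sid <- session_ids[(uid - 1L) %% n_sessions + 1L]
        ltab <- read_learner_output(file.path(dir, files[[sid]]$learner))
        ttab <- read_trials(file.path(dir, files[[sid]]$trials))
        ttab$chosen_ev <- ltab$chosen_ev
        beta <- if ("beta" %in% names(units)) units$beta[r] else 1
        ssign <- if ("self_sign" %in% names(units)) units$self_sign[r] else 1
        # default planted gains (Hz per unit regressor), scaled by beta;
        # sized so that every downstream analysis can recover its own
        # planted effect at study-scale unit counts
        b <- switch(units$profile[r],
                    null = list(),
                    outcome = list(outcome = 8 * beta, main = 4 * beta),
                    shadenfreude = list(outcome = 8 * beta, main = 4 * beta),
                    amount = list(amount = 8 * beta,
                                  amount_self = 8 * beta * ssign,
                                  main = 4 * beta),
                    tripartite_PE = list(ev_choice = 12 * beta,
                                         amount = 12 * beta,
                                         ev_outcome = 20 * beta,
                                         main = 4 * beta))
        m <- spike_model(sprintf("u%03d", uid), area = units$area[r],
                         profile = units$profile[r], baseline = baseline,
                         betas = b)
        st <- simulate_unit(m, ttab, seed = derive_seed(seed, 2000 + uid))
        spikes[[uid]] <- data.frame(unit_id = st$unit_id, area = st$area,
                                    session_id = sid,
                                    spike_time_s = st$times)
      }
    }
    sp <- do.call(rbind, spikes)
    sf <- file.path(dir, "spikes.csv")
    utils::write.csv(sp, sf, row.names = FALSE, quote = FALSE)
    unit_rows <- sf
    files$spikes <- basename(sf)
  }
  manifest <- list(
    n_subjects = n_subjects, n_sessions = n_sessions, seed = seed,
    population = if (is.null(units)) list() else units,
    files = files,
    checksums = as.list(tools::md5sum(
      sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE)))))
  names(manifest$checksums) <- basename(names(manifest$checksums))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a spike-time CSV into per-unit spike trains
#'
#' @param path spikes.csv written by \code{\link{generate_cohort}}.
#' @return named list of \code{spike_train} objects.
#' @export
read_spikes <- function(path) {
  sp <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(split(sp, sp$unit_id), function(d) {
    structure(list(unit_id = d$unit_id[1], area = d$area[1],
                   session_id = if ("session_id" %in% names(d))
                     d$session_id[1] else NA_character_,
                   times = sort(d$spike_time_s)),
              class = "spike_train")
  })
  out[order(names(out))]
}
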