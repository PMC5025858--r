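test_that("single-spike arithmetic and the half-open window convention", {
  events <- c(10, 20, 30)
  spikes <- fx_spike_at(events, 0)     # one spike exactly at each event
  rm <- compute_psth(spikes, events, span = c(-1000, 1000))
  # every window covering t = 0 sees 1 spike / 0.3 s
  covered <- rm$centers > -150 & rm$centers <= 150
  expect_true(all(abs(rm$rate[, covered] - 1 / 0.3) < 1e-9))
  expect_true(all(rm$rate[, !covered] == 0))
  # half-open [lo, hi): a spike at center + 150 is outside that window,
  # inside the next
  rm2 <- compute_psth(10.150, 10, span = c(0, 0))   # single bin at center 0
  expect_equal(as.numeric(rm2$rate), 0)
  rm3 <- compute_psth(10.150, 10, span = c(10, 10)) # center 10: [−140, 160)
  expect_equal(as.numeric(rm3$rate), 1 / 0.3)
  # bin spacing is exactly the step
  expect_true(all(diff(rm$centers) == 10))
  expect_error(compute_psth(spikes, numeric(0)), "empty event")
})

test_that("PSTH conserves spike mass and recovers a homogeneous rate", {
  set.seed(77)
  events <- seq(50, 950, by = 9)
  spikes <- sort(runif(2 * 1000, 0, 1000))   # 2 Hz homogeneous
  rm <- compute_psth(spikes, events, span = c(-3000, 2000))
  expect_lt(abs(mean(rm$rate) - 2), 0.15)
  # mass conservation on a fixture train: counts in one window equal
  # rate * window for a single event
  ev <- 500
  rm1 <- compute_psth(spikes, ev, span = c(0, 0))
  manual <- sum(spikes >= ev - 0.150 & spikes < ev + 0.150)
  expect_equal(as.numeric(rm1$rate) * 0.3, manual)
})

test_that("outcome-responsive selection separates planted from null units", {
  tt <- fx_behaviour()$learner$trials
  mk_rate <- function(profile, betas, seed)
    compute_psth(simulate_unit(spike_model("u", "rACC", profile, baseline = 2,
                                           betas = betas), tt, seed = seed),
                 tt$t_outcome)
  planted <- lapply(1:4, function(i)
    mk_rate("outcome", list(main = 6, outcome = 2), 800 + i))
  nulls <- lapply(1:4, function(i) mk_rate("null", list(), 900 + i))
  sel <- select_outcome_responsive(c(planted, nulls))
  expect_true(all(sel$selected[1:4]))
  expect_true(all(sel$crit1[1:4]))
  expect_true(sum(sel$selected[5:8]) <= 1)
  # identical pre/post rates are never selected: a constant-rate unit
  const <- compute_psth(seq(0.05, 2000, by = 0.4), tt$t_outcome)
  sel_c <- select_outcome_responsive(list(const))
  expect_false(sel_c$selected)
})

test_that("bootstrap envelope localises onset and scales amplitude", {
  # noiseless step-like units: kernel onset at 250 ms, strong response
  tt <- fx_behaviour()$learner$trials
  units <- lapply(1:6, function(i)
    compute_psth(simulate_unit(spike_model(paste0("u", i), "rACC", "outcome",
                                           baseline = 2,
                                           betas = list(main = 30)),
                               tt, seed = 700 + i), tt$t_outcome))
  env <- bootstrap_envelope(units, n_boot = 200, seed = 3)
  expect_false(env$flat)
  # half-max of a half-cosine bump starting at 250 ms with 600 ms duration
  # is reached at 400 ms; allow smoothing bias of about one kernel SD
  expect_lt(abs(env$onset_ms$estimate - 400), 80)
  expect_gt(env$amplitude$estimate, 10)
  # doubling all rates doubles amplitude, onset unchanged
  units2 <- lapply(units, function(rm) { rm$rate <- rm$rate * 2; rm })
  env2 <- bootstrap_envelope(units2, n_boot = 200, seed = 3)
  expect_equal(env2$amplitude$estimate, 2 * env$amplitude$estimate,
               tolerance = 1e-9)
  expect_equal(env2$onset_ms$estimate, env$onset_ms$estimate)
  # constant-rate units: amplitude CI covers 0
  flat_units <- lapply(1:4, function(i)
    compute_psth(simulate_unit(spike_model(paste0("f", i), "rACC", "null",
                                           baseline = 2), tt, seed = 60 + i),
                 tt$t_outcome))
  envf <- bootstrap_envelope(flat_units, n_boot = 200, seed = 4)
  expect_lt(envf$amplitude$ci[1], max(0.05, envf$amplitude$estimate))
  expect_error(bootstrap_envelope(units[1]), "at least 2")
})

test_that("win/lose response differences behave under planting and symmetry", {
  tt <- fx_behaviour()$learner$trials
  mk <- function(profile, betas, seed)
    compute_psth(simulate_unit(spike_model("u", "rACC", profile, baseline = 2,
                                           betas = betas), tt, seed = seed),
                 tt$t_outcome)
  planted <- lapply(1:3, function(i) mk("outcome", list(outcome = 8), 30 + i))
  labs <- replicate(3, tt$outcome, simplify = FALSE)
  res <- mean_response_difference(planted, labs, n_boot = 100, seed = 5)
  expect_true(all(res$exceeds))
  post <- res$centers >= 300 & res$centers <= 900
  pre <- res$centers >= -1500 & res$centers <= 0
  expect_gt(mean(res$course[, post]), mean(res$course[, pre]))
  # label swap leaves the absolute difference course unchanged
  labs_swapped <- lapply(labs, function(l) ifelse(l == "win", "lose", "win"))
  res_sw <- mean_response_difference(planted, labs_swapped, n_boot = 100,
                                     seed = 5)
  expect_equal(res_sw$course, res$course, tolerance = 1e-12)
  expect_error(mean_response_difference(planted,
                                        list(rep("win", 180))[rep(1, 3)]),
               "missing win or lose")
})

test_that("cross-task correlation flags shared coding and identity", {
  set.seed(99)
  n_units <- 20; n_bins <- 121
  centers <- seq(-600, 600, by = 10)
  shared <- matrix(rnorm(n_units), n_units, n_bins) +
    matrix(rnorm(n_units * n_bins, sd = 0.3), n_units)
  a <- shared + matrix(rnorm(n_units * n_bins, sd = 0.3), n_units)
  b <- shared + matrix(rnorm(n_units * n_bins, sd = 0.3), n_units)
  indep <- matrix(rnorm(n_units * n_bins), n_units)
  res <- response_difference_correlation(list(self = a, observed = b,
                                              slot = indep),
                                         centers, window = c(-300, 300))
  row_ab <- res[res$pair == "self_vs_observed", ]
  expect_true(row_ab$significant)
  expect_gt(row_ab$r, 0.5)
  expect_false(res$significant[res$pair == "self_vs_slot"])
  # perfectly duplicated difference courses correlate at exactly 1
  res_dup <- response_difference_correlation(list(x = a, y = a, z = a),
                                             centers, window = c(-300, 300))
  expect_equal(res_dup$r, rep(1, 3), tolerance = 1e-12)
  expect_error(response_difference_correlation(list(x = a[1:2, ], y = b[1:2, ]),
                                               centers), "at least 3")
})
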