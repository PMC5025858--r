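test_that("closed-loop behaviour keeps the session structure intact", {
  beh <- fx_behaviour()
  tr <- beh$trials
  expect_equal(nrow(tr), 180)
  self <- tr$player == "self"
  expect_true(all(is.finite(tr$choice_time[self])))
  expect_true(all(is.na(tr$choice_time[!self])))
  expect_true(all(tr$choice_time[self] >= behaviour_params()$ct_floor))
  expect_true(all(sign(tr$amount) == ifelse(tr$outcome == "win", 1, -1)))
  # self choices favour the good deck at tau = 0.2
  expect_gt(mean(tr$chosen_deck[self] == tr$good_deck[self]), 0.55)
})

test_that("flat softmax yields unbiased deck choices; zero slope kills the CT effect", {
  sess <- generate_session(seed = 11)
  flat <- simulate_behaviour(sess, behaviour_params(tau = 1e6), seed = 12)
  picks <- flat$trials$chosen_deck[flat$trials$player == "self"]
  # pooled over several sessions for power
  for (k in 1:5) {
    s <- generate_session(seed = 11 + k)
    b <- simulate_behaviour(s, behaviour_params(tau = 1e6), seed = 12 + k)
    picks <- c(picks, b$trials$chosen_deck[b$trials$player == "self"])
  }
  expect_lt(abs(mean(picks == "left") - 0.5), 3 * sqrt(0.25 / length(picks)))

  nos <- simulate_behaviour(sess, behaviour_params(ct_entropy_slope = 0,
                                                   ct_round1_extra = 0),
                            seed = 13)
  tt <- nos$learner$trials
  self <- tt$player == "self"
  r <- cor(tt$choice_time[self], tt$ce[self])
  expect_lt(abs(r), 2.6 / sqrt(sum(self)))  # |r| within ~2.6 se of 0
})

test_that("a constant-rate unit is Poisson in count and dispersion", {
  tt <- fx_behaviour()$trials
  m <- spike_model("u0", "AMY", "null", baseline = 2)
  st <- simulate_unit(m, tt, seed = 5, t_end = 100)
  n <- length(st$times)
  expect_lt(abs(n - 200), 3 * sqrt(200))
  expect_true(!is.unsorted(st$times, strictly = TRUE))
  expect_true(all(st$times >= 0 & st$times <= 100))
  # variance/mean ratio of 1-s window counts near 1
  counts <- tabulate(findInterval(st$times, 0:99), nbins = 100)
  fano <- var(counts) / mean(counts)
  expect_lt(abs(fano - 1), 0.45)
  expect_error(spike_model("x", baseline = -1), "non-negative")
})

test_that("planted outcome coding appears where the kernel says it should", {
  tt <- fx_behaviour()$learner$trials
  m <- spike_model("u1", "rACC", "outcome", baseline = 2,
                   betas = list(outcome = 8))
  st <- simulate_unit(m, tt, seed = 6)
  rm <- compute_psth(st, tt$t_outcome)
  sel_resp <- rm$centers >= 300 & rm$centers <= 900
  sel_pre <- rm$centers >= -900 & rm$centers <= -300
  wins <- tt$outcome == "win"
  d_resp <- mean(rm$rate[wins, sel_resp]) - mean(rm$rate[!wins, sel_resp])
  d_pre <- mean(rm$rate[wins, sel_pre]) - mean(rm$rate[!wins, sel_pre])
  expect_gt(d_resp, 2)
  expect_lt(abs(d_pre), 1)
  # shadenfreude: sign flips between self and observed trials
  ms <- spike_model("u2", "rACC", "shadenfreude", baseline = 2,
                    betas = list(outcome = 8))
  sts <- simulate_unit(ms, tt, seed = 7)
  rms <- compute_psth(sts, tt$t_outcome)
  self <- tt$player == "self"
  d_self <- mean(rms$rate[self & wins, sel_resp]) -
    mean(rms$rate[self & !wins, sel_resp])
  d_obs <- mean(rms$rate[!self & wins, sel_resp]) -
    mean(rms$rate[!self & !wins, sel_resp])
  expect_gt(d_self, 1)
  expect_lt(d_obs, -1)
})

test_that("cohort generation is reproducible and complete", {
  dir1 <- file.path(tempdir(), "coh1")
  dir2 <- file.path(tempdir(), "coh2")
  unlink(c(dir1, dir2), recursive = TRUE)
  units <- data.frame(area = "rACC", profile = "null", n = 2)
  m1 <- generate_cohort(dir1, n_subjects = 2, n_sessions = 3, units = units,
                        seed = 77)
  m2 <- generate_cohort(dir2, n_subjects = 2, n_sessions = 3, units = units,
                        seed = 77)
  expect_identical(m1$checksums, m2$checksums)
  expect_true(file.exists(file.path(dir1, "manifest.json")))
  expect_true(file.exists(file.path(dir1, "spikes.csv")))
  expect_equal(length(setdiff(names(m1$files), "spikes")), 3L)
  # behavioural-only cohort has no neural branch
  dir3 <- file.path(tempdir(), "coh3")
  unlink(dir3, recursive = TRUE)
  m3 <- generate_cohort(dir3, n_subjects = 1, n_sessions = 1, units = NULL,
                        seed = 1)
  expect_false("spikes" %in% names(m3$files))
  expect_false(file.exists(file.path(dir3, "spikes.csv")))
  # a different seed changes the data
  dir4 <- file.path(tempdir(), "coh4")
  unlink(dir4, recursive = TRUE)
  m4 <- generate_cohort(dir4, n_subjects = 2, n_sessions = 3, units = units,
                        seed = 78)
  expect_false(identical(m1$checksums, m4$checksums))
})
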