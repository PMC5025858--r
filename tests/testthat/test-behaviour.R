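test_that("choice model recovers planted value sensitivity", {
  data <- fx_cohort_trials()
  fit <- fit_choice_model(data)
  g <- fit$group
  expect_equal(nrow(fit$per_subject) / 3, 6)   # 6 subjects x 3 terms
  ev_row <- g[g$term == "evdiff", ]
  expect_gt(ev_row$mean_beta, 0)
  expect_lt(ev_row$p, 0.05)
  expect_equal(unique(g$df), 5L)               # n_subjects - 1
  # constant predictor errors out naming the term
  degenerate <- data
  degenerate$ce <- 1
  expect_error(fit_choice_model(degenerate), "'ce'")
})

test_that("choice-time model recovers the planted entropy slope", {
  data <- fx_cohort_trials()
  fit <- fit_choice_time_model(data)
  ce_row <- fit$group[fit$group$term == "ce", ]
  expect_lt(ce_row$p, 0.05)
  # the planted slope (0.4 s/bit plus round-1 slowing loaded on CE) is
  # recovered within 3 group standard errors
  betas <- fit$per_subject[fit$per_subject$term == "ce", "beta"]
  se <- sd(betas) / sqrt(length(betas))
  expect_lt(abs(mean(betas) - 0.4), 3 * se + 0.3)
  # zero-noise data: exact coefficients, R^2 = 1
  sess <- generate_session(seed = 400)
  beh <- simulate_behaviour(sess, behaviour_params(ct_noise_sd = 1e-9,
                                                   ct_round1_extra = 0),
                            seed = 401)
  d <- beh$learner$trials
  ds <- d[d$player == "self", ]
  f <- lm(choice_time ~ I(ev_left - ev_right) + ce, data = ds)
  expect_equal(unname(coef(f)[3]), 0.4, tolerance = 1e-5)
  expect_gt(summary(f)$r.squared, 0.999)
  # non-positive choice times are dropped with a note
  d2 <- data
  d2$choice_time[which(d2$player == "self")[1:3]] <- -1
  f2 <- fit_choice_time_model(d2)
  expect_match(f2$notes, "3 non-positive")
})

test_that("lag roles follow the round structure and effects are recovered", {
  data <- fx_cohort_trials()
  # structural property: within a session, t-3 and t-6 from any self trial
  # are self trials, t-1/t-2/t-4/t-5 are observed
  one <- data[data$session_id == data$session_id[1], ]
  self_pos <- which(one$player == "self")
  for (t in self_pos[self_pos > 6]) {
    expect_true(all(one$player[t - c(3, 6)] == "self"))
    expect_true(all(one$player[t - c(1, 2, 4, 5)] != "self"))
  }
  expect_identical(sort(c(3L, 6L, 1L, 2L, 4L, 5L)), 1:6)
  fit <- lagged_outcome_regression(data)
  expect_setequal(fit$group$term, c("self", "observed"))
  # the closed-loop learner uses observed outcomes, so both aggregates are
  # positive at the group level
  expect_gt(fit$group$mean_beta[fit$group$term == "observed"], 0)
  expect_lt(fit$group$p[fit$group$term == "observed"], 0.05)
  expect_lt(fit$group$p[fit$group$term == "self"], 0.05)
  # logistic variant runs
  fit_l <- lagged_outcome_regression(data, family = "logistic")
  expect_s3_class(fit_l, "ob_regression")
})

test_that("lagged PE regression recovers PE-driven switching", {
  data <- fx_cohort_trials()
  fit <- lagged_pe_regression(data)
  expect_setequal(fit$group$term, c("self", "observed"))
  expect_lt(fit$group$p[fit$group$term == "observed"], 0.05)
  expect_gt(fit$group$mean_beta[fit$group$term == "observed"], 0)
  # the most recent self PE sits three trials back and is heavily discounted
  # by the Bayesian subject; at this cohort size it carries no stable effect,
  # so only the observed channel is asserted here (the self channel is
  # exercised by the lagged-outcome test above)
  # degenerate PEs error out
  d0 <- data
  d0$pe_amount <- 0
  expect_error(lagged_pe_regression(d0), "constant")
})

test_that("group inference reduces to the one-sample t-test", {
  toy <- data.frame(subject = rep(c("a", "b", "c"), each = 1),
                    term = "beta1", beta = c(0.4, 0.7, 0.1),
                    se = NA, n = 10)
  res <- oblearn:::make_regression_result(toy, directions = 1, model = "toy")
  b <- c(0.4, 0.7, 0.1)
  t_hand <- mean(b) / (sd(b) / sqrt(3))
  expect_equal(res$group$t, t_hand, tolerance = 1e-12)
  expect_equal(res$group$p, pt(t_hand, 2, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(res$group$df, 2L)
})

test_that("descriptive choice-time battery detects the planted contrasts", {
  data <- fx_cohort_trials()
  rt <- rt_descriptive_tests(data)
  expect_true(all(c("better_vs_worse_deck", "after_observed_win_vs_loss",
                    "left_vs_right", "coherence_spearman",
                    "anova_rounds_1_5", "anova_rounds_2_5") %in% rt$test))
  # planted round-1 slowing: significant over rounds 1-5, absent in 2-5
  expect_lt(rt$p[rt$test == "anova_rounds_1_5"], 0.01)
  expect_gt(rt$p[rt$test == "anova_rounds_2_5"], 0.01)
  # no side preference was planted
  expect_gt(rt$p[rt$test == "left_vs_right"], 0.01)
  # entropy-driven slowing implies faster choices after coherent evidence
  expect_lt(rt$statistic[rt$test == "coherence_spearman"], 0)
})
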