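test_that("the uniform prior is normalised, symmetric and maximally uncertain", {
  b <- init_belief(101, 21)
  expect_lt(abs(sum(b$mass) - 1), 1e-10)
  expect_equal(unname(expected_value(b)["left"]), 0.5, tolerance = 1e-12)
  expect_equal(choice_entropy(expected_value(b)), 1)
  # uniform density: interior cells all carry equal mass
  interior <- b$mass[2:100, 2:20]
  expect_lt(diff(range(interior)), 1e-15)
  expect_error(init_belief(1, 5), "grid sizes")
})

test_that("the reversal transition mixes with the mirror image", {
  b <- init_belief(51, 11)
  b <- belief_update(b, "left", "win")   # asymmetric mass
  # v_eff = 0: identity
  b0 <- belief_transition(b, at_opportunity = TRUE, v_override = 0)
  expect_equal(b0$mass, b$mass, tolerance = 1e-12)
  no_op <- belief_transition(b, at_opportunity = FALSE)
  expect_identical(no_op$mass, b$mass)
  # v_eff = 0.5: result symmetric in q
  b5 <- belief_transition(b, TRUE, v_override = 0.5)
  expect_equal(b5$mass, b5$mass[rev(seq_len(nrow(b5$mass))), ],
               tolerance = 1e-12)
  # v_eff = 1: exact mirror
  b1 <- belief_transition(b, TRUE, v_override = 1)
  expect_equal(b1$mass, b$mass[rev(seq_len(nrow(b$mass))), ],
               tolerance = 1e-12)
})

test_that("grid posterior matches the Beta-Bernoulli conjugate closed form", {
  # single left-deck win from uniform: Beta(2,1) mean 2/3
  b <- belief_update(init_belief(), "left", "win")
  expect_lt(abs(expected_value(b)["left"] - 2 / 3), 1e-3)
  # a win then a loss cancel exactly back to 1/2 (q(1-q) symmetric)
  b2 <- belief_update(b, "left", "lose")
  expect_equal(unname(expected_value(b2)["left"]), 0.5, tolerance = 1e-9)
  # 50 consecutive wins: Beta(51,1) mean within grid resolution
  b3 <- init_belief()
  for (i in 1:50) b3 <- belief_update(b3, "left", "win")
  expect_lt(abs(expected_value(b3)["left"] - 51 / 52), 0.01)
  # a right-deck loss is evidence FOR the left deck
  b4 <- belief_update(init_belief(), "right", "lose")
  expect_equal(unname(expected_value(b4)["left"]),
               unname(expected_value(b)["left"]), tolerance = 1e-12)
})

test_that("normalisation is preserved through arbitrary update sequences", {
  set.seed(5)
  b <- init_belief(41, 7)
  for (i in 1:100) {
    b <- belief_update(b, sample(c("left", "right"), 1),
                       sample(c("win", "lose"), 1))
    if (i %% 10 == 0) b <- belief_transition(b, TRUE)
    expect_lt(abs(sum(b$mass) - 1), 1e-10)
    expect_true(all(b$mass >= 0))
  }
})

test_that("choice entropy closed forms and domain checks", {
  expect_equal(choice_entropy(c(0.5, 0.5)), 1)
  expect_equal(choice_entropy(c(1, 0)), 0)
  expect_equal(choice_entropy(c(0.7, 0.3)),
               -0.7 * log2(0.7) - 0.3 * log2(0.3), tolerance = 1e-12)
  expect_equal(round(choice_entropy(c(0.7, 0.3)), 5), 0.88129)
  expect_error(choice_entropy(c(1.2, -0.2)), "probabilities")
  # strictly concave in EV1, maximised at 0.5
  evs <- seq(0.01, 0.99, by = 0.01)
  h <- vapply(evs, function(p) choice_entropy(c(p, 1 - p)), numeric(1))
  expect_equal(evs[which.max(h)], 0.5)
  expect_true(all(diff(h, differences = 2) < 0))
})

test_that("softmax choice probability closed forms", {
  expect_equal(choice_probability(c(0.4, 0.4), 0.2), 0.5)
  expect_equal(choice_probability(c(0.7, 0.3), 0.1), 1 / (1 + exp(-4)),
               tolerance = 1e-12)
  expect_equal(choice_probability(c(0.9, 0.1), 1e6), 0.5, tolerance = 1e-5)
  # overflow-safe at tiny temperature
  expect_equal(choice_probability(c(1, 0), 1e-9), 1)
  expect_error(choice_probability(c(0.5, 0.5), 0), "positive")
})

test_that("prediction errors follow both codings", {
  expect_equal(prediction_error("win", 10, 1, "binary"), 0)
  expect_equal(prediction_error("lose", -10, 0.7, "binary"), -0.7)
  expect_equal(prediction_error("win", 100, 0.5, "amount"), 100 - 0.5 * 55)
  expect_true(all(abs(prediction_error(c("win", "lose"), c(10, -100),
                                       c(0.2, 0.9), "binary")) <= 1))
  expect_error(prediction_error("draw", 0, 0.5), "outcome")
  expect_error(prediction_error("win", 10, 1.4), "chosen_ev")
})
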