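test_that("the nine-column design carries the trial structure", {
  u <- fx_unit_fit()
  X <- u$X
  expect_equal(dim(X), c(180L, 9L))
  # each event loads exactly one main effect
  mains <- unclass(X)[, c("self_main", "obs1_main", "obs2_main")]
  expect_true(all(rowSums(mains) == 1))
  # modulators are zero outside their trial type and centred within it
  self_rows <- u$trials$player == "self"
  expect_true(all(unclass(X)[!self_rows, c("self_ev", "self_amount")] == 0))
  expect_equal(sum(unclass(X)[self_rows, "self_ev"]), 0, tolerance = 1e-9)
  expect_equal(sum(unclass(X)[, "obs1_amount"]), 0, tolerance = 1e-9)
  # contrast algebra: the observed-PE contrast is amount minus EV
  cons <- attr(X, "contrasts")
  expect_equal(cons$obs_pe, cons$obs_amount - cons$obs_ev)
  # missing EVs are refused
  bad <- u$trials; bad$chosen_ev <- NULL
  expect_error(build_design_matrix(bad), "chosen_ev")
})

test_that("sliding GLM t-statistics recover planted signs and stay calibrated", {
  planted <- fx_unit_fit("tripartite_PE",
                         list(ev_choice = 8, amount = 8, ev_outcome = 8,
                              main = 2), seed = 311)
  f <- planted$fit
  resp <- f$centers >= 350 & f$centers <= 850
  choice <- f$centers >= -850 & f$centers <= -350
  expect_gt(mean(f$contrast_t$obs_amount[resp]), 1)
  expect_lt(mean(f$contrast_t$obs_ev[resp]), -0.5)
  expect_gt(mean(f$contrast_t$obs_ev[choice]), 0.5)
  # the PE contrast (amount minus EV) exceeds the amount-only projection
  # (t_amount / sqrt(2)) because the planted negative EV coding adds to it
  expect_gt(mean(f$contrast_t$obs_pe[resp]),
            mean(f$contrast_t$obs_amount[resp]) / sqrt(2))
  # a null unit's modulator t-values look Student-like (main-effect rows
  # test the baseline rate against zero and are excluded)
  nullu <- fx_unit_fit("null", seed = 312)
  mods <- c("self_ev", "self_amount", "obs1_ev", "obs1_amount",
            "obs2_ev", "obs2_amount")
  # overlapping windows correlate neighbouring bins, so the distributional
  # check uses every 30th bin (300 ms apart, disjoint windows)
  keep <- seq(1, length(nullu$fit$centers), by = 30)
  tv <- as.numeric(nullu$fit$t[mods, keep])
  ks <- suppressWarnings(ks.test(tv, "pt", df = nullu$fit$df))
  expect_gt(ks$p.value, 0.001)
  tv_all <- as.numeric(nullu$fit$t[mods, ])
  expect_lt(mean(abs(tv_all) > 2), 0.12)
  expect_lt(abs(mean(tv_all)), 0.25)
  # duplicated regressor triggers a rank error naming the column
  Xd <- unclass(planted$X)
  Xd[, "obs2_amount"] <- Xd[, "obs1_amount"]
  expect_error(oblearn:::ols_tcourses(cbind(Xd, dup = Xd[, "obs1_amount"]),
                                      planted$rm$rate[, 1:5]),
               "collinear")
})

test_that("a pure amount coder projects onto the PE contrast as amount alone", {
  amt <- fx_unit_fit("amount", list(amount = 8, amount_self = 8), seed = 313)
  f <- amt$fit
  resp <- f$centers >= 350 & f$centers <= 850
  # with no EV coding the PE contrast carries the amount effect alone,
  # attenuated by sqrt(2) for the extra (noise-only) EV columns it spans
  expect_gt(mean(f$contrast_t$obs_pe[resp]), 2)
  expect_lt(abs(mean(f$contrast_t$obs_pe[resp]) -
                  mean(f$contrast_t$obs_amount[resp]) / sqrt(2)), 1)
  expect_lt(mean(abs(f$contrast_t$obs_ev[resp])), 1)
})

test_that("cluster masses match a brute-force scan and trivial cases", {
  # constant t = 1 over k bins: one cluster of mass k
  cm <- oblearn:::cluster_masses(rep(1, 7), 0.2)
  expect_equal(nrow(cm$pos), 1L)
  expect_equal(cm$pos$mass, 7)
  expect_equal(nrow(cm$neg), 0L)
  # all-zero course: no clusters
  cm0 <- oblearn:::cluster_masses(rep(0, 50), 0.2)
  expect_equal(nrow(cm0$pos) + nrow(cm0$neg), 0L)
  # random courses against an independent brute-force scan
  set.seed(123)
  for (rep in 1:50) {
    tv <- rnorm(40, sd = 0.5)
    cm <- oblearn:::cluster_masses(tv, 0.2)
    runs_pos <- split(which(tv > 0.2),
                      cumsum(c(1, diff(which(tv > 0.2)) != 1)))
    brute_pos <- if (length(which(tv > 0.2)))
      sort(vapply(runs_pos, function(i) sum(tv[i]), numeric(1))) else numeric(0)
    expect_equal(sort(cm$pos$mass), unname(brute_pos), tolerance = 1e-12)
    em <- oblearn:::extreme_masses(tv, 0.2)
    expect_equal(unname(em["pos"]),
                 if (length(brute_pos)) max(brute_pos) else 0,
                 tolerance = 1e-12)
  }
})

test_that("cluster permutation test flags planted effects, not null ones", {
  beh <- fx_behaviour()
  tt <- beh$learner$trials
  mk <- function(profile, betas, seed) {
    st <- simulate_unit(spike_model("u", "rACC", profile, baseline = 2.3,
                                    betas = betas), tt, seed = seed)
    rm <- compute_psth(st, tt$t_outcome)
    X <- build_design_matrix(tt)
    list(fit = fit_sliding_glm(rm, X),
         perms = oblearn:::permuted_tcourses(rm, X, n_perm = 40,
                                             seed = seed + 1))
  }
  planted <- lapply(1:6, function(i)
    mk("amount", list(amount = 8, amount_self = 8), 2000 + 7 * i))
  obs <- do.call(rbind, lapply(planted, function(u) u$fit$contrast_t$obs_amount))
  pool <- lapply(planted, function(u) u$perms$obs_amount)
  ct <- cluster_permutation_test(obs, pool, n_shuffle = 500, seed = 5)
  expect_true(any(ct$clusters$significant & ct$clusters$sign == "pos"))
  # all-zero observed course: no clusters at all
  ct0 <- cluster_permutation_test(matrix(0, 3, ncol(obs)), pool,
                                  n_shuffle = 200, seed = 6)
  expect_equal(nrow(ct0$clusters), 0L)
  expect_warning(cluster_permutation_test(obs, pool, n_shuffle = 50, seed = 7),
                 "unstable")
})
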