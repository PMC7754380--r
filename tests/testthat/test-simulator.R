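test_that("scenario constants follow their stated distributions", {
  set.seed(51)
  sc_fix <- sim_scenario(if_fixed = 0.5, tau2 = 0.08)
  k <- draw_scenario_constants(sc_fix)
  expect_equal(k$IF, 0.5)
  expect_equal(k$tau2, 0.08)
  expect_equal(tau2_predictive_median(sc_fix), 0.08)

  sc_small <- sim_scenario(inconsistency = "low", tau2 = "small")
  draws <- purrr::map(1:20000, function(i) draw_scenario_constants(sc_small))
  ifs <- purrr::map_dbl(draws, "IF")
  t2s <- purrr::map_dbl(draws, "tau2")
  expect_equal(median(ifs), 0, tolerance = 0.02)     # symmetric t around 0
  expect_equal(median(t2s), exp(-3.95), tolerance = 0.05)

  sc_mod <- sim_scenario(inconsistency = "moderate", tau2 = "substantial")
  expect_equal(sc_mod$if_center, 1)
  expect_equal(tau2_predictive_median(sc_mod), exp(-2.56))
})

test_that("complete networks respect sizes, risks, and the consistency
           equation for trial-level effects", {
  set.seed(61)
  sc <- sim_scenario(if_fixed = 0.3, tau2 = 0.04, mechanism = "mar")
  arms <- purrr::map_dfr(1:250, function(i) simulate_complete_network(sc)$arms)

  pc <- arms$comparison %in% c("NP", "OP")
  expect_true(all(arms$n[pc] >= 102 & arms$n[pc] <= 187))
  expect_true(all(arms$n[!pc] >= 128 & arms$n[!pc] <= 241))
  expect_true(all(arms$p > 0 & arms$p < 1))
  expect_true(all(arms$r_complete >= 0 & arms$r_complete <= arms$n))

  # per-trial true log OR: lor + shared trial deviation, identical in both arms
  expect_true(all(abs(arms$lor_trial[c(TRUE, FALSE)] -
                        arms$lor_trial[c(FALSE, TRUE)]) < 1e-12))
  # mu_NO = mu_NP - mu_OP + IF exactly
  no <- arms[arms$comparison == "NO", ]
  expect_equal(unique(no$lor_trial - no$eps), log(2) - log(1.5) + 0.3)

  # the trial deviation carries variance tau2 into the contrast for any split
  eta_diff <- qlogis(arms$p[c(FALSE, TRUE)]) - qlogis(arms$p[c(TRUE, FALSE)])
  lor_true <- arms$lor_trial[c(TRUE, FALSE)] - arms$eps[c(TRUE, FALSE)]
  # 2000 trials: chi-square relative SE of a variance estimate ~ sqrt(2/n)
  expect_lt(abs(var(eta_diff - lor_true) - 0.04), 4 * sqrt(2 / 2000) * 0.04)

  # degenerate scenario: no heterogeneity, no inconsistency
  sc0 <- sim_scenario(if_fixed = 0, tau2 = 0)
  arms0 <- simulate_complete_network(sc0)$arms
  op <- arms0[arms0$comparison == "OP", ]
  expect_equal(unique(op$lor_trial), log(1.5))
})

test_that("log IMOR draws honour truncation directions and MAR moments", {
  set.seed(71)
  sc_inf <- sim_scenario(mechanism = "informative")
  ints <- rep(c("P", "N", "O"), length.out = 30000)
  phi <- draw_log_imors(sc_inf, ints)
  expect_true(all(phi[ints == "P"] <= 0))
  expect_true(all(phi[ints != "P"] >= 0))

  # closed-form truncated-normal mean oracle for the active arms
  alpha <- (0 - log(2)) / 1
  m_true <- log(2) + dnorm(alpha) / (1 - pnorm(alpha))
  expect_equal(mean(phi[ints != "P"]), m_true, tolerance = 0.02)
  # placebo is the mirror image
  expect_equal(mean(phi[ints == "P"]), -m_true, tolerance = 0.02)

  sc_mar <- sim_scenario(mechanism = "mar")
  phi_mar <- draw_log_imors(sc_mar, rep("N", 1e5))
  expect_equal(mean(phi_mar), 0, tolerance = 0.02)
  expect_equal(var(phi_mar), 1, tolerance = 0.03)
})

test_that("imposed missingness respects the extent/balance ranges and never
           touches the randomized counts", {
  set.seed(81)
  combos <- tidyr::expand_grid(extent = c("moderate", "large"),
                               balance = c("balanced", "unbalanced"))
  for (i in seq_len(nrow(combos))) {
    sc <- sim_scenario(mod_extent = combos$extent[i],
                       mod_balance = combos$balance[i],
                       mechanism = "informative", tau2 = 0.02, if_fixed = 0)
    truth <- purrr::map_dfr(1:250, function(j) simulate_network(sc)$truth)
    rng_e <- switch(paste(combos$extent[i], combos$balance[i]),
                    "moderate balanced" = c(0.05, 0.20),
                    "large balanced" = c(0.21, 0.40),
                    "moderate unbalanced" = c(0.05, 0.10),
                    "large unbalanced" = c(0.21, 0.30))
    e <- truth$role == "experimental"
    expect_true(all(truth$q[e] >= rng_e[1] & truth$q[e] <= rng_e[2]))
    if (combos$balance[i] == "balanced") {
      expect_equal(truth$q[e], truth$q[!e])       # control copies experimental
    } else {
      rng_c <- if (combos$extent[i] == "moderate") c(0.11, 0.20) else c(0.31, 0.40)
      expect_true(all(truth$q[!e] >= rng_c[1] & truth$q[!e] <= rng_c[2]))
      expect_true(all(truth$q[e] < truth$q[!e]))  # control arms lose more
    }
    expect_true(all(truth$r_obs <= truth$n - truth$m))
    expect_true(all(truth$m >= 0 & truth$m <= truth$n))
  }
})

test_that("forcing q = 0 reproduces the complete data bit-exactly", {
  set.seed(91)
  sc <- sim_scenario(mechanism = "informative")
  cm <- simulate_complete_network(sc)
  sim <- impose_missingness(cm, q_override = 0)
  tb <- as_tibble(sim$network)
  expect_equal(tb$m, rep(0L, nrow(tb)))
  expect_equal(tb$r_obs, cm$arms$r_complete)
  expect_equal(tb$n, cm$arms$n)
})

test_that("MAR leaves the completer event proportion unbiased", {
  set.seed(92)
  sc <- sim_scenario(mechanism = "mar", imor_sd2 = 0, tau2 = 0.02,
                     if_fixed = 0)
  truth <- purrr::map_dfr(1:400, function(j) simulate_network(sc)$truth)
  # pooled completer proportion vs pooled underlying risk
  n_obs <- truth$n - truth$m
  obs_rate <- sum(truth$r_obs) / sum(n_obs)
  true_rate <- sum(truth$p * n_obs) / sum(n_obs)
  se <- sqrt(sum(truth$p * (1 - truth$p) * n_obs)) / sum(n_obs)
  expect_lt(abs(obs_rate - true_rate), 4 * se)
})

test_that("true probability of being best behaves at the degenerate limit", {
  set.seed(93)
  pb0 <- true_prob_best(sim_scenario(tau2 = 0), reps = 1e4)
  expect_equal(pb0$p_best, c(1, 0, 0))   # log2 > log1.5 > 0 with no noise
  expect_error(true_prob_best(reps = 100), class = "misnma_config_error")
})
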