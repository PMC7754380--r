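# A minimal hand-built fit object: rank/summary machinery only needs the
# draw matrices and the treatment ordering.
fake_fit <- function(draws_matrix, treats) {
  structure(list(draws = list(draws_matrix),
                 model = list(treats = treats, random = TRUE)),
            class = "nma_fit")
}

test_that("gelman_rubin matches the closed-form PSRF", {
  set.seed(31)
  x <- rnorm(500)
  expect_lte(gelman_rubin(list(x, x)), 1)           # B = 0

  ch <- replicate(4, rnorm(10000), simplify = FALSE)
  expect_lt(gelman_rubin(ch), 1.01)

  far <- list(rnorm(2000, 0, 1), rnorm(2000, 10, 1))
  r <- gelman_rubin(far)
  n <- 2000
  W <- mean(c(var(far[[1]]), var(far[[2]])))
  B <- n * var(c(mean(far[[1]]), mean(far[[2]])))
  expect_equal(r, sqrt((n - 1) / n + B / (n * W)))
  expect_gt(r, 1.5)

  expect_warning(r0 <- gelman_rubin(list(rep(1, 100), rep(1, 100))),
                 "Zero within-chain variance")
  expect_equal(r0, 1)
  expect_error(gelman_rubin(list(rnorm(100))), class = "misnma_contract_error")
})

test_that("posterior summaries follow the percentile convention", {
  s <- posterior_summary(rep(3.2, 10))
  expect_equal(unlist(s), c(mean = 3.2, median = 3.2, sd = 0,
                            conf.low = 3.2, conf.high = 3.2))

  s100 <- posterior_summary(1:100)
  expect_equal(s100$conf.low, 3.475)      # linear-interpolation percentile
  expect_equal(s100$conf.high, 97.525)

  set.seed(41)
  sn <- posterior_summary(rnorm(1e5))
  expect_equal(sn$conf.low, -1.96, tolerance = 0.03)
  expect_equal(sn$conf.high, 1.96, tolerance = 0.03)
})

test_that("rank probabilities match a hand count and are doubly stochastic", {
  # three hand-written draws for T = 3 (reference A fixed at 0)
  m <- cbind("mu[B]" = c(1, -1, 2), "mu[C]" = c(0.5, 1, -2))
  f <- fake_fit(m, c("A", "B", "C"))
  rp <- rank_probabilities(f, "higher-better")
  probs <- attr(rp, "matrix")
  # draw 1: B > C > A; draw 2: C > A > B; draw 3: B > A > C
  expect_equal(probs["B", ], c("1" = 2 / 3, "2" = 0, "3" = 1 / 3))
  expect_equal(probs["C", ], c("1" = 1 / 3, "2" = 1 / 3, "3" = 1 / 3))
  expect_equal(probs["A", ], c("1" = 0, "2" = 2 / 3, "3" = 1 / 3))
  expect_equal(rowSums(probs), c(A = 1, B = 1, C = 1))
  expect_equal(unname(colSums(probs)), c(1, 1, 1))

  # certain ordering: P(best) = 1 for B
  m2 <- cbind("mu[B]" = rep(1, 10), "mu[C]" = rep(-1, 10))
  pb <- prob_best(fake_fit(m2, c("A", "B", "C")))
  expect_equal(unname(pb["B"]), 1)

  # lower-better flips the ranking
  pb_low <- prob_best(fake_fit(m2, c("A", "B", "C")), "lower-better")
  expect_equal(unname(pb_low["C"]), 1)
})

test_that("fit honours draw-count contracts, seeds, and derives contrasts
           rather than sampling them", {
  net <- triangle_net()
  spec <- model_spec("pattern_mixture", imor_prior("identical", "network"))
  mc <- mcmc_options(chains = 2, iterations = 900, burn_in = 300, thin = 3,
                     seed = 5)
  f1 <- suppressWarnings(fit(net, spec, mc))
  expect_length(f1$draws, 2)
  expect_equal(nrow(f1$draws[[1]]), (900 - 300) / 3)

  f2 <- suppressWarnings(fit(net, spec, mc))
  expect_identical(f1$draws, f2$draws)   # same seed, same draws

  # consistency identity: the N vs O contrast is exactly mu_N - mu_O
  b <- basic_draws(f1)
  expect_identical(contrast_draws(f1, "N", "O"), b[, "N"] - b[, "O"])

  # diagnostics cover every sampled column
  expect_setequal(f1$diagnostics$term, colnames(f1$draws[[1]]))

  expect_error(mcmc_options(chains = 1), class = "misnma_config_error")
  expect_error(mcmc_options(iterations = 100, burn_in = 100),
               class = "misnma_config_error")
})

test_that("models with no missing counts agree with the completer-only model", {
  net <- triangle_net(m = 0)
  mc <- tiny_mcmc(seed = 8, iterations = 1600, burn_in = 400)
  f_none <- suppressWarnings(fit(net, model_spec("none"), mc))
  f_pm <- suppressWarnings(
    fit(net, model_spec("pattern_mixture", imor_prior("identical", "network")),
        mc))
  t_none <- tidy(f_none)
  t_pm <- tidy(f_pm)
  # missingness terms are inert: basic parameters agree up to MC error
  expect_equal(t_pm$estimate[1:2], t_none$estimate[1:2], tolerance = 0.1)
})
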