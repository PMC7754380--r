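two_trial_net <- function() {
  nma_network(tibble::tibble(
    trial_id = rep(c("t1", "t2"), each = 2),
    intervention = c("A", "B", "A", "B"),
    n = c(100L, 100L, 80L, 80L),
    r_obs = c(30L, 40L, 25L, 35L),
    m = c(10L, 8L, 5L, 12L)), reference = "A")
}

base_state <- function(net, n_phi = 1) {
  n_arms <- nrow(as_tibble(net))
  list(u = c(-0.8, -0.7), theta = c(0.4, 0.5), mu = 0.45, tau2 = 0.04,
       q = rep(0.1, n_arms), phi = rep(0, n_phi))
}

test_that("with phi = 0 the pattern-mixture joint splits into completer and
           missingness binomials", {
  net <- two_trial_net()
  spec_pm <- model_spec("pattern_mixture", imor_prior("identical", "network"))
  spec_none <- model_spec("none")
  st <- base_state(net)
  lp_pm <- log_joint(st, net, spec_pm)
  st_none <- st[c("u", "theta", "mu", "tau2")]
  lp_none <- log_joint(st_none, net, spec_none)
  tb <- as_tibble(net)
  miss_ll <- sum(dbinom(tb$m, tb$n, st$q, log = TRUE))
  phi_prior <- dnorm(0, 0, 1, log = TRUE)
  expect_equal(lp_pm, lp_none + miss_ll + phi_prior, tolerance = 1e-12)
})

test_that("pattern-mixture and selection joints are equal state for state", {
  net <- two_trial_net()
  spec_pm <- model_spec("pattern_mixture", imor_prior("identical", "trial"))
  spec_sel <- model_spec("selection", imor_prior("identical", "trial"))
  set.seed(11)
  diffs <- purrr::map_dbl(1:25, function(i) {
    st <- list(u = rnorm(2, -0.5, 0.5), theta = rnorm(2, 0.3, 0.3),
               mu = rnorm(1, 0.4, 0.3), tau2 = runif(1, 0.005, 0.2),
               q = runif(4, 0.02, 0.4), phi = rnorm(2, 0, 0.8))
    log_joint(st, net, spec_pm) - log_joint(st, net, spec_sel)
  })
  # same factorization of the same joint law: the difference is a data-only
  # constant, and the combinatorial constants coincide exactly
  expect_lt(max(abs(diffs - diffs[1])), 1e-9)
  expect_lt(abs(diffs[1]), 1e-9)
})

test_that("log_joint guards its support and contracts", {
  net <- two_trial_net()
  spec <- model_spec("pattern_mixture", imor_prior("identical", "network"))
  st <- base_state(net)
  expect_true(is.finite(log_joint(st, net, spec)))
  bad <- st; bad$tau2 <- -0.1
  expect_equal(log_joint(bad, net, spec), -Inf)
  bad <- st; bad$q[1] <- 1
  expect_equal(log_joint(bad, net, spec), -Inf)
  short <- st; short$u <- st$u[1]
  expect_error(log_joint(short, net, spec), class = "misnma_contract_error")
  wrongphi <- st; wrongphi$phi <- rep(0, 4)
  expect_error(log_joint(wrongphi, net, spec), class = "misnma_contract_error")
})

test_that("conditional contrast moments reproduce the multivariate normal", {
  basic <- c(B = 0.3, C = 0.7)
  # two-arm trial: plain N(d, tau2)
  m2 <- conditional_theta_moments(c("A", "B"), k = 2, basic = basic, tau2 = 0.09)
  expect_equal(m2$mean, 0.3)
  expect_equal(m2$variance, 0.09)

  # three-arm trial, third contrast: variance (3/4) tau2
  m3 <- conditional_theta_moments(c("A", "B", "C"), k = 3, theta = 0.5,
                                  basic = basic, tau2 = 0.09)
  expect_equal(m3$variance, 3 / 4 * 0.09)
  expect_equal(m3$mean, 0.7 + (0.5 - 0.3) / 2)

  # non-reference baseline: differences are taken against the baseline arm
  mb <- conditional_theta_moments(c("B", "C"), k = 2, basic = basic, tau2 = 0.04)
  expect_equal(mb$mean, 0.7 - 0.3)

  expect_error(conditional_theta_moments(c("A", "B"), k = 1, basic = basic,
                                         tau2 = 0.1),
               class = "misnma_contract_error")

  # compounding the sequential conditionals over a 3-arm trial reproduces the
  # joint MVN with variance tau2 and covariance tau2/2
  set.seed(21)
  tau2 <- 0.36
  n <- 2e5
  th2 <- rnorm(n, 0.3, sqrt(tau2))
  mom3 <- conditional_theta_moments(c("A", "B", "C"), k = 3, basic = basic,
                                    tau2 = tau2)
  # mean of theta3 given theta2 is d3 + (theta2 - d2)/2, variance (3/4) tau2
  th3 <- rnorm(n, 0.7 + (th2 - 0.3) / 2, sqrt(mom3$variance))
  S <- stats::cov(cbind(th2, th3))
  expect_equal(S[1, 1], tau2, tolerance = 0.02)
  expect_equal(S[2, 2], tau2, tolerance = 0.02)
  expect_equal(S[1, 2], tau2 / 2, tolerance = 0.02)
})
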