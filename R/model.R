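# Internal "compiled" representation of a model: arm-level index vectors and
# everything the sampler needs to evaluate the joint density quickly.
compile_model <- function(net, spec, split = NULL) {
  stopifnot(inherits(net, "nma_network"), inherits(spec, "nma_model_spec"))
  d <- net$data
  trials <- net$trials
  treats <- c(net$reference, setdiff(net$interventions, net$reference))

  tr <- match(d$trial_id, trials)
  treat <- match(d$intervention, treats)
  a_i <- as.integer(table(factor(d$trial_id, levels = trials)))
  base_treat <- treat[d$k == 1][order(tr[d$k == 1])]

  split_info <- NULL
  if (!is.null(split)) {
    split <- as.character(split)
    assert_that(length(split) == 2 && all(split %in% net$interventions),
                "`comparison` must name two interventions in the network.")
    ok <- splittable_comparisons(net)
    hit <- (ok$from == split[1] & ok$to == split[2]) |
      (ok$from == split[2] & ok$to == split[1])
    if (!any(hit)) {
      abort_misnma(sprintf(
        "Comparison %s vs %s is not splittable in this network.",
        split[1], split[2]), "misnma_contract_error")
    }
    direct <- vapply(trials, function(id) {
      all(split %in% d$intervention[d$trial_id == id])
    }, logical(1))
    split_info <- list(pair = split, direct_trial = direct,
                       pair_idx = match(split, treats))
  }

  # multi-arm trials assigned to the direct component keep only the split arms
  if (!is.null(split_info)) {
    keep <- rep(TRUE, nrow(d))
    for (i in which(split_info$direct_trial & a_i > 2)) {
      rows <- which(tr == i)
      keep[rows] <- d$intervention[rows] %in% split_info$pair
    }
    if (!all(keep)) {
      d <- d[keep, ]
      d <- d |>
        dplyr::group_by(.data$trial_id) |>
        dplyr::mutate(k = dplyr::row_number()) |>
        dplyr::ungroup()
      tr <- match(d$trial_id, trials)
      treat <- match(d$intervention, treats)
      a_i <- as.integer(table(factor(d$trial_id, levels = trials)))
      base_treat <- treat[d$k == 1][order(tr[d$k == 1])]
    }
  }

  nb <- which(d$k > 1)                       # non-baseline arms
  miss <- switch(spec$missingness,
                 none = "none", pattern_mixture = "pm", selection = "sel")

  phi_map <- NULL
  if (miss != "none") {
    subnet <- net
    subnet$data <- d
    phi_map <- phi_index_map(subnet, spec$imor_prior)
  }

  list(
    net = net, spec = spec, d = d,
    trials = trials, treats = treats,
    n_trials = length(trials), n_treats = length(treats),
    tr = tr, treat = treat, a_i = a_i, base_treat = base_treat,
    n = d$n, r = d$r_obs, m = d$m, nobs = d$n_obs, k = d$k,
    nb = nb, n_arms = nrow(d),
    miss = miss,
    phi_map = phi_map,
    n_phi = if (is.null(phi_map)) 0L else attr(phi_map, "n_phi"),
    n_hyper = if (is.null(phi_map)) 0L else attr(phi_map, "n_hyper"),
    split = split_info,
    random = spec$effects == "random"
  )
}

# Per-arm log-likelihood. eta = logit of the underlying risk p; q and phi are
# per-arm vectors (ignored when the model has no missingness component).
# Degenerate p is eps-clamped here (likelihood only, never in the transforms).
arm_loglik <- function(mod, eta, q = NULL, phi = NULL) {
  p <- clamp01(stats::plogis(eta))
  if (mod$miss == "none") {
    return(stats::dbinom(mod$r, mod$nobs, p, log = TRUE))
  }
  q <- clamp01(q)
  if (mod$miss == "pm") {
    po <- pm_observed_risk(p, q, phi)
    po <- clamp01(po)
    stats::dbinom(mod$r, mod$nobs, po, log = TRUE) +
      stats::dbinom(mod$m, mod$n, q, log = TRUE)
  } else {
    cells <- selection_cells_(p, q, phi)
    lgamma(mod$n + 1) - lgamma(mod$r + 1) - lgamma(mod$nobs - mod$r + 1) -
      lgamma(mod$m + 1) +
      xlogy(mod$r, cells$p1) + xlogy(mod$nobs - mod$r, cells$p2) +
      xlogy(mod$m, cells$p3)
  }
}

# Expand parameter-level phi to per-arm phi.
phi_by_arm <- function(mod, phi) {
  if (mod$miss == "none") return(NULL)
  phi[mod$phi_map$phi_id]
}

# Random-effects prior mean for each non-baseline arm: the consistency
# difference of basic parameters, or the isolated direct-effect parameter
# for trials assigned to the direct component of a node-split.
re_means <- function(mod, mu, dsplit = NULL) {
  dmean <- mu[mod$treat[mod$nb]] - mu[mod$base_treat[mod$tr[mod$nb]]]
  if (!is.null(mod$split)) {
    dir_arm <- mod$split$direct_trial[mod$tr[mod$nb]]
    # orientation: + dsplit when the non-baseline arm is pair[1]
    sgn <- ifelse(mod$treat[mod$nb] == mod$split$pair_idx[1], 1, -1)
    dmean[dir_arm] <- sgn[dir_arm] * dsplit
  }
  dmean
}

# Per-non-baseline-arm log density of the random-effects model, using the
# sequential conditional-normal representation for multi-arm trials.
re_logprior <- function(mod, th_nb, mu, tau, dsplit = NULL) {
  dmean <- re_means(mod, mu, dsplit)
  out <- numeric(length(mod$nb))
  two <- mod$a_i[mod$tr[mod$nb]] == 2
  out[two] <- stats::dnorm(th_nb[two], dmean[two], tau, log = TRUE)
  if (any(!two)) {
    karm <- mod$k[mod$nb]
    for (i in which(mod$a_i > 2)) {
      rows <- which(mod$tr[mod$nb] == i)
      ks <- karm[rows]
      ord <- order(ks)
      rows <- rows[ord]; ks <- ks[ord]
      run <- 0
      for (j in seq_along(rows)) {
        kk <- ks[j]
        mean_j <- dmean[rows[j]] + if (kk > 2) run / (kk - 1) else 0
        var_j <- kk / (2 * (kk - 1)) * tau^2
        out[rows[j]] <- stats::dnorm(th_nb[rows[j]], mean_j, sqrt(var_j),
                                     log = TRUE)
        run <- run + (th_nb[rows[j]] - dmean[rows[j]])
      }
    }
  }
  out
}

#' Conditional moments of a multi-arm trial contrast
#'
#' In a trial with `a >= 2` arms the vector of log odds ratios against the
#' baseline arm is multivariate normal with common variance `tau2` and
#' covariance `tau2 / 2`. Sampling it sequentially, the contrast of arm `k`
#' given the earlier contrasts is normal with mean
#' `d_k + (1/(k-1)) * sum_{j<k} (theta_j - d_j)` and variance
#' `(k / (2 (k-1))) * tau2`, where `d_j` is the consistency difference of
#' basic parameters. Two-arm trials reduce to `N(d_2, tau2)`.
#'
#' @param treatments Character vector of the trial's interventions in arm
#'   order (position 1 = baseline arm).
#' @param k Arm position (2-based contrasts; `k >= 2`).
#' @param theta Numeric vector of contrasts for arms `2 .. a` (entries
#'   beyond position `k - 1` are ignored); may be `NULL` for `k = 2`.
#' @param basic Named numeric vector of basic parameters (log OR of each
#'   intervention versus the reference); the reference itself is 0 and may
#'   be omitted.
#' @param tau2 Between-trial variance.
#' @return A list with elements `mean` and `variance`.
#' @export
conditional_theta_moments <- function(treatments, k, theta = NULL, basic,
                                      tau2) {
  a <- length(treatments)
  assert_that(a >= 2, "A trial needs at least two arms.")
  assert_that(k >= 2 && k <= a,
              "`k` must index a non-baseline arm (2 <= k <= number of arms).")
  bval <- function(t) if (t %in% names(basic)) unname(basic[[t]]) else 0
  d <- unname(vapply(treatments, bval, numeric(1))) - bval(treatments[1])
  mean_k <- d[k]
  if (k > 2) {
    js <- 2:(k - 1)
    mean_k <- mean_k + sum(theta[js - 1] - d[js]) / (k - 1)
  }
  list(mean = mean_k, variance = k / (2 * (k - 1)) * tau2)
}

# ---- joint density ---------------------------------------------------------

#' Log joint density of the NMA model
#'
#' Assembles the full log posterior kernel: the observed-data likelihood of
#' the chosen missingness model, the random-effects density of the
#' trial-specific contrasts, and the priors on baselines, basic parameters,
#' tau, the log-IMOR parameters and (for hierarchical structures) their
#' hyper-parameters. Returns `-Inf` outside the support.
#'
#' @param state Named list with elements `u` (per-trial baseline log odds),
#'   `theta` (per-non-baseline-arm contrasts, trial order then arm order;
#'   omitted for fixed-effects models), `mu` (basic parameters for the
#'   non-reference interventions, in the order
#'   `setdiff(interventions, reference)` after the reference), `tau2`
#'   (between-trial variance; random effects only), `q` (per-arm missingness
#'   probabilities; models with missingness only), `phi` (log-IMOR
#'   parameters per [phi_index_map()]), `phi_mu`/`phi_sd` (hierarchical
#'   hyper-parameters), `d_split` (direct-effect parameter; node-split
#'   models only).
#' @param net An `nma_network`.
#' @param spec An `nma_model_spec`.
#' @param split Optional comparison (length-2 character) for node-split
#'   models.
#' @return A single finite number, or `-Inf` outside the support.
#' @export
log_joint <- function(state, net, spec, split = NULL) {
  mod <- compile_model(net, spec, split = split)
  log_joint_compiled(mod, state)
}

log_joint_compiled <- function(mod, state) {
  spec <- mod$spec
  u <- state$u
  assert_that(length(u) == mod$n_trials, "`u` must have one entry per trial.")
  mu_free <- state$mu
  assert_that(length(mu_free) == mod$n_treats - 1,
              "`mu` must have one entry per non-reference intervention.")
  mu <- c(0, mu_free)

  if (mod$random) {
    th_nb <- state$theta
    assert_that(length(th_nb) == length(mod$nb),
                "`theta` must have one entry per non-baseline arm.")
    tau2 <- state$tau2
    if (is.null(tau2) || tau2 < 0) return(-Inf)
    tau <- sqrt(tau2)
  } else {
    th_nb <- re_means(mod, mu, state$d_split)
    tau <- NA_real_
  }
  th_arm <- numeric(mod$n_arms)
  th_arm[mod$nb] <- th_nb
  eta <- u[mod$tr] + th_arm

  q <- phi_arm <- NULL
  if (mod$miss != "none") {
    q <- state$q
    assert_that(length(q) == mod$n_arms, "`q` must have one entry per arm.")
    if (any(q < 0 | q >= 1)) return(-Inf)
    phi <- state$phi
    assert_that(length(phi) == mod$n_phi,
                "`phi` has the wrong length for this prior structure.")
    phi_arm <- phi_by_arm(mod, phi)
  }

  ll <- sum(arm_loglik(mod, eta, q, phi_arm))

  lp <- sum(stats::dnorm(u, 0, sqrt(spec$effect_prior_sd2), log = TRUE)) +
    sum(stats::dnorm(mu_free, 0, sqrt(spec$effect_prior_sd2), log = TRUE))
  if (!is.null(mod$split)) {
    lp <- lp + stats::dnorm(state$d_split, 0, sqrt(spec$effect_prior_sd2),
                            log = TRUE)
  }
  if (mod$random) {
    if (tau2 == 0) return(-Inf)
    lp <- lp + sum(re_logprior(mod, th_nb, mu, tau, state$d_split))
    # half-normal prior density on tau (no sampling-scale Jacobian here:
    # log_joint is parameterised in tau2 directly through its density in tau)
    lp <- lp + log(2) + stats::dnorm(tau, 0, spec$tau_prior_scale, log = TRUE)
  }

  if (mod$miss != "none") {
    pr <- spec$imor_prior
    if (pr$structure == "identical") {
      lp <- lp + sum(stats::dnorm(state$phi, pr$mean, sqrt(pr$sd2), log = TRUE))
    } else {
      phi_mu <- state$phi_mu
      phi_sd <- state$phi_sd
      assert_that(length(phi_mu) == mod$n_hyper && length(phi_sd) == mod$n_hyper,
                  "Hierarchical hyper-parameters have the wrong length.")
      if (any(phi_sd <= 0 | phi_sd >= pr$hyper_sd_upper)) return(-Inf)
      g <- mod$phi_map$hyper_id
      lp <- lp + sum(stats::dnorm(state$phi, phi_mu[g], phi_sd[g], log = TRUE)) +
        sum(stats::dnorm(phi_mu, pr$mean, sqrt(pr$hyper_mean_sd2), log = TRUE)) +
        sum(-log(pr$hyper_sd_upper))
    }
    # flat Beta(1,1) prior on each q: contributes 0
  }

  ll + lp
}
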