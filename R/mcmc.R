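#' MCMC options
#'
#' @param chains Number of parallel chains (>= 2 so that convergence can be
#'   assessed).
#' @param iterations Total updates per chain, burn-in included.
#' @param burn_in Discarded updates per chain; proposal scales adapt during
#'   burn-in and are frozen afterwards.
#' @param thin Thinning interval applied after burn-in.
#' @param seed Master seed; chain `c` runs from seed `seed + c - 1`.
#' @param rhat_threshold Gelman-Rubin threshold above which [fit()] warns
#'   (never errors).
#' @return An object of class `mcmc_options`.
#' @export
mcmc_options <- function(chains = 2, iterations = 20000, burn_in = 2000,
                         thin = 3, seed = 1, rhat_threshold = 1.05) {
  assert_that(chains >= 2, "`chains` must be at least 2.", "misnma_config_error")
  assert_that(burn_in < iterations, "`burn_in` must be smaller than `iterations`.",
              "misnma_config_error")
  assert_that(thin >= 1, "`thin` must be at least 1.", "misnma_config_error")
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed), rhat_threshold = rhat_threshold),
            class = "mcmc_options")
}

# Per-arm likelihood on a subset of arms (idx NULL = all).
arm_loglik_idx <- function(mod, eta, q, phi, idx = NULL) {
  if (is.null(idx)) return(arm_loglik(mod, eta, q, phi))
  sub <- mod
  sub$r <- mod$r[idx]; sub$nobs <- mod$nobs[idx]
  sub$m <- mod$m[idx]; sub$n <- mod$n[idx]
  arm_loglik(sub, eta[idx], q[idx], if (is.null(phi)) NULL else phi[idx])
}

ltau_logprior <- function(ltau, scale) {
  # half-normal on tau = exp(ltau) plus log-scale Jacobian
  tau <- exp(ltau)
  log(2) + stats::dnorm(tau, 0, scale, log = TRUE) + ltau
}

hz_to_sd <- function(hz, upper) upper * stats::plogis(hz)

hz_logprior <- function(hz, upper) {
  # flat prior on sd in (0, upper), logit-bounded sampling scale Jacobian
  s <- hz_to_sd(hz, upper)
  log(s) + log(upper - s) - 2 * log(upper)
}

# One full adaptive Metropolis-within-Gibbs chain.
run_chain <- function(mod, mcmc, chain_id) {
  set.seed(mcmc$seed + chain_id - 1L)
  spec <- mod$spec
  pr <- spec$imor_prior
  N <- mod$n_trials
  Tn <- mod$n_treats
  n_nb <- length(mod$nb)
  n_arms <- mod$n_arms
  eff_sd <- sqrt(spec$effect_prior_sd2)
  has_miss <- mod$miss != "none"
  hier <- has_miss && pr$structure == "hierarchical"
  has_split <- !is.null(mod$split)

  # ---- initial state (jittered restarts on non-finite joint) ----
  base_r <- mod$r[mod$k == 1][order(mod$tr[mod$k == 1])]
  base_no <- mod$nobs[mod$k == 1][order(mod$tr[mod$k == 1])]
  init_u <- stats::qlogis((base_r + 0.5) / (base_no + 1))
  for (attempt in 0:100) {
    jit <- if (attempt == 0) 0 else 0.5
    u <- init_u + stats::rnorm(N, 0, jit)
    muf <- stats::rnorm(Tn - 1, 0, jit)
    th <- if (mod$random) stats::rnorm(n_nb, 0, jit) else NULL
    ltau <- log(spec$tau_prior_scale * stats::qnorm(0.75)) +
      stats::rnorm(1, 0, jit)
    lq <- if (has_miss) {
      stats::qlogis((mod$m + 0.5) / (mod$n + 1)) + stats::rnorm(n_arms, 0, jit)
    } else NULL
    phi <- if (has_miss) rep(pr$mean, mod$n_phi) + stats::rnorm(mod$n_phi, 0, jit) else NULL
    hmu <- if (hier) rep(pr$mean, mod$n_hyper) else NULL
    hz <- if (hier) rep(0, mod$n_hyper) else NULL
    dsp <- if (has_split) stats::rnorm(1, 0, jit) else NULL

    mu <- c(0, muf)
    tau <- exp(ltau)
    q <- if (has_miss) stats::plogis(lq) else NULL
    phi_arm <- if (has_miss) phi[mod$phi_map$phi_id] else NULL
    th_nb <- if (mod$random) th else re_means(mod, mu, dsp)
    th_arm <- numeric(n_arms); th_arm[mod$nb] <- th_nb
    eta <- u[mod$tr] + th_arm
    ll_arm <- arm_loglik(mod, eta, q, phi_arm)
    re_nb <- if (mod$random) re_logprior(mod, th, mu, tau, dsp) else NULL
    if (all(is.finite(ll_arm)) && (!mod$random || all(is.finite(re_nb)))) break
    if (attempt == 100) {
      abort_misnma("Could not find a finite starting point after 100 jittered restarts.",
                   "misnma_init_error")
    }
  }

  # ---- proposal scales and acceptance bookkeeping ----
  sc <- list(u = rep(0.25, N), th = rep(0.3, max(n_nb, 1)),
             mu = rep(0.3, Tn - 1), mushift = rep(0.3, Tn - 1),
             dspshift = 0.3, ltau = 0.6,
             lq = rep(0.5, max(n_arms, 1)), phi = rep(0.5, max(mod$n_phi, 1)),
             hz = rep(0.6, max(mod$n_hyper, 1)), dsp = 0.3)
  acc <- lapply(sc, function(x) x * 0)
  batch <- 0L
  adapt_every <- 50L

  n_keep <- (mcmc$iterations - mcmc$burn_in) %/% mcmc$thin
  cols <- chain_col_names(mod)
  draws <- matrix(NA_real_, n_keep, length(cols),
                  dimnames = list(NULL, cols))
  keep_row <- 0L

  tr_nb <- mod$tr[mod$nb]
  phi_id <- if (has_miss) mod$phi_map$phi_id else NULL
  g_arm <- if (hier) mod$phi_map$hyper_id else NULL

  for (it in seq_len(mcmc$iterations)) {
    adapting <- it <= mcmc$burn_in

    # -- trial baselines u (parallel per-trial MH) --
    u2 <- u + sc$u * stats::rnorm(N)
    eta2 <- u2[mod$tr] + th_arm
    ll2 <- arm_loglik(mod, eta2, q, phi_arm)
    dll <- rowsum(ll2 - ll_arm, mod$tr)[, 1]
    dlp <- stats::dnorm(u2, 0, eff_sd, log = TRUE) -
      stats::dnorm(u, 0, eff_sd, log = TRUE)
    ok <- log(stats::runif(N)) < dll + dlp
    ok[!is.finite(dll + dlp)] <- FALSE
    if (any(ok)) {
      u[ok] <- u2[ok]
      sel <- ok[mod$tr]
      ll_arm[sel] <- ll2[sel]
      eta[sel] <- eta2[sel]
    }
    acc$u <- acc$u + ok

    # -- contrasts theta (parallel per-trial block MH; random effects only) --
    if (mod$random && n_nb > 0) {
      th2 <- th + sc$th * stats::rnorm(n_nb)
      th_arm2 <- th_arm; th_arm2[mod$nb] <- th2
      eta2 <- u[mod$tr] + th_arm2
      ll2 <- arm_loglik_idx(mod, eta2, q, phi_arm, mod$nb)
      re2 <- re_logprior(mod, th2, mu, tau, dsp)
      dd <- rowsum((ll2 - ll_arm[mod$nb]) + (re2 - re_nb), tr_nb)
      dtr <- sort(unique(tr_nb))
      okt <- rep(FALSE, N)
      dv <- dd[, 1]
      dv[!is.finite(dv)] <- -Inf
      okt[dtr] <- log(stats::runif(length(dtr))) < dv
      sel_nb <- okt[tr_nb]
      if (any(sel_nb)) {
        th[sel_nb] <- th2[sel_nb]
        re_nb[sel_nb] <- re2[sel_nb]
        ll_arm[mod$nb][sel_nb] <- ll2[sel_nb]
        th_arm[mod$nb] <- th
        eta <- u[mod$tr] + th_arm
      }
      acc$th <- acc$th + okt[tr_nb]
    }

    # -- basic parameters mu (scalar MH each) --
    for (j in seq_len(Tn - 1)) {
      mu2f <- muf; mu2f[j] <- muf[j] + sc$mu[j] * stats::rnorm(1)
      mu2 <- c(0, mu2f)
      dlp <- stats::dnorm(mu2f[j], 0, eff_sd, log = TRUE) -
        stats::dnorm(muf[j], 0, eff_sd, log = TRUE)
      if (mod$random) {
        re2 <- re_logprior(mod, th, mu2, tau, dsp)
        dtot <- sum(re2 - re_nb) + dlp
        if (is.finite(dtot) && log(stats::runif(1)) < dtot) {
          muf <- mu2f; mu <- mu2; re_nb <- re2
          acc$mu[j] <- acc$mu[j] + 1
        }
      } else {
        th_nb2 <- re_means(mod, mu2, dsp)
        th_arm2 <- numeric(n_arms); th_arm2[mod$nb] <- th_nb2
        eta2 <- u[mod$tr] + th_arm2
        ll2 <- arm_loglik(mod, eta2, q, phi_arm)
        dtot <- sum(ll2 - ll_arm) + dlp
        if (is.finite(dtot) && log(stats::runif(1)) < dtot) {
          muf <- mu2f; mu <- mu2; th_arm <- th_arm2; eta <- eta2; ll_arm <- ll2
          acc$mu[j] <- acc$mu[j] + 1
        }
      }
    }

    # -- joint shift of a basic parameter and its contrasts --
    # Shifting mu_t and every contrast whose random-effects mean involves
    # mu_t by the same amount leaves the RE density invariant, so the
    # proposal is informed by the likelihood directly; this decouples the
    # basic parameters from the centred contrast parameterisation.
    if (mod$random && n_nb > 0) {
      for (j in seq_len(Tn - 1)) {
        tj <- j + 1L
        dep <- if (is.null(mod$split)) rep(TRUE, n_nb) else !mod$split$direct_trial[tr_nb]
        up <- dep & (mod$treat[mod$nb] == tj)
        dn <- dep & (mod$base_treat[mod$tr[mod$nb]] == tj)
        delta <- sc$mushift[j] * stats::rnorm(1)
        th2 <- th + delta * up - delta * dn
        mu2f <- muf; mu2f[j] <- muf[j] + delta
        aff <- mod$nb[up | dn]
        if (length(aff) == 0) next
        th_arm2 <- th_arm; th_arm2[mod$nb] <- th2
        eta2 <- u[mod$tr] + th_arm2
        ll2 <- arm_loglik_idx(mod, eta2, q, phi_arm, aff)
        dtot <- sum(ll2 - ll_arm[aff]) +
          stats::dnorm(mu2f[j], 0, eff_sd, log = TRUE) -
          stats::dnorm(muf[j], 0, eff_sd, log = TRUE)
        if (is.finite(dtot) && log(stats::runif(1)) < dtot) {
          muf <- mu2f; mu <- c(0, muf); th <- th2
          th_arm[mod$nb] <- th
          eta <- u[mod$tr] + th_arm
          ll_arm[aff] <- ll2
          re_nb <- re_logprior(mod, th, mu, tau, dsp)
          acc$mushift[j] <- acc$mushift[j] + 1
        }
      }
    }

    # -- node-split direct effect --
    if (has_split) {
      dsp2 <- dsp + sc$dsp * stats::rnorm(1)
      dlp <- stats::dnorm(dsp2, 0, eff_sd, log = TRUE) -
        stats::dnorm(dsp, 0, eff_sd, log = TRUE)
      if (mod$random) {
        re2 <- re_logprior(mod, th, mu, tau, dsp2)
        dtot <- sum(re2 - re_nb) + dlp
        if (is.finite(dtot) && log(stats::runif(1)) < dtot) {
          dsp <- dsp2; re_nb <- re2
          acc$dsp <- acc$dsp + 1
        }
      } else {
        th_nb2 <- re_means(mod, mu, dsp2)
        th_arm2 <- numeric(n_arms); th_arm2[mod$nb] <- th_nb2
        eta2 <- u[mod$tr] + th_arm2
        ll2 <- arm_loglik(mod, eta2, q, phi_arm)
        dtot <- sum(ll2 - ll_arm) + dlp
        if (is.finite(dtot) && log(stats::runif(1)) < dtot) {
          dsp <- dsp2; th_arm <- th_arm2; eta <- eta2; ll_arm <- ll2
          acc$dsp <- acc$dsp + 1
        }
      }
    }

    # joint shift of the direct effect and its trials' contrasts
    if (has_split && mod$random && n_nb > 0) {
      dir_nb <- mod$split$direct_trial[tr_nb]
      if (any(dir_nb)) {
        sgn_nb <- ifelse(mod$treat[mod$nb] == mod$split$pair_idx[1], 1, -1)
        delta <- sc$dspshift * stats::rnorm(1)
        th2 <- th + delta * sgn_nb * dir_nb
        dsp2 <- dsp + delta
        aff <- mod$nb[dir_nb]
        th_arm2 <- th_arm; th_arm2[mod$nb] <- th2
        eta2 <- u[mod$tr] + th_arm2
        ll2 <- arm_loglik_idx(mod, eta2, q, phi_arm, aff)
        dtot <- sum(ll2 - ll_arm[aff]) +
          stats::dnorm(dsp2, 0, eff_sd, log = TRUE) -
          stats::dnorm(dsp, 0, eff_sd, log = TRUE)
        if (is.finite(dtot) && log(stats::runif(1)) < dtot) {
          dsp <- dsp2; th <- th2
          th_arm[mod$nb] <- th
          eta <- u[mod$tr] + th_arm
          ll_arm[aff] <- ll2
          re_nb <- re_logprior(mod, th, mu, tau, dsp)
          acc$dspshift <- acc$dspshift + 1
        }
      }
    }

    # -- between-trial variance (log-scale MH) --
    if (mod$random) {
      ltau2 <- ltau + sc$ltau * stats::rnorm(1)
      tau2v <- exp(ltau2)
      re2 <- re_logprior(mod, th, mu, tau2v, dsp)
      dtot <- sum(re2 - re_nb) +
        ltau_logprior(ltau2, spec$tau_prior_scale) -
        ltau_logprior(ltau, spec$tau_prior_scale)
      if (is.finite(dtot) && log(stats::runif(1)) < dtot) {
        ltau <- ltau2; tau <- tau2v; re_nb <- re2
        acc$ltau <- acc$ltau + 1
      }
    }

    if (has_miss) {
      # -- per-arm missingness probabilities q (parallel per-arm MH) --
      lq2 <- lq + sc$lq * stats::rnorm(n_arms)
      q2 <- stats::plogis(lq2)
      ll2 <- arm_loglik(mod, eta, q2, phi_arm)
      dq <- (ll2 - ll_arm) +
        (log(q2) + log1p(-q2)) - (log(q) + log1p(-q))
      dq[!is.finite(dq)] <- -Inf
      okq <- log(stats::runif(n_arms)) < dq
      if (any(okq)) {
        lq[okq] <- lq2[okq]; q[okq] <- q2[okq]; ll_arm[okq] <- ll2[okq]
      }
      acc$lq <- acc$lq + okq

      # -- log-IMOR parameters (parallel MH over disjoint groups) --
      phi2 <- phi + sc$phi * stats::rnorm(mod$n_phi)
      phi_arm2 <- phi2[phi_id]
      ll2 <- arm_loglik(mod, eta, q, phi_arm2)
      dgrp <- rowsum(ll2 - ll_arm, phi_id)[, 1]
      if (!hier) {
        dgrp <- dgrp + stats::dnorm(phi2, pr$mean, sqrt(pr$sd2), log = TRUE) -
          stats::dnorm(phi, pr$mean, sqrt(pr$sd2), log = TRUE)
      } else {
        hsd <- hz_to_sd(hz, pr$hyper_sd_upper)
        dgrp <- dgrp + stats::dnorm(phi2, hmu[g_arm], hsd[g_arm], log = TRUE) -
          stats::dnorm(phi, hmu[g_arm], hsd[g_arm], log = TRUE)
      }
      dgrp[!is.finite(dgrp)] <- -Inf
      okp <- log(stats::runif(mod$n_phi)) < dgrp
      if (any(okp)) {
        phi[okp] <- phi2[okp]
        sel <- okp[phi_id]
        phi_arm <- phi[phi_id]
        ll_arm[sel] <- ll2[sel]
      }
      acc$phi <- acc$phi + okp

      # -- hierarchical hyper-parameters --
      if (hier) {
        hsd <- hz_to_sd(hz, pr$hyper_sd_upper)
        # group means: exact normal-normal Gibbs draw
        for (g in seq_len(mod$n_hyper)) {
          idx <- which(g_arm == g)
          vpost <- 1 / (length(idx) / hsd[g]^2 + 1 / pr$hyper_mean_sd2)
          mpost <- vpost * (sum(phi[idx]) / hsd[g]^2 +
                              pr$mean / pr$hyper_mean_sd2)
          hmu[g] <- stats::rnorm(1, mpost, sqrt(vpost))
        }
        # group sds: MH on the logit-bounded scale
        hz2 <- hz + sc$hz * stats::rnorm(mod$n_hyper)
        hsd2 <- hz_to_sd(hz2, pr$hyper_sd_upper)
        dsum <- rowsum(
          stats::dnorm(phi, hmu[g_arm], hsd2[g_arm], log = TRUE) -
            stats::dnorm(phi, hmu[g_arm], hsd[g_arm], log = TRUE),
          g_arm)[, 1]
        dsum <- dsum + hz_logprior(hz2, pr$hyper_sd_upper) -
          hz_logprior(hz, pr$hyper_sd_upper)
        dsum[!is.finite(dsum)] <- -Inf
        okh <- log(stats::runif(mod$n_hyper)) < dsum
        hz[okh] <- hz2[okh]
        acc$hz <- acc$hz + okh
      }
    }

    # -- proposal-scale adaptation (burn-in only) --
    if (adapting && it %% adapt_every == 0) {
      batch <- batch + 1L
      step <- min(0.25, batch^-0.5)
      for (nm in names(sc)) {
        rate <- acc[[nm]] / adapt_every
        sc[[nm]] <- sc[[nm]] * exp(ifelse(rate > 0.3, step, -step))
        acc[[nm]] <- acc[[nm]] * 0
      }
    }
    if (!adapting) {
      off <- it - mcmc$burn_in
      if (off %% mcmc$thin == 0 && keep_row < n_keep) {
        keep_row <- keep_row + 1L
        draws[keep_row, ] <- chain_row(mod, u, th, muf, exp(2 * ltau), q, phi,
                                       hmu, if (hier) hz_to_sd(hz, pr$hyper_sd_upper) else NULL,
                                       dsp)
      }
    }
  }
  draws
}

chain_col_names <- function(mod) {
  pr <- mod$spec$imor_prior
  hier <- mod$miss != "none" && pr$structure == "hierarchical"
  cols <- c(
    paste0("u[", mod$trials, "]"),
    if (mod$random) paste0("theta[", mod$d$trial_id[mod$nb], ":",
                           mod$d$intervention[mod$nb], "]"),
    paste0("mu[", mod$treats[-1], "]"),
    if (mod$random) "tau2",
    if (mod$miss != "none") paste0("q[", mod$d$trial_id, ":",
                                   mod$d$intervention, "]"),
    if (mod$miss != "none") paste0("phi[", attr(mod$phi_map, "phi_labels"), "]"),
    if (hier) paste0("phi_mu[", attr(mod$phi_map, "hyper_labels"), "]"),
    if (hier) paste0("phi_sd[", attr(mod$phi_map, "hyper_labels"), "]"),
    if (!is.null(mod$split)) "d_split"
  )
  cols
}

chain_row <- function(mod, u, th, muf, tau2, q, phi, hmu, hsd, dsp) {
  c(u, if (mod$random) th, muf, if (mod$random) tau2,
    if (mod$miss != "none") q, if (mod$miss != "none") phi,
    hmu, hsd, if (!is.null(mod$split)) dsp)
}

#' Fit the Bayesian NMA model
#'
#' Samples the joint posterior of the network meta-analysis model defined by
#' `spec` using an adaptive random-walk Metropolis-within-Gibbs sampler:
#' trial baselines and contrasts update in parallel per trial, tau on the
#' log scale, per-arm missingness probabilities and log-IMOR parameters in
#' disjoint blocks, and hierarchical group means by exact conjugate Gibbs
#' draws. Proposal scales adapt towards roughly 20-40% acceptance during
#' burn-in and are then frozen.
#'
#' @param net An `nma_network`.
#' @param spec An `nma_model_spec`.
#' @param mcmc An [mcmc_options()].
#' @return An object of class `nma_fit` carrying the per-chain draws, the
#'   model metadata and a per-parameter convergence table (Gelman-Rubin
#'   R-hat and effective sample size). A warning (never an error) is raised
#'   when any R-hat exceeds the threshold.
#' @export
fit <- function(net, spec = model_spec(), mcmc = mcmc_options()) {
  fit_compiled(compile_model(net, spec), mcmc)
}

fit_compiled <- function(mod, mcmc) {
  stopifnot(inherits(mcmc, "mcmc_options"))
  draws <- lapply(seq_len(mcmc$chains), function(ch) run_chain(mod, mcmc, ch))
  diag <- convergence_table(draws)
  if (any(diag$rhat > mcmc$rhat_threshold, na.rm = TRUE)) {
    worst <- diag[which.max(diag$rhat), ]
    warning(sprintf(
      "Convergence warning: R-hat %.3f for %s exceeds %.2f; inspect the chains.",
      worst$rhat, worst$term, mcmc$rhat_threshold), call. = FALSE)
  }
  structure(
    list(draws = draws, model = mod, net = mod$net, spec = mod$spec,
         mcmc = mcmc, diagnostics = diag),
    class = "nma_fit"
  )
}

#' @export
print.nma_fit <- function(x, ...) {
  cat(sprintf("<nma_fit> %s model, %d chains x %d kept draws\n",
              x$spec$missingness, length(x$draws), nrow(x$draws[[1]])))
  print(tidy(x))
  invisible(x)
}

# ---- convergence diagnostics ----------------------------------------------

#' Gelman-Rubin potential scale reduction factor
#'
#' The classic split-free PSRF over parallel chains:
#' `sqrt((n - 1)/n + B/(n W))` with `W` the mean within-chain variance and
#' `B` the between-chain variance of the chain means (times `n`).
#'
#' @param chains A list of numeric vectors (one per chain, equal length) or
#'   a matrix with one column per chain.
#' @return R-hat as a single number; 1 (with a warning) when every chain has
#'   zero variance.
#' @export
gelman_rubin <- function(chains) {
  if (is.matrix(chains)) chains <- asplit(chains, 2)
  assert_that(length(chains) >= 2, "Need at least two chains.")
  n <- unique(lengths(chains))
  assert_that(length(n) == 1 && n >= 10,
              "Chains must have equal length of at least 10 draws.")
  means <- vapply(chains, mean, numeric(1))
  vars <- vapply(chains, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) {
    if (B == 0) {
      warning("Zero within-chain variance in all chains; returning R-hat = 1.",
              call. = FALSE)
      return(1)
    }
    return(Inf)
  }
  sqrt((n - 1) / n + B / (n * W))
}

# crude but serviceable ESS: pooled draws discounted by the mean per-chain
# autocorrelation (lags truncated at the first negative estimate)
ess_basic <- function(chains) {
  if (is.matrix(chains)) chains <- asplit(chains, 2)
  n <- length(chains[[1]])
  max_lag <- min(n - 1, 200)
  rho_sum <- 0
  for (ch in chains) {
    if (stats::var(ch) == 0) next
    ac <- stats::acf(ch, lag.max = max_lag, plot = FALSE,
                     demean = TRUE)$acf[-1]
    neg <- which(ac < 0)
    if (length(neg) > 0) ac <- ac[seq_len(neg[1] - 1)]
    rho_sum <- rho_sum + sum(ac)
  }
  rho <- rho_sum / length(chains)
  max(1, length(chains) * n / (1 + 2 * max(0, rho)))
}

convergence_table <- function(draws) {
  cols <- colnames(draws[[1]])
  purrr::map_dfr(cols, function(cn) {
    ch <- lapply(draws, function(m) m[, cn])
    const <- all(vapply(ch, function(x) stats::var(x) == 0, logical(1)))
    tibble::tibble(
      term = cn,
      rhat = if (const) NA_real_ else suppressWarnings(gelman_rubin(ch)),
      ess = ess_basic(ch)
    )
  })
}
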