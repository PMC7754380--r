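# Inverse-CDF draws from a one-sided truncated normal.
rtruncnorm1 <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

# Closed-form mean of a truncated normal (used as a test oracle too).
truncnorm_mean <- function(mean, sd, lower = -Inf, upper = Inf) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  num <- stats::dnorm(a) - stats::dnorm(b)
  den <- stats::pnorm(b) - stats::pnorm(a)
  mean + sd * num / den
}

#' Simulation scenario for a triangle network with missing outcome data
#'
#' Encodes the design of the simulation study: a triangle network of two-arm
#' trials comparing a new intervention (N), an old intervention (O) and
#' placebo (P), with trial sizes, baseline risks, true effects,
#' inconsistency, between-trial variance and the missingness process all
#' configurable. The defaults are the study conditions: a typical loop of
#' 1 NO, 3 NP and 4 OP trials; arm sizes U(102, 187) for placebo-controlled
#' and U(128, 241) for old-controlled trials; control-arm risks U(0.27,
#' 0.40) and U(0.63, 0.76); true log ORs log 2 (N vs P) and log 1.5 (O vs
#' P); the NO effect closed by consistency plus an inconsistency factor
#' drawn from a scaled-shifted t (scale 0.44, 3 df, centred at 0 or 1);
#' tau2 from the predictive log-normals LN(-3.95, 1.34^2) ("small") or
#' LN(-2.56, 1.74^2) ("substantial"); and moderate/large, balanced or
#' unbalanced missingness with truncated-normal informative log IMORs
#' (active arms' completers twice as likely to have improved, placebo the
#' mirror image) or N(0, 1) MAR draws.
#'
#' @param trials_per_comparison Named counts of two-arm trials per edge,
#'   default `c(NO = 1, NP = 3, OP = 4)`.
#' @param inconsistency `"low"` (IF centred at 0) or `"moderate"` (centred
#'   at 1); `if_fixed` overrides with an exact IF value.
#' @param tau2 `"small"`, `"substantial"`, or a fixed numeric value.
#' @param mod_extent `"moderate"` or `"large"`.
#' @param mod_balance `"balanced"` or `"unbalanced"`.
#' @param mechanism `"informative"` or `"mar"`.
#' @param if_fixed Optional fixed inconsistency factor.
#' @param size_range_placebo,size_range_old Arm-size uniform bounds.
#' @param risk_range_placebo,risk_range_old Control-arm initial risk bounds.
#' @param lor_NP,lor_OP True basic-parameter log ORs.
#' @param if_scale,if_df Scale and df of the t-distributed IF.
#' @param imor_sd2 Variance of the simulated log IMORs.
#' @param placebo_var_fraction Share of the trial-level random deviation
#'   carried by the control arm in placebo-controlled trials (placebo log
#'   odds vary less than active-arm log odds); old-controlled trials split
#'   it evenly.
#' @param labels Intervention labels, default `c(new = "N", old = "O",
#'   placebo = "P")`.
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(trials_per_comparison = c(NO = 1, NP = 3, OP = 4),
                         inconsistency = c("low", "moderate"),
                         tau2 = c("small", "substantial"),
                         mod_extent = c("moderate", "large"),
                         mod_balance = c("balanced", "unbalanced"),
                         mechanism = c("informative", "mar"),
                         if_fixed = NULL,
                         size_range_placebo = c(102, 187),
                         size_range_old = c(128, 241),
                         risk_range_placebo = c(0.27, 0.40),
                         risk_range_old = c(0.63, 0.76),
                         lor_NP = log(2), lor_OP = log(1.5),
                         if_scale = 0.44, if_df = 3,
                         imor_sd2 = 1,
                         placebo_var_fraction = 0.25,
                         labels = c(new = "N", old = "O", placebo = "P")) {
  inconsistency <- match.arg(inconsistency)
  mod_extent <- match.arg(mod_extent)
  mod_balance <- match.arg(mod_balance)
  mechanism <- match.arg(mechanism)
  if (is.character(tau2)) {
    tau2 <- match_arg2(tau2, c("small", "substantial"), "tau2")
    tau2_meanlog <- if (tau2 == "small") -3.95 else -2.56
    tau2_sdlog <- if (tau2 == "small") 1.34 else 1.74
    tau2_fixed <- NULL
  } else {
    assert_that(is.numeric(tau2) && tau2 >= 0, "`tau2` must be non-negative.",
                "misnma_config_error")
    tau2_fixed <- tau2
    tau2_meanlog <- tau2_sdlog <- NA_real_
    tau2 <- "fixed"
  }
  stopifnot(all(c("NO", "NP", "OP") %in% names(trials_per_comparison)))
  assert_that(sum(trials_per_comparison[c("NP", "OP")] > 0) == 2 ||
                trials_per_comparison[["NO"]] > 0,
              "The triangle must be connected.", "misnma_config_error")
  ranges_ok <- function(r) length(r) == 2 && r[1] <= r[2]
  stopifnot(ranges_ok(size_range_placebo), ranges_ok(size_range_old),
            ranges_ok(risk_range_placebo), ranges_ok(risk_range_old))
  structure(
    list(trials_per_comparison = trials_per_comparison,
         inconsistency = inconsistency,
         if_center = if (inconsistency == "low") 0 else 1,
         if_scale = if_scale, if_df = if_df, if_fixed = if_fixed,
         tau2_class = tau2, tau2_meanlog = tau2_meanlog,
         tau2_sdlog = tau2_sdlog, tau2_fixed = tau2_fixed,
         mod_extent = mod_extent, mod_balance = mod_balance,
         mechanism = mechanism,
         size_range_placebo = size_range_placebo,
         size_range_old = size_range_old,
         risk_range_placebo = risk_range_placebo,
         risk_range_old = risk_range_old,
         lor_NP = lor_NP, lor_OP = lor_OP,
         imor_sd2 = imor_sd2,
         placebo_var_fraction = placebo_var_fraction,
         labels = labels),
    class = "sim_scenario"
  )
}

#' Predictive median of the scenario's tau2 distribution
#'
#' The median of LN(meanlog, sdlog^2) is `exp(meanlog)`: about 0.02 for the
#' small and 0.08 for the substantial heterogeneity setting.
#'
#' @param scenario A [sim_scenario()].
#' @return A single number.
#' @export
tau2_predictive_median <- function(scenario) {
  if (scenario$tau2_class == "fixed") return(scenario$tau2_fixed)
  exp(scenario$tau2_meanlog)
}

#' Draw the per-network constants
#'
#' Each simulated network gets one inconsistency factor (scaled-shifted
#' Student t) and one between-trial variance (log-normal predictive draw,
#' or the fixed value).
#'
#' @param scenario A [sim_scenario()].
#' @return List with elements `IF` and `tau2`.
#' @export
draw_scenario_constants <- function(scenario) {
  IF <- if (!is.null(scenario$if_fixed)) {
    scenario$if_fixed
  } else {
    scenario$if_center + scenario$if_scale * stats::rt(1, scenario$if_df)
  }
  tau2 <- if (scenario$tau2_class == "fixed") {
    scenario$tau2_fixed
  } else {
    exp(stats::rnorm(1, scenario$tau2_meanlog, scenario$tau2_sdlog))
  }
  list(IF = IF, tau2 = tau2)
}

#' Simulate the complete (pre-missingness) triangle network
#'
#' One two-arm trial per requested comparison slot. For each trial the
#' shared sample size comes from the comparison type's uniform range, the
#' control-arm initial risk from its range, and the trial-level random
#' deviation `eps ~ N(0, tau2)` is split between the arms: the control arm
#' gets `-a * eps` and the experimental arm `+(1 - a) * eps` on the log-odds
#' scale, so the contrast variance is exactly `tau2` while placebo log odds
#' vary less (`a = placebo_var_fraction` in placebo-controlled trials, 0.5
#' in old-controlled ones). The true NO effect is
#' `lor_NP - lor_OP + IF`. Complete-data events are binomial in each arm.
#'
#' @param scenario A [sim_scenario()].
#' @param constants Optional list `(IF, tau2)`; drawn via
#'   [draw_scenario_constants()] when `NULL`.
#' @return A list of class `sim_complete`: `arms` (tibble with one row per
#'   arm: trial, comparison, intervention, role, n, true risk `p`, complete
#'   events `r_complete`, trial deviation `eps`, true trial log OR
#'   `lor_trial`) and `constants`.
#' @export
simulate_complete_network <- function(scenario, constants = NULL) {
  constants <- constants %||% draw_scenario_constants(scenario)
  lb <- scenario$labels
  lor_NO <- scenario$lor_NP - scenario$lor_OP + constants$IF
  specs <- list(
    NO = list(ctrl = lb[["old"]], exp = lb[["new"]], lor = lor_NO,
              size = scenario$size_range_old, risk = scenario$risk_range_old,
              a = 0.5),
    NP = list(ctrl = lb[["placebo"]], exp = lb[["new"]], lor = scenario$lor_NP,
              size = scenario$size_range_placebo,
              risk = scenario$risk_range_placebo,
              a = scenario$placebo_var_fraction),
    OP = list(ctrl = lb[["placebo"]], exp = lb[["old"]], lor = scenario$lor_OP,
              size = scenario$size_range_placebo,
              risk = scenario$risk_range_placebo,
              a = scenario$placebo_var_fraction)
  )
  rows <- list()
  trial_no <- 0
  for (cmp in c("NO", "NP", "OP")) {
    for (rep_i in seq_len(scenario$trials_per_comparison[[cmp]])) {
      trial_no <- trial_no + 1
      sp <- specs[[cmp]]
      n_arm <- floor(stats::runif(1, sp$size[1], sp$size[2] + 1))
      p0 <- stats::runif(1, sp$risk[1], sp$risk[2])
      eps <- stats::rnorm(1, 0, sqrt(constants$tau2))
      eta_c <- stats::qlogis(p0) - sp$a * eps
      eta_e <- stats::qlogis(p0) + sp$lor + (1 - sp$a) * eps
      p_c <- stats::plogis(eta_c)
      p_e <- stats::plogis(eta_e)
      rows[[trial_no]] <- tibble::tibble(
        trial_id = sprintf("%s_%d", cmp, rep_i),
        comparison = cmp,
        intervention = c(sp$ctrl, sp$exp),
        role = c("control", "experimental"),
        n = n_arm,
        p = c(p_c, p_e),
        r_complete = c(stats::rbinom(1, n_arm, p_c),
                       stats::rbinom(1, n_arm, p_e)),
        eps = eps,
        lor_trial = sp$lor + eps
      )
    }
  }
  structure(list(arms = dplyr::bind_rows(rows), constants = constants,
                 scenario = scenario),
            class = "sim_complete")
}

#' Draw per-arm log IMORs for a simulated trial-arm set
#'
#' Under the informative mechanism the placebo arm's log IMOR is normal with
#' mean `-log 2` truncated above at 0 (completers more likely improved),
#' and the active arms' (N, O) is normal with mean `log 2` truncated below
#' at 0 (participants twice as likely missing because their outcome
#' improved). Under MAR every arm draws from N(0, 1).
#'
#' @param scenario A [sim_scenario()].
#' @param interventions Character vector of arm interventions.
#' @return Numeric vector of log IMORs, one per arm.
#' @export
draw_log_imors <- function(scenario, interventions) {
  sdv <- sqrt(scenario$imor_sd2)
  if (scenario$mechanism == "mar") {
    return(stats::rnorm(length(interventions), 0, sdv))
  }
  placebo <- interventions == scenario$labels[["placebo"]]
  out <- numeric(length(interventions))
  if (any(placebo)) {
    out[placebo] <- rtruncnorm1(sum(placebo), -log(2), sdv, upper = 0)
  }
  if (any(!placebo)) {
    out[!placebo] <- rtruncnorm1(sum(!placebo), log(2), sdv, lower = 0)
  }
  out
}

# Missingness-probability draws per trial following the balance rules:
# balanced -> the control arm copies the experimental arm's q; unbalanced ->
# the control arm draws from the higher range.
draw_mod_probs <- function(scenario, n_trials) {
  rng <- switch(paste(scenario$mod_extent, scenario$mod_balance),
    "moderate balanced" = list(e = c(0.05, 0.20), c = NULL),
    "large balanced" = list(e = c(0.21, 0.40), c = NULL),
    "moderate unbalanced" = list(e = c(0.05, 0.10), c = c(0.11, 0.20)),
    "large unbalanced" = list(e = c(0.21, 0.30), c = c(0.31, 0.40))
  )
  q_e <- stats::runif(n_trials, rng$e[1], rng$e[2])
  q_c <- if (is.null(rng$c)) q_e else stats::runif(n_trials, rng$c[1], rng$c[2])
  list(q_exp = q_e, q_ctrl = q_c)
}

#' Impose missing outcome data on a complete network
#'
#' Draws per-arm missingness probabilities according to the scenario's
#' extent/balance rules and log IMORs per [draw_log_imors()], then converts
#' the complete-data events into observed data by the exact joint law of the
#' 2x2 event-by-missingness table: among the `r_complete` events a
#' `Bin(c1, r_complete)` number goes missing, among the non-events a
#' `Bin(c0, .)` number, with `(c1, c0)` from [selection_cells()]. This
#' participant-level coupling has the same distribution as drawing
#' `m ~ Bin(q, n)` and then `r_obs ~ Bin(p_obs, n - m)` with `p_obs` from
#' the pattern-mixture link, and reduces bit-exactly to the complete data
#' when `q = 0`.
#'
#' @param complete A `sim_complete` from [simulate_complete_network()].
#' @param q_override Optional single value or per-arm vector forcing the
#'   missingness probability (e.g. 0 for no missingness).
#' @return A list of class `sim_network`: `network` (an [nma_network()] of
#'   the observed data with reference = placebo), `truth` (per-arm tibble
#'   with the latent `p`, `q`, `phi`, `p_obs`) and `constants`.
#' @export
impose_missingness <- function(complete, q_override = NULL) {
  stopifnot(inherits(complete, "sim_complete"))
  scenario <- complete$scenario
  arms <- complete$arms
  n_trials <- length(unique(arms$trial_id))
  qs <- draw_mod_probs(scenario, n_trials)
  trial_idx <- match(arms$trial_id, unique(arms$trial_id))
  q <- ifelse(arms$role == "experimental", qs$q_exp[trial_idx],
              qs$q_ctrl[trial_idx])
  if (!is.null(q_override)) q <- rep_len(q_override, nrow(arms))
  phi <- draw_log_imors(scenario, arms$intervention)

  pos <- q > 0
  c1 <- c0 <- numeric(nrow(arms))
  if (any(pos)) {
    cells <- selection_cells_(arms$p[pos], q[pos], phi[pos])
    c1[pos] <- cells$c1
    c0[pos] <- cells$c0
  }
  mis_events <- stats::rbinom(nrow(arms), arms$r_complete, c1)
  mis_non <- stats::rbinom(nrow(arms), arms$n - arms$r_complete, c0)
  m <- mis_events + mis_non
  r_obs <- arms$r_complete - mis_events

  obs <- tibble::tibble(
    trial_id = arms$trial_id,
    intervention = arms$intervention,
    n = arms$n,
    r_obs = r_obs,
    m = m
  )
  p_obs <- ifelse(pos, pm_observed_risk(arms$p, pmin(q, 1 - 1e-12), phi), arms$p)
  truth <- dplyr::mutate(arms, q = q, phi = phi, p_obs = p_obs,
                         m = m, r_obs = r_obs)
  structure(
    list(network = nma_network(obs, reference = scenario$labels[["placebo"]]),
         truth = truth,
         constants = complete$constants),
    class = "sim_network"
  )
}

#' Simulate one observed triangle network
#'
#' Convenience wrapper: [draw_scenario_constants()] +
#' [simulate_complete_network()] + [impose_missingness()].
#'
#' @param scenario A [sim_scenario()].
#' @return A `sim_network` (see [impose_missingness()]).
#' @export
simulate_network <- function(scenario) {
  impose_missingness(simulate_complete_network(scenario))
}

#' True probability of being best
#'
#' Monte Carlo computation of the design's true ranking probabilities: per
#' replicate draw the true placebo-comparison log ORs
#' `theta_NP ~ N(lor_NP, tau2)` and `theta_OP ~ N(lor_OP, tau2)`, set
#' placebo to 0, and record which intervention has the largest value. By
#' default `tau2` is fixed at the predictive median of the scenario's
#' heterogeneity distribution (0.02 small / 0.08 substantial); pass `tau2`
#' to mix over something else.
#'
#' @param scenario A [sim_scenario()].
#' @param reps Number of Monte Carlo replicates (>= 1e4).
#' @param tau2 Optional override of the heterogeneity variance.
#' @return A tibble with columns `intervention` (new / old / placebo
#'   labels) and `p_best`.
#' @export
true_prob_best <- function(scenario = sim_scenario(), reps = 1e5,
                           tau2 = NULL) {
  assert_that(reps >= 1e4, "`reps` must be at least 10^4.",
              "misnma_config_error")
  tau2 <- tau2 %||% tau2_predictive_median(scenario)
  sdv <- sqrt(tau2)
  th_np <- stats::rnorm(reps, scenario$lor_NP, sdv)
  th_op <- stats::rnorm(reps, scenario$lor_OP, sdv)
  best <- max.col(cbind(th_np, th_op, 0), ties.method = "first")
  lb <- scenario$labels
  tibble::tibble(
    intervention = c(lb[["new"]], lb[["old"]], lb[["placebo"]]),
    p_best = tabulate(best, 3) / reps
  )
}
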