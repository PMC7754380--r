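#' Prior specification for the log IMOR
#'
#' The informative missingness odds ratio (IMOR) links outcome and
#' missingness: on the log scale, `phi = logit(p_mis) - logit(p_obs)` under
#' the pattern-mixture factorization and `phi = logit(c1) - logit(c0)` under
#' the selection factorization (both equal the log joint odds ratio of the
#' 2x2 event-by-missingness table). `phi = 0` is missing at random.
#'
#' Two structures are supported. Under the *identical* structure one phi
#' parameter is shared by a whole group of trial-arms; under the
#' *hierarchical* structure each trial-arm has its own latent phi drawn from
#' a group-level normal with unknown mean and standard deviation. The
#' `scope` chooses the grouping: per intervention, per trial, or a single
#' group for the whole network.
#'
#' @param structure `"identical"` or `"hierarchical"`.
#' @param scope `"intervention"`, `"trial"` or `"network"`.
#' @param mean Location of the log-IMOR prior; 0 encodes MAR on average.
#' @param sd2 Variance of the identical-structure prior (default 1; values
#'   in \[0.25, 4\] span liberal to conservative uncertainty).
#' @param hyper_mean_sd2 Variance of the normal prior on the hierarchical
#'   group mean (default 1).
#' @param hyper_sd_upper Upper bound of the uniform prior on the
#'   hierarchical group standard deviation (default 1).
#' @return An object of class `imor_prior`.
#' @export
imor_prior <- function(structure = c("identical", "hierarchical"),
                       scope = c("intervention", "trial", "network"),
                       mean = 0, sd2 = 1,
                       hyper_mean_sd2 = 1, hyper_sd_upper = 1) {
  structure <- match.arg(structure)
  scope <- match.arg(scope)
  assert_that(sd2 > 0, "`sd2` must be positive.", "misnma_config_error")
  assert_that(hyper_sd_upper > 0, "`hyper_sd_upper` must be positive.",
              "misnma_config_error")
  assert_that(hyper_mean_sd2 > 0, "`hyper_mean_sd2` must be positive.",
              "misnma_config_error")
  structure(
    list(structure = structure, scope = scope, mean = mean, sd2 = sd2,
         hyper_mean_sd2 = hyper_mean_sd2, hyper_sd_upper = hyper_sd_upper),
    class = "imor_prior"
  )
}

#' Model specification for the NMA likelihood and priors
#'
#' @param missingness How missing outcome data enter the likelihood:
#'   `"none"` (completer-only binomial), `"pattern_mixture"` (binomial for
#'   the missing count and for events among completers, with the completer
#'   risk linked to the underlying risk via the log IMOR), or `"selection"`
#'   (one multinomial over observed events / observed non-events / missing).
#' @param imor_prior An [imor_prior()]; ignored when `missingness = "none"`.
#' @param tau_prior_scale Scale of the half-normal prior on the
#'   between-trial standard deviation tau (default 1).
#' @param effect_prior_sd2 Variance of the vague normal priors on trial
#'   baselines and basic parameters (default 10000).
#' @param effects `"random"` (common tau^2 across comparisons) or `"fixed"`.
#' @return An object of class `nma_model_spec`.
#' @export
model_spec <- function(missingness = c("pattern_mixture", "selection", "none"),
                       imor_prior = misnma::imor_prior(),
                       tau_prior_scale = 1,
                       effect_prior_sd2 = 10000,
                       effects = c("random", "fixed")) {
  missingness <- match.arg(missingness)
  effects <- match.arg(effects)
  assert_that(tau_prior_scale > 0, "`tau_prior_scale` must be positive.",
              "misnma_config_error")
  assert_that(effect_prior_sd2 > 0, "`effect_prior_sd2` must be positive.",
              "misnma_config_error")
  stopifnot(inherits(imor_prior, "imor_prior"))
  structure(
    list(missingness = missingness, imor_prior = imor_prior,
         tau_prior_scale = tau_prior_scale,
         effect_prior_sd2 = effect_prior_sd2, effects = effects),
    class = "nma_model_spec"
  )
}

#' @export
print.nma_model_spec <- function(x, ...) {
  cat(sprintf("<nma_model_spec> missingness: %s", x$missingness))
  if (x$missingness != "none") {
    cat(sprintf(" | log-IMOR prior: %s / %s (mean %g, sd2 %g)",
                x$imor_prior$structure, x$imor_prior$scope,
                x$imor_prior$mean, x$imor_prior$sd2))
  }
  cat(sprintf(" | effects: %s\n", x$effects))
  invisible(x)
}

# ---- serialisation ---------------------------------------------------------

#' Serialise / deserialise a model specification
#'
#' @param spec An `nma_model_spec`.
#' @param path Optional file; extension `.yaml`/`.yml` selects YAML,
#'   anything else JSON.
#' @return `spec_to_config`: a named list (written to `path` when given);
#'   `spec_from_config`: an `nma_model_spec`.
#' @export
spec_to_config <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "nma_model_spec"))
  cfg <- list(
    missingness = spec$missingness,
    structure = spec$imor_prior$structure,
    scope = spec$imor_prior$scope,
    imor_mean = spec$imor_prior$mean,
    imor_sd2 = spec$imor_prior$sd2,
    hyper_mean_sd2 = spec$imor_prior$hyper_mean_sd2,
    hyper_sd_upper = spec$imor_prior$hyper_sd_upper,
    tau_prior_scale = spec$tau_prior_scale,
    effect_prior_sd2 = spec$effect_prior_sd2,
    effects = spec$effects
  )
  if (!is.null(path)) {
    if (grepl("\\.ya?ml$", path)) {
      yaml::write_yaml(cfg, path)
    } else {
      writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), path)
    }
    return(invisible(cfg))
  }
  cfg
}

#' @rdname spec_to_config
#' @param config A named list, or a path to a YAML/JSON file holding one.
#' @export
spec_from_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.ya?ml$", config)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::fromJSON(config)
    }
  }
  model_spec(
    missingness = config$missingness %||% "pattern_mixture",
    imor_prior = imor_prior(
      structure = config$structure %||% "identical",
      scope = config$scope %||% "intervention",
      mean = config$imor_mean %||% 0,
      sd2 = config$imor_sd2 %||% 1,
      hyper_mean_sd2 = config$hyper_mean_sd2 %||% 1,
      hyper_sd_upper = config$hyper_sd_upper %||% 1
    ),
    tau_prior_scale = config$tau_prior_scale %||% 1,
    effect_prior_sd2 = config$effect_prior_sd2 %||% 10000,
    effects = config$effects %||% "random"
  )
}

# ---- IMOR transforms -------------------------------------------------------

#' Completer event risk under the pattern-mixture link
#'
#' Given the underlying event risk `p`, the missingness probability `q` and
#' the log IMOR `phi`, returns the unique completer risk `p_obs` in (0, 1)
#' satisfying the mixture identity
#' `p = p_obs (1 - q) + p_mis q` with
#' `p_mis = d p_obs / (1 - p_obs + d p_obs)`, `d = exp(phi)`.
#' The solution is the root of the quadratic
#' `(1-q)(d-1) x^2 + ((1-q) + q d - p (d-1)) x - p = 0`
#' inside (0, 1), evaluated in the cancellation-free form
#' `x = 2 p / (b + sqrt(b^2 + 4 a p))`.
#'
#' @param p Underlying event risk, in (0, 1). Vectorised.
#' @param q Missingness probability, in \[0, 1). Vectorised.
#' @param phi Log IMOR. Vectorised.
#' @return `p_obs`, same length as the recycled inputs.
#' @export
pm_observed_risk <- function(p, q, phi) {
  n <- max(length(p), length(q), length(phi))
  p <- rep_len(p, n); q <- rep_len(q, n); phi <- rep_len(phi, n)
  if (any(q >= 1)) {
    abort_misnma("`q` = 1 leaves no completers: degenerate arm.",
                 "misnma_domain_error")
  }
  if (any(p <= 0 | p >= 1) || any(q < 0)) {
    abort_misnma("`p` must lie in (0,1) and `q` in [0,1).",
                 "misnma_domain_error")
  }
  d <- exp(phi)
  a <- (1 - q) * (d - 1)
  b <- (1 - q) + q * d - p * (d - 1)
  disc <- b^2 + 4 * a * p
  disc[disc < 0 & disc > -1e-12] <- 0  # floating-point guard
  2 * p / (b + sqrt(disc))
}

#' Event risk among the missing under the pattern-mixture link
#'
#' `logit(p_mis) = logit(p_obs) + phi`.
#'
#' @param p_obs Completer event risk, in (0, 1). Vectorised.
#' @param phi Log IMOR. Vectorised.
#' @return `p_mis`.
#' @export
pm_missing_risk <- function(p_obs, phi) {
  if (any(p_obs <= 0 | p_obs >= 1)) {
    abort_misnma("`p_obs` must lie strictly in (0,1).", "misnma_domain_error")
  }
  stats::plogis(stats::qlogis(p_obs) + phi)
}

#' Multinomial cell probabilities of the selection factorization
#'
#' Solves for the conditional missingness probabilities `c0` (among
#' non-events) and `c1` (among events) such that
#' `q = c1 p + c0 (1 - p)` and `logit(c1) - logit(c0) = phi`,
#' then returns the three observable cells: observed event
#' `p1 = (1 - c1) p`, observed non-event `p2 = (1 - c0)(1 - p)` and missing
#' `p3 = q`. `c0` is the root of
#' `(1-p)(d-1) y^2 + (p d + (1-p) - q (d-1)) y - q = 0` in \[0, 1).
#'
#' @inheritParams pm_observed_risk
#' @return A tibble with columns `p1`, `p2`, `p3`, `c1`, `c0`.
#' @export
selection_cells <- function(p, q, phi) {
  tibble::as_tibble(selection_cells_(p, q, phi))
}

# plain-list workhorse: the sampler evaluates this in a hot loop
selection_cells_ <- function(p, q, phi) {
  n <- max(length(p), length(q), length(phi))
  p <- rep_len(p, n); q <- rep_len(q, n); phi <- rep_len(phi, n)
  if (any(p <= 0 | p >= 1) || any(q < 0) || any(q >= 1)) {
    abort_misnma("`p` must lie in (0,1) and `q` in [0,1).",
                 "misnma_domain_error")
  }
  d <- exp(phi)
  a <- (1 - p) * (d - 1)
  b <- p * d + (1 - p) - q * (d - 1)
  disc <- b^2 + 4 * a * q
  disc[disc < 0 & disc > -1e-12] <- 0
  c0 <- 2 * q / (b + sqrt(disc))
  if (any(!is.finite(c0) | c0 < 0 | c0 >= 1)) {
    abort_misnma("Internal error: no selection-model root in [0,1).",
                 "misnma_internal_error")
  }
  c1 <- d * c0 / (1 + (d - 1) * c0)
  list(
    p1 = (1 - c1) * p,
    p2 = (1 - c0) * (1 - p),
    p3 = q,
    c1 = c1,
    c0 = c0
  )
}

#' Joint event-by-missingness cell probabilities
#'
#' `joint_cells_pm()` builds the 2x2 table (event/non-event crossed with
#' observed/missing) through the pattern-mixture factorization;
#' `joint_cells_selection()` through the selection factorization. The two
#' agree for every valid input because both fix the same margins `p`, `q`
#' and the same joint odds ratio `exp(phi)`.
#'
#' @inheritParams pm_observed_risk
#' @return A tibble with columns `event_obs`, `nonevent_obs`, `event_mis`,
#'   `nonevent_mis` summing to one per row.
#' @export
joint_cells_pm <- function(p, q, phi) {
  n <- max(length(p), length(q), length(phi))
  p <- rep_len(p, n); q <- rep_len(q, n); phi <- rep_len(phi, n)
  if (any(q == 0)) {
    # no missing participants: mass on the observed column only
    zero <- q == 0
    po <- p
    po[!zero] <- pm_observed_risk(p[!zero], q[!zero], phi[!zero])
    pm <- stats::plogis(stats::qlogis(po) + phi)
    return(tibble::tibble(
      event_obs = po * (1 - q), nonevent_obs = (1 - po) * (1 - q),
      event_mis = ifelse(zero, 0, pm * q),
      nonevent_mis = ifelse(zero, 0, (1 - pm) * q)
    ))
  }
  po <- pm_observed_risk(p, q, phi)
  pm <- pm_missing_risk(po, phi)
  tibble::tibble(
    event_obs = po * (1 - q),
    nonevent_obs = (1 - po) * (1 - q),
    event_mis = pm * q,
    nonevent_mis = (1 - pm) * q
  )
}

#' @rdname joint_cells_pm
#' @export
joint_cells_selection <- function(p, q, phi) {
  cells <- selection_cells(p, q, phi)
  n <- nrow(cells)
  p <- rep_len(p, n)
  tibble::tibble(
    event_obs = cells$p1,
    nonevent_obs = cells$p2,
    event_mis = cells$c1 * p,
    nonevent_mis = cells$c0 * (1 - p)
  )
}

# ---- phi parameter map -----------------------------------------------------

#' Map trial-arms to log-IMOR parameters
#'
#' Assigns every trial-arm the index of the log-IMOR parameter that governs
#' it under the chosen prior structure. Under the identical structure the
#' number of distinct phi parameters is the number of interventions, trials,
#' or one, for intervention-, trial- and network-scope respectively. Under
#' the hierarchical structure every arm carries its own latent phi and the
#' grouping instead indexes the (mean, sd) hyper-parameter pairs.
#'
#' @param net An `nma_network`.
#' @param prior An [imor_prior()].
#' @return A tibble with one row per arm: `trial_id`, `k`, `intervention`,
#'   `phi_id`, and (hierarchical only) `hyper_id`. Attributes `n_phi` and
#'   `n_hyper` carry the parameter counts; `phi_labels` / `hyper_labels`
#'   name them.
#' @export
phi_index_map <- function(net, prior) {
  stopifnot(inherits(net, "nma_network"), inherits(prior, "imor_prior"))
  arms <- net$data[, c("trial_id", "k", "intervention")]
  group <- switch(prior$scope,
    intervention = arms$intervention,
    trial = arms$trial_id,
    network = rep("network", nrow(arms))
  )
  labels <- sort(unique(group))
  gid <- match(group, labels)
  if (prior$structure == "identical") {
    out <- dplyr::mutate(arms, phi_id = gid)
    attr(out, "n_phi") <- length(labels)
    attr(out, "n_hyper") <- 0L
    attr(out, "phi_labels") <- labels
  } else {
    out <- dplyr::mutate(arms, phi_id = dplyr::row_number(), hyper_id = gid)
    attr(out, "n_phi") <- nrow(arms)
    attr(out, "n_hyper") <- length(labels)
    attr(out, "phi_labels") <- paste(arms$trial_id, arms$intervention, sep = ":")
    attr(out, "hyper_labels") <- labels
  }
  out
}
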