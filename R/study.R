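#' Build a grid of model specifications
#'
#' Expands missingness models by prior structure and scope into a tibble of
#' `nma_model_spec` objects. The default grid is the twelve models of the
#' simulation design: pattern-mixture and selection, each under identical
#' and hierarchical structure crossed with intervention-, trial- and
#' network-scope log IMORs. `missingness = "none"` rows ignore structure
#' and scope.
#'
#' @param missingness Character vector from
#'   `c("pattern_mixture", "selection", "none")`.
#' @param structure,scope Character vectors of prior-structure choices.
#' @param ... Passed on to [model_spec()] (e.g. `tau_prior_scale`).
#' @return A tibble with columns `model_id`, `missingness`, `structure`,
#'   `scope` and a list-column `spec`.
#' @export
model_grid <- function(missingness = c("pattern_mixture", "selection"),
                       structure = c("identical", "hierarchical"),
                       scope = c("intervention", "trial", "network"),
                       ...) {
  assert_that(length(missingness) > 0, "The model grid must not be empty.",
              "misnma_usage_error")
  rows <- list()
  for (ms in missingness) {
    if (ms == "none") {
      rows[[length(rows) + 1]] <- tibble::tibble(
        missingness = "none", structure = NA_character_, scope = NA_character_,
        spec = list(model_spec("none", ...))
      )
    } else {
      for (st in structure) for (sc in scope) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          missingness = ms, structure = st, scope = sc,
          spec = list(model_spec(ms, imor_prior(st, sc), ...))
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  dplyr::mutate(out, model_id = dplyr::row_number(), .before = 1)
}

model_label <- function(missingness, structure, scope) {
  ifelse(missingness == "none", "none",
         paste(missingness, structure, scope, sep = "/"))
}

#' Run a (scaled-down) simulation study
#'
#' For every replicate: simulate an observed triangle network from the
#' scenario, fit every model in the grid, optionally node-split the
#' new-versus-old comparison, and collect posterior summaries into one long
#' table keyed by (replicate, model, estimand). Per-replicate and per-fit
#' seeds are derived deterministically from `seed`, so the same call
#' reproduces the same table bit for bit. Individual fit failures are
#' caught, flagged in the `error` column and tolerated up to a 20% failure
#' rate.
#'
#' @param scenario A [sim_scenario()].
#' @param n_networks Number of simulated networks.
#' @param models A tibble from [model_grid()] (or a single
#'   `nma_model_spec`).
#' @param mcmc An [mcmc_options()]; its seed field is overridden by the
#'   derived per-fit seeds.
#' @param seed Master seed.
#' @param nodesplit Split the new-vs-old comparison per replicate?
#' @param direction Ranking direction for the probability of being best.
#' @return A tibble of class `nma_study` with columns `replicate`,
#'   `model_id`, `model`, `missingness`, `structure`, `scope`, `estimand`,
#'   `estimate` (posterior mean), `median`, `sd`, `conf.low`, `conf.high`,
#'   `rhat_max`, `error`. The per-replicate truth (`IF`, `tau2`, `mu_NO`)
#'   is attached as attribute `truth`.
#' @export
run_study <- function(scenario, n_networks, models = model_grid(),
                      mcmc = mcmc_options(iterations = 6000, burn_in = 1000,
                                          thin = 1),
                      seed = 1, nodesplit = FALSE,
                      direction = "higher-better") {
  assert_that(n_networks >= 1, "`n_networks` must be at least 1.",
              "misnma_usage_error")
  if (inherits(models, "nma_model_spec")) {
    models <- tibble::tibble(
      model_id = 1L, missingness = models$missingness,
      structure = if (models$missingness == "none") NA_character_ else models$imor_prior$structure,
      scope = if (models$missingness == "none") NA_character_ else models$imor_prior$scope,
      spec = list(models)
    )
  }
  assert_that(nrow(models) > 0, "The model grid must not be empty.",
              "misnma_usage_error")
  set.seed(seed)
  rep_seeds <- sample.int(2^31 - 2, n_networks)
  fit_seeds <- matrix(sample.int(2^31 - 2, n_networks * (nrow(models) + 1)),
                      n_networks)
  lb <- scenario$labels

  rows <- list()
  truths <- list()
  n_fail <- 0
  for (rep_i in seq_len(n_networks)) {
    set.seed(rep_seeds[rep_i])
    sim <- simulate_network(scenario)
    truths[[rep_i]] <- tibble::tibble(
      replicate = rep_i,
      IF = sim$constants$IF,
      tau2 = sim$constants$tau2,
      mu_NO = scenario$lor_NP - scenario$lor_OP + sim$constants$IF
    )
    for (mi in seq_len(nrow(models))) {
      m <- mcmc
      m$seed <- fit_seeds[rep_i, mi]
      res <- tryCatch({
        f <- suppressWarnings(fit(sim$network, models$spec[[mi]], m))
        summarise_fit_rows(f, lb, direction)
      }, error = function(e) {
        tibble::tibble(estimand = "fit", estimate = NA_real_,
                       median = NA_real_, sd = NA_real_,
                       conf.low = NA_real_, conf.high = NA_real_,
                       rhat_max = NA_real_, error = conditionMessage(e))
      })
      if (!"error" %in% names(res)) res$error <- NA_character_
      if (any(!is.na(res$error))) n_fail <- n_fail + 1
      rows[[length(rows) + 1]] <- dplyr::mutate(
        res, replicate = rep_i, model_id = models$model_id[mi],
        missingness = models$missingness[mi],
        structure = models$structure[mi], scope = models$scope[mi],
        model = model_label(models$missingness[mi], models$structure[mi],
                            models$scope[mi]),
        .before = 1)
    }
    if (nodesplit) {
      m <- mcmc
      m$seed <- fit_seeds[rep_i, nrow(models) + 1]
      ns_spec <- models$spec[[1]]
      res <- tryCatch({
        ns <- suppressWarnings(node_split(sim$network,
                                          c(lb[["new"]], lb[["old"]]),
                                          ns_spec, m))
        s <- ns$IF
        tibble::tibble(estimand = "IF", estimate = s$mean, median = s$median,
                       sd = s$sd, conf.low = s$conf.low,
                       conf.high = s$conf.high,
                       rhat_max = suppressWarnings(
                         max(ns$fit$diagnostics$rhat, na.rm = TRUE)),
                       error = NA_character_)
      }, error = function(e) {
        tibble::tibble(estimand = "IF", estimate = NA_real_, median = NA_real_,
                       sd = NA_real_, conf.low = NA_real_, conf.high = NA_real_,
                       rhat_max = NA_real_, error = conditionMessage(e))
      })
      if (any(!is.na(res$error))) n_fail <- n_fail + 1
      rows[[length(rows) + 1]] <- dplyr::mutate(
        res, replicate = rep_i, model_id = models$model_id[1],
        missingness = models$missingness[1],
        structure = models$structure[1], scope = models$scope[1],
        model = paste0("nodesplit:",
                       model_label(models$missingness[1], models$structure[1],
                                   models$scope[1])),
        .before = 1)
    }
  }
  n_units <- n_networks * (nrow(models) + as.integer(nodesplit))
  if (n_fail > 0.2 * n_units) {
    abort_misnma(sprintf("Too many fit failures: %d of %d units.",
                         n_fail, n_units), "misnma_study_error")
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "truth") <- dplyr::bind_rows(truths)
  attr(out, "seed") <- seed
  attr(out, "scenario") <- scenario
  class(out) <- c("nma_study", class(out))
  out
}

summarise_fit_rows <- function(f, labels, direction) {
  rhat_max <- suppressWarnings(max(f$diagnostics$rhat, na.rm = TRUE))
  row_of <- function(est, draws) {
    s <- posterior_summary(draws)
    tibble::tibble(estimand = est, estimate = s$mean, median = s$median,
                   sd = s$sd, conf.low = s$conf.low, conf.high = s$conf.high,
                   rhat_max = rhat_max)
  }
  out <- list(
    row_of("mu_NP", contrast_draws(f, labels[["new"]], labels[["placebo"]])),
    row_of("mu_OP", contrast_draws(f, labels[["old"]], labels[["placebo"]])),
    row_of("mu_NO", contrast_draws(f, labels[["new"]], labels[["old"]])),
    row_of("tau2", pooled_draws(f, "tau2")[, 1])
  )
  pb <- prob_best(f, direction)
  for (nm in names(pb)) {
    out[[length(out) + 1]] <- tibble::tibble(
      estimand = paste0("p_best_", nm), estimate = pb[[nm]],
      median = NA_real_, sd = NA_real_, conf.low = NA_real_,
      conf.high = NA_real_, rhat_max = rhat_max)
  }
  dplyr::bind_rows(out)
}

#' Plot-ready interval table
#'
#' Collapses tidy fit rows or a study table to one row per (estimand,
#' model) with a point estimate and 95% interval bounds, following the
#' reporting convention: posterior means for log ORs and IFs, posterior
#' medians for `tau2`. Multiple replicates are averaged.
#'
#' @param rows A tibble with columns `estimand` (or `term`), `model` (added
#'   as `"model"` when absent), `estimate`, `median`, `conf.low`,
#'   `conf.high`.
#' @return A tibble sorted by estimand then model with columns `estimand`,
#'   `model`, `point`, `conf.low`, `conf.high`.
#' @export
interval_table <- function(rows) {
  assert_that(nrow(rows) >= 1, "Need at least one row.", "misnma_usage_error")
  if (!"estimand" %in% names(rows) && "term" %in% names(rows)) {
    rows <- dplyr::rename(rows, estimand = "term")
  }
  if (!"model" %in% names(rows)) rows$model <- "model"
  rows |>
    dplyr::group_by(.data$estimand, .data$model) |>
    dplyr::summarise(
      point = mean(ifelse(.data$estimand == "tau2", .data$median,
                          .data$estimate), na.rm = TRUE),
      conf.low = mean(.data$conf.low, na.rm = TRUE),
      conf.high = mean(.data$conf.high, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$estimand, .data$model)
}
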