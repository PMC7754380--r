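# Pooled draws (all chains) for a set of columns.
pooled_draws <- function(x, cols = NULL) {
  m <- do.call(rbind, x$draws)
  if (is.null(cols)) m else m[, cols, drop = FALSE]
}

#' Posterior draws of basic parameters
#'
#' @param x An `nma_fit`.
#' @return Matrix (draws x interventions) of log OR versus the network
#'   reference, including the reference column (identically 0), in
#'   intervention order `c(reference, others)`.
#' @export
basic_draws <- function(x) {
  stopifnot(inherits(x, "nma_fit"))
  treats <- x$model$treats
  m <- pooled_draws(x, paste0("mu[", treats[-1], "]"))
  out <- cbind(0, m)
  colnames(out) <- treats
  out
}

#' Posterior draws of an arbitrary contrast
#'
#' Functional parameters are never sampled: the contrast `t` vs `l` is
#' derived draw-by-draw as `mu_tA - mu_lA` through the consistency equation.
#'
#' @param x An `nma_fit`.
#' @param t,l Intervention labels.
#' @return Numeric vector of pooled posterior draws of the log OR of `t`
#'   versus `l`.
#' @export
contrast_draws <- function(x, t, l) {
  b <- basic_draws(x)
  assert_that(all(c(t, l) %in% colnames(b)),
              "Both interventions must be in the network.")
  b[, t] - b[, l]
}

#' Equal-tailed posterior summary of a draw vector
#'
#' @param draws Numeric vector of posterior draws (>= 2).
#' @return One-row tibble: `mean`, `median`, `sd`, `conf.low`, `conf.high`
#'   (2.5 and 97.5 linear-interpolation percentiles).
#' @export
posterior_summary <- function(draws) {
  assert_that(length(draws) >= 2, "Need at least two draws to summarise.")
  qs <- stats::quantile(draws, c(0.025, 0.975), names = FALSE, type = 7)
  tibble::tibble(mean = mean(draws), median = stats::median(draws),
                 sd = stats::sd(draws), conf.low = qs[1], conf.high = qs[2])
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy posterior summaries of an NMA fit
#'
#' @param x An `nma_fit`.
#' @param parameters Which parameters to summarise: `"basic"` (log OR of
#'   each non-reference intervention versus the reference, plus `tau2`),
#'   `"contrasts"` (every pairwise log OR via the consistency equation,
#'   plus `tau2`) or `"all"` (every sampled column).
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate` (posterior mean),
#'   `median`, `std.error` (posterior SD), `conf.low`, `conf.high` (95%
#'   equal-tailed credible interval), `rhat`, `ess`. By the reporting
#'   convention used throughout, log ORs are read from `estimate` and
#'   `tau2` from `median`.
#' @method tidy nma_fit
#' @export
tidy.nma_fit <- function(x, parameters = c("basic", "contrasts", "all"), ...) {
  parameters <- match.arg(parameters)
  treats <- x$model$treats
  diag <- x$diagnostics
  summarise_cols <- function(terms, draws_list) {
    purrr::map2_dfr(terms, draws_list, function(tm, dr) {
      s <- posterior_summary(dr)
      dg <- diag[diag$term == tm, ]
      tibble::tibble(term = tm, estimate = s$mean, median = s$median,
                     std.error = s$sd, conf.low = s$conf.low,
                     conf.high = s$conf.high,
                     rhat = if (nrow(dg)) dg$rhat else NA_real_,
                     ess = if (nrow(dg)) dg$ess else NA_real_)
    })
  }
  if (parameters == "all") {
    cols <- colnames(x$draws[[1]])
    return(summarise_cols(cols, purrr::map(cols, function(cn) pooled_draws(x, cn)[, 1])))
  }
  b <- basic_draws(x)
  if (parameters == "basic") {
    terms <- paste0("mu[", treats[-1], "]")
    drs <- purrr::map(treats[-1], function(t) b[, t] - b[, treats[1]])
  } else {
    prs <- utils::combn(treats, 2)
    terms <- paste0("mu[", prs[2, ], ":", prs[1, ], "]")
    drs <- purrr::map(seq_len(ncol(prs)), function(j) b[, prs[2, j]] - b[, prs[1, j]])
  }
  out <- summarise_cols(terms, drs)
  if (x$model$random) {
    out <- dplyr::bind_rows(out,
                            summarise_cols("tau2", list(pooled_draws(x, "tau2")[, 1])))
  }
  out
}

#' One-row model overview
#'
#' @param x An `nma_fit`.
#' @param ... Unused.
#' @return A tibble with network size, model labels, sampling settings and
#'   the worst R-hat / smallest ESS across parameters.
#' @method glance nma_fit
#' @export
glance.nma_fit <- function(x, ...) {
  tibble::tibble(
    n_trials = x$net$n_trials,
    n_interventions = length(x$net$interventions),
    missingness = x$spec$missingness,
    structure = if (x$spec$missingness == "none") NA_character_ else x$spec$imor_prior$structure,
    scope = if (x$spec$missingness == "none") NA_character_ else x$spec$imor_prior$scope,
    effects = x$spec$effects,
    chains = x$mcmc$chains,
    draws = length(x$draws) * nrow(x$draws[[1]]),
    max_rhat = suppressWarnings(max(x$diagnostics$rhat, na.rm = TRUE)),
    min_ess = min(x$diagnostics$ess, na.rm = TRUE)
  )
}

#' Posterior rank probabilities
#'
#' Orders the basic parameters in every MCMC draw and tabulates, for each
#' intervention, the frequency of achieving each rank. Ties are broken by a
#' uniform random permutation, so the table is doubly stochastic.
#'
#' @param x An `nma_fit`.
#' @param direction `"higher-better"` (rank 1 = largest log OR versus the
#'   reference) or `"lower-better"`.
#' @return A tibble of class `nma_ranks` with columns `intervention`,
#'   `rank`, `probability`; the T x T matrix is attached as attribute
#'   `matrix`.
#' @export
rank_probabilities <- function(x, direction = c("higher-better", "lower-better")) {
  direction <- match.arg(direction)
  b <- basic_draws(x)
  sgn <- if (direction == "higher-better") -1 else 1
  T_ <- ncol(b)
  counts <- matrix(0, T_, T_, dimnames = list(colnames(b), seq_len(T_)))
  rk <- t(apply(sgn * b, 1, rank, ties.method = "random"))
  for (t in seq_len(T_)) {
    tab <- tabulate(rk[, t], nbins = T_)
    counts[t, ] <- tab
  }
  probs <- counts / nrow(b)
  out <- tibble::as_tibble(as.data.frame.table(probs, stringsAsFactors = FALSE))
  names(out) <- c("intervention", "rank", "probability")
  out$rank <- as.integer(out$rank)
  out <- dplyr::arrange(out, .data$intervention, .data$rank)
  attr(out, "matrix") <- probs
  class(out) <- c("nma_ranks", class(out))
  out
}

#' Probability of being best
#'
#' @param x An `nma_fit`.
#' @param direction Passed to [rank_probabilities()].
#' @return Named numeric vector: posterior probability that each
#'   intervention ranks first.
#' @export
prob_best <- function(x, direction = c("higher-better", "lower-better")) {
  rp <- rank_probabilities(x, direction)
  m <- attr(rp, "matrix")
  stats::setNames(m[, 1], rownames(m))
}
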