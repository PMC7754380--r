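#' Node-splitting assessment of local inconsistency
#'
#' Fits a single joint model in which the chosen comparison is isolated: the
#' trials containing both of its interventions inform a direct-effect
#' parameter only, while the rest of the network estimates the indirect
#' effect through the consistency structure. A common between-trial variance
#' is shared by both components. The inconsistency factor is the draw-wise
#' difference `IF = direct - indirect`, and `p_conflict` is the two-sided
#' posterior probability `2 min(P(IF > 0), P(IF < 0))` (both one-sided tails
#' are reported too, since decision rules differ on sidedness).
#'
#' Multi-arm trials that contain the split comparison are assigned to the
#' direct component with their remaining contrasts dropped.
#'
#' @param net An `nma_network`.
#' @param comparison Character vector of two intervention labels; must be a
#'   row of [splittable_comparisons()].
#' @param spec An `nma_model_spec`.
#' @param mcmc An [mcmc_options()].
#' @return An object of class `nma_nodesplit`: the underlying `nma_fit`
#'   plus `direct`, `indirect` and `IF` summaries, the IF draws and the
#'   conflict probabilities.
#' @export
node_split <- function(net, comparison, spec = model_spec(),
                       mcmc = mcmc_options()) {
  mod <- compile_model(net, spec, split = comparison)
  fit <- fit_compiled(mod, mcmc)
  direct <- pooled_draws(fit, "d_split")[, 1]
  indirect <- contrast_draws(fit, comparison[1], comparison[2])
  if_draws <- direct - indirect
  p_gt <- mean(if_draws > 0)
  p_lt <- mean(if_draws < 0)
  structure(
    list(
      comparison = as.character(comparison),
      fit = fit,
      direct = posterior_summary(direct),
      indirect = posterior_summary(indirect),
      IF = posterior_summary(if_draws),
      if_draws = if_draws,
      p_gt = p_gt, p_lt = p_lt,
      p_conflict = 2 * min(p_gt, p_lt)
    ),
    class = "nma_nodesplit"
  )
}

#' @export
print.nma_nodesplit <- function(x, ...) {
  cat(sprintf("<nma_nodesplit> %s vs %s\n", x$comparison[1], x$comparison[2]))
  print(tidy(x))
  cat(sprintf("p_conflict (two-sided) = %.3f  [P(IF>0) = %.3f, P(IF<0) = %.3f]\n",
              x$p_conflict, x$p_gt, x$p_lt))
  invisible(x)
}

#' @describeIn node_split Tidy direct / indirect / inconsistency summaries.
#' @param x An `nma_nodesplit`.
#' @param ... Unused.
#' @method tidy nma_nodesplit
#' @export
tidy.nma_nodesplit <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$direct, term = "direct", .before = 1),
    dplyr::mutate(x$indirect, term = "indirect", .before = 1),
    dplyr::mutate(x$IF, term = "IF", .before = 1)
  ) |>
    dplyr::rename(estimate = "mean", std.error = "sd")
}

#' @describeIn node_split One-row overview with the conflict probability.
#' @method glance nma_nodesplit
#' @export
glance.nma_nodesplit <- function(x, ...) {
  dplyr::mutate(glance(x$fit),
                comparison = paste(x$comparison, collapse = " vs "),
                p_conflict = x$p_conflict, .before = 1)
}
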