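`%||%` <- function(x, y) if (is.null(x)) y else x

# x*log(p) with the 0*log(0) = 0 convention used by multinomial kernels
xlogy <- function(x, y) {
  out <- x * log(y)
  out[x == 0] <- 0
  out
}

clamp01 <- function(x, eps = 1e-12) pmin(pmax(x, eps), 1 - eps)

abort_misnma <- function(msg, class) {
  rlang::abort(msg, class = c(class, "misnma_error"))
}

assert_that <- function(ok, msg, class = "misnma_contract_error") {
  if (!isTRUE(ok)) abort_misnma(msg, class)
  invisible(TRUE)
}

match_arg2 <- function(arg, choices, name) {
  arg <- as.character(arg)[1]
  if (!arg %in% choices) {
    abort_misnma(
      sprintf("`%s` must be one of %s, not '%s'.", name,
              paste0("'", choices, "'", collapse = ", "), arg),
      "misnma_config_error"
    )
  }
  arg
}
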