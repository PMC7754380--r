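#' Build an arm-level network meta-analysis dataset
#'
#' Validates arm-level aggregate data for a network of trials with a binary
#' outcome and (possibly) missing outcome data, and attaches the network
#' bookkeeping used by the models: the ordered intervention set, the
#' reference intervention and per-trial arm indexing.
#'
#' @param data A data frame with one row per trial-arm and columns
#'   `trial_id` (trial label), `intervention` (arm label), `n` (randomized),
#'   `r_obs` (events among completers) and `m` (participants with missing
#'   outcome). Row order within a trial is preserved; the first listed arm of
#'   each trial is its baseline arm.
#' @param reference Reference intervention used to define the basic
#'   parameters. Defaults to the most-connected intervention (ties broken
#'   lexicographically), which stabilises basic-parameter estimation.
#' @param baseline Optional named character vector overriding the baseline
#'   arm of selected trials, e.g. `c("3" = "placebo")`.
#'
#' @return An object of class `nma_network`: the validated data as a tibble
#'   (with arm index `k` and completer count `n_obs` added) plus network
#'   metadata (`interventions`, `reference`, `n_trials`).
#' @seealso [read_network()], [comparison_graph()], [splittable_comparisons()]
#' @export
nma_network <- function(data, reference = NULL, baseline = NULL) {
  required <- c("trial_id", "intervention", "n", "r_obs", "m")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort_misnma(
      paste0("Missing required column(s): ", paste(missing_cols, collapse = ", ")),
      "misnma_format_error"
    )
  }
  data <- tibble::as_tibble(data)
  data$trial_id <- as.character(data$trial_id)
  data$intervention <- as.character(data$intervention)
  for (col in c("n", "r_obs", "m")) {
    x <- data[[col]]
    if (!is.numeric(x) || any(is.na(x)) || any(x != floor(x))) {
      abort_misnma(sprintf("Column '%s' must contain non-missing integers.", col),
                   "misnma_format_error")
    }
    data[[col]] <- as.integer(x)
  }

  # per-arm invariants: n >= 2, 0 <= m <= n, 0 <= r_obs <= n - m
  data <- dplyr::group_by(data, .data$trial_id) |>
    dplyr::mutate(k = dplyr::row_number()) |>
    dplyr::ungroup()
  bad <- data$n < 2 | data$m < 0 | data$m > data$n |
    data$r_obs < 0 | data$r_obs > data$n - data$m
  if (any(bad)) {
    first <- which(bad)[1]
    abort_misnma(
      sprintf(paste0(
        "Invalid counts in trial '%s', arm %d ('%s'): need n >= 2, ",
        "0 <= m <= n and 0 <= r_obs <= n - m (got n=%d, r_obs=%d, m=%d)."),
        data$trial_id[first], data$k[first], data$intervention[first],
        data$n[first], data$r_obs[first], data$m[first]),
      "misnma_validation_error"
    )
  }

  # optional baseline override: rotate the chosen arm to position 1
  if (!is.null(baseline)) {
    data <- data |>
      dplyr::group_by(.data$trial_id) |>
      dplyr::group_modify(function(df, key) {
        id <- key$trial_id[1]
        want <- if (id %in% names(baseline)) baseline[[id]] else NULL
        if (!is.null(want) && !is.na(want)) {
          idx <- which(df$intervention == want)
          if (length(idx) != 1) {
            abort_misnma(sprintf(
              "Baseline override '%s' is not an arm of trial '%s'.",
              want, id), "misnma_validation_error")
          }
          df <- df[c(idx, setdiff(seq_len(nrow(df)), idx)), ]
        }
        df
      }) |>
      dplyr::ungroup() |>
      dplyr::group_by(.data$trial_id) |>
      dplyr::mutate(k = dplyr::row_number()) |>
      dplyr::ungroup()
  }

  per_trial <- dplyr::count(data, .data$trial_id, name = "a")
  if (any(per_trial$a < 2)) {
    abort_misnma(
      sprintf("Trial '%s' has fewer than 2 arms.",
              per_trial$trial_id[which(per_trial$a < 2)[1]]),
      "misnma_validation_error"
    )
  }
  dup <- data |>
    dplyr::count(.data$trial_id, .data$intervention, name = "n_rows") |>
    dplyr::filter(.data$n_rows > 1)
  if (nrow(dup) > 0) {
    abort_misnma(
      sprintf("Trial '%s' lists intervention '%s' more than once.",
              dup$trial_id[1], dup$intervention[1]),
      "misnma_validation_error"
    )
  }

  interventions <- sort(unique(data$intervention))
  edges <- edge_table(data)
  if (!graph_connected(interventions, edges)) {
    abort_misnma("The comparison graph is not connected.",
                 "misnma_connectivity_error")
  }

  if (is.null(reference)) {
    deg <- purrr::map_int(interventions, function(t) {
      sum(edges$from == t | edges$to == t)
    })
    reference <- interventions[order(-deg, interventions)][1]
  } else {
    reference <- as.character(reference)
    if (!reference %in% interventions) {
      abort_misnma(sprintf("Reference '%s' is not an intervention in the data.",
                           reference), "misnma_validation_error")
    }
  }

  data$n_obs <- data$n - data$m
  structure(
    list(
      data = data,
      trials = unique(data$trial_id),
      interventions = interventions,
      reference = reference,
      n_trials = length(unique(data$trial_id))
    ),
    class = "nma_network"
  )
}

#' Read an arm-level network from delimited text
#'
#' Reads a CSV or TSV file (delimiter auto-detected from the header line)
#' with columns `trial_id, intervention, n, r_obs, m` and validates it with
#' [nma_network()].
#'
#' @param path Path to the file.
#' @param reference,baseline Passed to [nma_network()].
#' @return An `nma_network`.
#' @export
read_network <- function(path, reference = NULL, baseline = NULL) {
  if (!file.exists(path)) {
    abort_misnma(sprintf("File '%s' does not exist.", path), "misnma_format_error")
  }
  header <- readLines(path, n = 1)
  delim <- if (grepl("\t", header)) "\t" else ","
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  nma_network(df, reference = reference, baseline = baseline)
}

#' Write an arm-level network back to delimited text
#'
#' The inverse of [read_network()]: counts round-trip bit-exactly.
#'
#' @param net An `nma_network`.
#' @param path Output path; `.tsv` extension selects tab delimiting.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "nma_network"))
  out <- net$data[, c("trial_id", "intervention", "n", "r_obs", "m")]
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  readr::write_delim(out, path, delim = delim)
  invisible(path)
}

#' @method as_tibble nma_network
#' @export
as_tibble.nma_network <- function(x, ...) x$data

#' @export
print.nma_network <- function(x, ...) {
  cat(sprintf("<nma_network> %d trials, %d interventions (reference: %s)\n",
              x$n_trials, length(x$interventions), x$reference))
  cat("Interventions:", paste(x$interventions, collapse = ", "), "\n")
  print(x$data, n = 8)
  invisible(x)
}

# ---- comparison graph ------------------------------------------------------

edge_table <- function(data) {
  pairs <- data |>
    dplyr::group_by(.data$trial_id) |>
    dplyr::summarise(
      pair = list(t(utils::combn(sort(.data$intervention), 2))),
      .groups = "drop"
    )
  all_pairs <- do.call(rbind, pairs$pair)
  tibble::tibble(from = all_pairs[, 1], to = all_pairs[, 2]) |>
    dplyr::count(.data$from, .data$to, name = "n_trials") |>
    dplyr::arrange(.data$from, .data$to)
}

graph_connected <- function(nodes, edges) {
  if (length(nodes) <= 1) return(TRUE)
  seen <- nodes[1]
  frontier <- nodes[1]
  while (length(frontier) > 0) {
    nb <- unique(c(edges$to[edges$from %in% frontier],
                   edges$from[edges$to %in% frontier]))
    frontier <- setdiff(nb, seen)
    seen <- c(seen, frontier)
  }
  length(seen) == length(nodes)
}

# enumerate simple cycles of length >= 3 (undirected, canonical form)
find_loops <- function(nodes, edges) {
  if (nrow(edges) < 3) return(list())
  adj <- lapply(stats::setNames(nodes, nodes), function(v) {
    sort(unique(c(edges$to[edges$from == v], edges$from[edges$to == v])))
  })
  cycles <- list()
  seen_keys <- character(0)
  walk <- function(path) {
    head <- path[length(path)]
    for (nb in adj[[head]]) {
      if (nb == path[1] && length(path) >= 3) {
        cyc <- path
        # canonical: rotate to min node, orient towards smaller neighbour
        i <- which.min(match(cyc, nodes))
        cyc <- c(cyc[i:length(cyc)], cyc[seq_len(i - 1)])
        if (length(cyc) > 2 && match(cyc[2], nodes) > match(cyc[length(cyc)], nodes)) {
          cyc <- c(cyc[1], rev(cyc[-1]))
        }
        key <- paste(cyc, collapse = "|")
        if (!key %in% seen_keys) {
          seen_keys <<- c(seen_keys, key)
          cycles[[length(cycles) + 1]] <<- cyc
        }
      } else if (!nb %in% path) {
        walk(c(path, nb))
      }
    }
  }
  for (v in nodes) walk(v)
  cycles
}

#' Comparison graph of a network
#'
#' Derives the undirected comparison graph (one edge per intervention pair
#' co-occurring in at least one trial, with its trial count) and enumerates
#' the closed loops of length three or more. Loops are what make local
#' inconsistency assessable via node-splitting.
#'
#' @param net An `nma_network`.
#' @return A list of class `nma_graph` with `edges` (tibble `from`, `to`,
#'   `n_trials`) and `loops` (list of character vectors).
#' @export
comparison_graph <- function(net) {
  stopifnot(inherits(net, "nma_network"))
  edges <- edge_table(net$data)
  loops <- find_loops(net$interventions, edges)
  structure(list(edges = edges, loops = loops), class = "nma_graph")
}

#' @export
print.nma_graph <- function(x, ...) {
  cat(sprintf("<nma_graph> %d edges, %d loop(s)\n", nrow(x$edges), length(x$loops)))
  print(x$edges)
  invisible(x)
}

#' Comparisons eligible for node-splitting
#'
#' A comparison can be split when it has direct evidence (at least one trial
#' containing both interventions) and, after removing every trial that
#' contains both, the two interventions are still joined by an indirect path.
#'
#' @param net An `nma_network`.
#' @return A tibble with columns `from`, `to` (one row per splittable pair);
#'   zero rows when nothing is splittable.
#' @export
splittable_comparisons <- function(net) {
  stopifnot(inherits(net, "nma_network"))
  edges <- edge_table(net$data)
  keep <- purrr::pmap_lgl(edges, function(from, to, n_trials) {
    both <- net$data |>
      dplyr::group_by(.data$trial_id) |>
      dplyr::summarise(has = all(c(from, to) %in% .data$intervention),
                       .groups = "drop")
    remaining <- net$data |>
      dplyr::filter(.data$trial_id %in% both$trial_id[!both$has])
    if (nrow(remaining) == 0) return(FALSE)
    redges <- edge_table(remaining)
    nodes <- unique(remaining$intervention)
    if (!all(c(from, to) %in% nodes)) return(FALSE)
    # connected to each other through the remaining evidence?
    seen <- from
    frontier <- from
    while (length(frontier) > 0) {
      nb <- unique(c(redges$to[redges$from %in% frontier],
                     redges$from[redges$to %in% frontier]))
      frontier <- setdiff(nb, seen)
      seen <- c(seen, frontier)
    }
    to %in% seen
  })
  edges[keep, c("from", "to")]
}

#' JSON summary of a network
#'
#' @param net An `nma_network`.
#' @param path Optional path; when given the JSON is written there.
#' @return JSON string (invisibly when written to file) describing N, T,
#'   interventions, reference, edges and loops.
#' @export
network_summary <- function(net, path = NULL) {
  g <- comparison_graph(net)
  obj <- list(
    n_trials = net$n_trials,
    n_interventions = length(net$interventions),
    interventions = net$interventions,
    reference = net$reference,
    edges = g$edges,
    loops = purrr::map(g$loops, identity)
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
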