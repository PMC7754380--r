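test_that("a triangle network is built, round-trips and summarises", {
  dat <- triangle_data()
  net <- nma_network(dat, reference = "P")
  expect_s3_class(net, "nma_network")
  expect_equal(net$n_trials, 8)
  expect_equal(net$interventions, c("N", "O", "P"))
  expect_equal(net$reference, "P")
  expect_equal(as_tibble(net)$n_obs, as_tibble(net)$n - as_tibble(net)$m)

  # trial-level accounting: events + non-events + missing = randomized
  tb <- as_tibble(net)
  sums <- tb |>
    dplyr::group_by(trial_id) |>
    dplyr::summarise(lhs = sum(r_obs + (n - m - r_obs) + m), rhs = sum(n))
  expect_equal(sums$lhs, sums$rhs)

  # CSV and TSV round-trips are bit-exact
  for (ext in c("csv", "tsv")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_network(net, path)
    back <- read_network(path, reference = "P")
    expect_equal(as_tibble(back)[, names(dat)], as_tibble(net)[, names(dat)])
  }

  js <- jsonlite::fromJSON(network_summary(net))
  expect_equal(js$n_trials, 8)
  expect_equal(js$n_interventions, 3)
  expect_equal(nrow(js$edges), 3)
})

test_that("boundary counts are accepted and invariant violations rejected", {
  ok <- tibble::tibble(trial_id = c("t", "t"), intervention = c("A", "B"),
                       n = c(10L, 10L), r_obs = c(10L, 0L), m = c(0L, 10L))
  expect_s3_class(nma_network(ok), "nma_network")

  bad <- ok; bad$r_obs[2] <- 1L   # r_obs + m > n
  expect_error(nma_network(bad), class = "misnma_validation_error")

  nocol <- ok[, -3]
  expect_error(nma_network(nocol), class = "misnma_format_error")

  onearm <- tibble::tibble(trial_id = c("t", "u", "u"),
                           intervention = c("A", "A", "B"),
                           n = 10L, r_obs = 1L, m = 0L)
  expect_error(nma_network(onearm), class = "misnma_validation_error")

  disconnected <- tibble::tibble(
    trial_id = rep(c("t", "u"), each = 2),
    intervention = c("A", "B", "C", "D"), n = 10L, r_obs = 1L, m = 0L)
  expect_error(nma_network(disconnected), class = "misnma_connectivity_error")
})

test_that("reference defaults to the most-connected intervention", {
  # star around B: B appears in every trial
  star <- tibble::tibble(
    trial_id = rep(c("t", "u", "v"), each = 2),
    intervention = c("A", "B", "B", "C", "B", "D"),
    n = 10L, r_obs = 2L, m = 1L)
  expect_equal(nma_network(star)$reference, "B")
})

test_that("comparison graph finds edges and loops", {
  net <- triangle_net()
  g <- comparison_graph(net)
  expect_equal(nrow(g$edges), 3)
  expect_length(g$loops, 1)
  expect_setequal(g$loops[[1]], c("N", "O", "P"))

  # chain A-B, B-C: two edges, no loop
  chain <- nma_network(tibble::tibble(
    trial_id = rep(c("t", "u"), each = 2),
    intervention = c("A", "B", "B", "C"), n = 10L, r_obs = 2L, m = 0L))
  gc <- comparison_graph(chain)
  expect_equal(nrow(gc$edges), 2)
  expect_length(gc$loops, 0)

  # star network: no loops
  star <- nma_network(tibble::tibble(
    trial_id = rep(c("t", "u", "v"), each = 2),
    intervention = c("A", "B", "A", "C", "A", "D"),
    n = 10L, r_obs = 2L, m = 0L))
  expect_length(comparison_graph(star)$loops, 0)
})

test_that("splittable comparisons require direct evidence plus an indirect path", {
  # full triangle: all three pairs splittable (verified by exhaustive check)
  net <- triangle_net()
  sp <- splittable_comparisons(net)
  expect_equal(nrow(sp), 3)

  # every splittable pair lies on a loop
  g <- comparison_graph(net)
  on_loop <- purrr::map2_lgl(sp$from, sp$to, function(f, t) {
    any(purrr::map_lgl(g$loops, function(l) all(c(f, t) %in% l)))
  })
  expect_true(all(on_loop))

  # chain: direct evidence but no indirect path -> nothing splittable
  chain <- nma_network(tibble::tibble(
    trial_id = rep(c("t", "u"), each = 2),
    intervention = c("A", "B", "B", "C"), n = 10L, r_obs = 2L, m = 0L))
  expect_equal(nrow(splittable_comparisons(chain)), 0)
})

test_that("baseline override rotates the chosen arm to position 1", {
  dat <- triangle_data()
  net <- nma_network(dat, reference = "P", baseline = c(NP_1 = "N"))
  arm1 <- as_tibble(net) |> dplyr::filter(trial_id == "NP_1", k == 1)
  expect_equal(arm1$intervention, "N")
  # counts untouched, only order changed
  expect_equal(sort(as_tibble(net)$r_obs), sort(dat$r_obs))
})
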