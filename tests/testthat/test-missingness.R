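test_that("pattern-mixture link matches its defining identity and the oracle", {
  # frozen spot checks
  expect_equal(pm_observed_risk(0.3, 0, 0.7), 0.3)          # no missing
  expect_equal(pm_observed_risk(0.3, 0.2, 0), 0.3)          # MAR
  expect_equal(pm_observed_risk(0.5, 0.2, log(2)),
               0.4660520, tolerance = 1e-6)                 # root of 0.8x^2+0.7x-0.5
  expect_equal(pm_missing_risk(0.5, log(2)), 2 / 3)
  expect_equal(pm_missing_risk(0.3, 0), 0.3)

  set.seed(101)
  p <- runif(10000, 0.01, 0.99)
  q <- runif(10000, 0, 0.95)
  phi <- rnorm(10000, 0, 1.5)
  expect_lt(max(abs(pm_observed_risk(p, q, phi) -
                      oracle_pm_observed_risk(p, q, phi))), 1e-10)

  # conservation: p_obs and p_mis reconstruct p through the mixture
  po <- pm_observed_risk(p, q, phi)
  pm <- pm_missing_risk(po, phi)
  expect_lt(max(abs(po * (1 - q) + pm * q - p)), 1e-10)

  # monotonicity: completer risk strictly decreasing in phi when q > 0
  grid_phi <- seq(-3, 3, by = 0.25)
  po_grid <- pm_observed_risk(0.4, 0.3, grid_phi)
  expect_true(all(diff(po_grid) < 0))

  expect_error(pm_observed_risk(0.5, 1, 0), class = "misnma_domain_error")
  expect_error(pm_observed_risk(1, 0.1, 0), class = "misnma_domain_error")
  expect_error(pm_missing_risk(1, 0), class = "misnma_domain_error")
})

test_that("selection cells solve the missingness identity and normalise", {
  mar <- selection_cells(0.5, 0.2, 0)
  expect_equal(mar$c0, 0.2)
  expect_equal(mar$c1, 0.2)
  expect_equal(c(mar$p1, mar$p2, mar$p3), c(0.4, 0.4, 0.2))

  none <- selection_cells(0.3, 0, 1)
  expect_equal(none$c0, 0)
  expect_equal(none$c1, 0)
  expect_equal(none$p3, 0)

  sp <- selection_cells(0.5, 0.2, log(2))   # root of c0^2 + 2.6 c0 - 0.4
  expect_equal(sp$c0, 0.1456832, tolerance = 1e-6)
  expect_equal(sp$c1, 0.2543168, tolerance = 1e-6)

  set.seed(202)
  p <- runif(10000, 0.01, 0.99)
  q <- runif(10000, 0, 0.95)
  phi <- rnorm(10000, 0, 1.5)
  cells <- selection_cells(p, q, phi)
  expect_lt(max(abs(cells$c0 - oracle_selection_c0(p, q, phi))), 1e-10)
  expect_lt(max(abs(cells$p1 + cells$p2 + cells$p3 - 1)), 1e-12)
  expect_equal(cells$p3, q)

  # monotonicity: missingness among events increasing in phi
  c1_grid <- selection_cells(0.4, 0.3, seq(-3, 3, by = 0.25))$c1
  expect_true(all(diff(c1_grid) > 0))
})

test_that("pattern-mixture and selection factorizations share the joint table", {
  set.seed(303)
  p <- runif(100, 0.02, 0.98)
  q <- runif(100, 0, 0.9)
  phi <- rnorm(100, 0, 1.5)
  a <- joint_cells_pm(p, q, phi)
  b <- joint_cells_selection(p, q, phi)
  expect_lt(max(abs(as.matrix(a) - as.matrix(b))), 1e-10)
  expect_lt(max(abs(rowSums(as.matrix(a)) - 1)), 1e-12)

  # MAR limit: outcome independent of missingness
  mar <- joint_cells_pm(0.35, 0.25, 0)
  expect_equal(mar$event_mis, 0.35 * 0.25)
  expect_equal(mar$event_obs, 0.35 * 0.75)

  # no missingness: missing column empty
  dry <- joint_cells_pm(0.35, 0, 1.2)
  expect_equal(dry$event_mis, 0)
  expect_equal(dry$nonevent_mis, 0)
})

test_that("phi parameter counts follow structure and scope", {
  net <- triangle_net()
  n_arms <- nrow(as_tibble(net))
  cases <- list(
    list(imor_prior("identical", "intervention"), 3L, 0L),
    list(imor_prior("identical", "trial"), 8L, 0L),
    list(imor_prior("identical", "network"), 1L, 0L),
    list(imor_prior("hierarchical", "intervention"), n_arms, 3L),
    list(imor_prior("hierarchical", "trial"), n_arms, 8L),
    list(imor_prior("hierarchical", "network"), n_arms, 1L)
  )
  for (cs in cases) {
    map <- phi_index_map(net, cs[[1]])
    expect_equal(attr(map, "n_phi"), cs[[2]])
    expect_equal(attr(map, "n_hyper"), cs[[3]])
    expect_equal(nrow(map), n_arms)
    # arms sharing a group share a phi id under the identical structure
    if (cs[[1]]$structure == "identical" && cs[[1]]$scope == "intervention") {
      byint <- split(map$phi_id, map$intervention)
      expect_true(all(purrr::map_int(byint, dplyr::n_distinct) == 1))
    }
  }
})

test_that("model specifications validate and round-trip through config files", {
  expect_error(imor_prior(sd2 = 0), class = "misnma_config_error")
  expect_error(model_spec(tau_prior_scale = -1), class = "misnma_config_error")

  spec <- model_spec("selection", imor_prior("hierarchical", "trial", sd2 = 2),
                     tau_prior_scale = 0.5)
  for (ext in c(".json", ".yaml")) {
    path <- withr::local_tempfile(fileext = ext)
    spec_to_config(spec, path)
    back <- spec_from_config(path)
    expect_equal(back$missingness, "selection")
    expect_equal(back$imor_prior$structure, "hierarchical")
    expect_equal(back$imor_prior$scope, "trial")
    expect_equal(back$imor_prior$sd2, 2)
    expect_equal(back$tau_prior_scale, 0.5)
  }
})
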