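test_that("site simulator is reproducible and respects the window", {
  w <- square_window(100)
  s1 <- simulate_sites(w, kappa = 5e-4, mu = 30, sigma_km = 3, seed = 11)
  s2 <- simulate_sites(w, kappa = 5e-4, mu = 30, sigma_km = 3, seed = 11)
  expect_identical(s1$sites, s2$sites)

  s3 <- simulate_sites(w, kappa = 5e-4, mu = 30, sigma_km = 3, seed = 12)
  expect_false(identical(s1$sites, s3$sites))

  expect_true(all(points_in_polygon(s1$sites$x, s1$sites$y, w)))

  empty <- simulate_sites(w, kappa = 0, mu = 10, background = 0, seed = 1)
  expect_equal(nrow(empty$sites), 0)

  degenerate <- rect_window(0, 0, 0, 0)
  expect_error(simulate_sites(degenerate, kappa = 1, mu = 1, seed = 1), "area")
})

test_that("cluster process matches its Poisson expectation", {
  # kappa * area * mu = 2e-4 * 1e4 * 100 = 200 expected offspring; sigma is
  # small relative to the window so edge losses are negligible
  w <- square_window(100)
  counts <- vapply(1:100, function(s) {
    nrow(simulate_sites(w, kappa = 2e-4, mu = 100, sigma_km = 1,
                        seed = 42 + s)$sites)
  }, numeric(1))
  expect_lt(abs(mean(counts) - 200), 3 * sqrt(200))
})

test_that("attribution flags follow the configured mix", {
  w <- square_window(100)
  sim <- simulate_sites(w, background = 0.05, seed = 3,
                        phase_mix = c(GI1DA = 1, GS1 = 0, FP_GENERIC = 0,
                                      FP_PB_GENERIC = 0, GS1_PB = 0))
  expect_true(all(sim$sites$attributions == "GI1DA"))
  expect_error(
    simulate_sites(w, background = 0.01, seed = 3,
                   phase_mix = c(GI1DA = 0.5, GS1 = 0.2, FP_GENERIC = 0,
                                 FP_PB_GENERIC = 0, GS1_PB = 0)),
    "sum to 1"
  )
})

test_that("raw-material simulator is reproducible and exercises the filters", {
  w <- square_window(100)
  sim <- simulate_sites(w, background = 0.01, seed = 5)

  r1 <- simulate_raw_materials(sim$sites, seed = 9)
  r2 <- simulate_raw_materials(sim$sites, seed = 9)
  expect_identical(r1, r2)

  # one source per assemblage forces single-distance catchments downstream
  one <- simulate_raw_materials(sim$sites, n_sources = c(1L, 1L),
                                sub_share_frac = 0, seed = 2)
  rmcas <- apply_rmca_filters(build_rmcas(sim$sites, one))
  expect_true(all(rmcas$status == "excluded_single_distance"))

  # shares within an assemblage account for the full composition
  tot <- tapply(r1$share_percent, r1$assemblage_id, sum)
  expect_true(all(abs(tot - 100) < 1e-9))
})

test_that("forced trace materials appear at the configured rate", {
  w <- square_window(200)
  sim <- simulate_sites(w, background = 0.025, seed = 21)  # ~1000 assemblages
  expect_gt(nrow(sim$sites), 900)
  # concentration 5 keeps spontaneous sub-1% shares negligible (the marginal
  # share is Beta(5, (k-1)*5); P(< 1%) ~ 1e-7), so the observed rate isolates
  # the forced traces
  rm_tbl <- simulate_raw_materials(sim$sites, n_sources = c(2L, 5L),
                                   concentration = 5,
                                   sub_share_frac = 0.10, seed = 22)
  frac <- mean(tapply(rm_tbl$share_percent, rm_tbl$assemblage_id,
                      function(s) any(s < 1)))
  expect_lt(abs(frac - 0.10), 0.03)
})
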