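test_that("share filter drops trace materials and single pieces", {
  rec <- tibble::tibble(
    assemblage_id = "a1",
    source_x = 1:4 * km, source_y = 0,
    share_percent = c(55, 30, 14.5, 0.5),
    single_piece = FALSE
  )
  fs <- filter_shares(rec)
  expect_equal(nrow(fs$kept), 3)
  expect_equal(fs$excluded$share_percent, 0.5)
  expect_equal(fs$excluded$reason, "share_below_min")

  rec2 <- rec
  rec2$share_percent <- c(55, 30, 14, 1)  # all at or above 1%
  expect_equal(nrow(filter_shares(rec2)$kept), 4)

  rec3 <- rec2
  rec3$single_piece[2] <- TRUE
  fs3 <- filter_shares(rec3)
  expect_equal(fs3$excluded$reason, "single_piece")

  empty <- rec[0, ]
  expect_equal(nrow(filter_shares(empty)$kept), 0)
})

test_that("a source-free catchment is the 5 km buffer disc", {
  r <- build_rmca(0, 0, NULL)
  expect_lt(abs(r$area_km2 - pi * 25) / (pi * 25), 0.001)
  expect_equal(r$n_distinct_distances, 0)

  # sources inside the buffer do not enlarge it
  inside <- tibble::tibble(source_x = 2 * km, source_y = 1 * km)
  r2 <- build_rmca(0, 0, inside)
  expect_equal(r2$area_km2, r$area_km2, tolerance = 1e-6)
  expect_equal(r2$n_distinct_distances, 1)
})

test_that("hull area matches an independent shoelace oracle", {
  src <- tibble::tibble(source_x = c(60, 0) * km, source_y = c(0, 80) * km)
  r <- build_rmca(0, 0, src)
  # oracle: shoelace over the hull of a densely discretised buffer circle
  # and the exact source points, computed with test-local code
  circ <- cbind(5 * km * cos(seq(0, 2 * pi, length.out = 3601)[-3601]),
                5 * km * sin(seq(0, 2 * pi, length.out = 3601)[-3601]))
  pts <- rbind(circ, as.matrix(src))
  hull <- pts[grDevices::chull(pts[, 1], pts[, 2]), ]
  oracle_km2 <- shoelace(hull) / 1e6
  expect_lt(abs(r$area_km2 - oracle_km2) / oracle_km2, 0.005)
})

test_that("distinct distances are counted at 1 m resolution", {
  eq <- tibble::tibble(source_x = c(100, 0) * km, source_y = c(0, 100) * km)
  expect_equal(build_rmca(0, 0, eq)$n_distinct_distances, 1)

  near <- tibble::tibble(source_x = c(100 * km, 100 * km + 0.4), source_y = 0)
  expect_equal(build_rmca(0, 0, near)$n_distinct_distances, 1)

  apart <- tibble::tibble(source_x = c(100 * km, 100 * km + 2000), source_y = 0)
  expect_equal(build_rmca(0, 0, apart)$n_distinct_distances, 2)
})

test_that("hull area is monotone in the source set", {
  set.seed(31)
  src <- tibble::tibble(source_x = runif(8, -80, 80) * km,
                        source_y = runif(8, -80, 80) * km)
  full <- build_rmca(0, 0, src)$area_km2
  for (i in 1:8) {
    less <- build_rmca(0, 0, src[-i, ])$area_km2
    expect_lte(less, full + 1e-9)
  }
})

test_that("exclusion filters partition catchments with correct precedence", {
  rmcas <- tibble::tibble(
    assemblage_id = paste0("a", 1:5),
    area_km2 = c(78, 499, 500, 2000, 10000),
    n_sources = c(0, 3, 1, 4, 2),
    n_distinct_distances = c(0, 3, 1, 4, 2),
    hull = vector("list", 5)
  )
  out <- apply_rmca_filters(rmcas)
  expect_equal(as.character(out$status),
               c("excluded_single_distance", "excluded_small",
                 "excluded_single_distance", "kept", "kept"))
  expect_equal(out$assemblage_id[out$status == "kept"], c("a4", "a5"))
  # conservation: every catchment lands in exactly one class
  expect_equal(sum(table(out$status)), nrow(rmcas))

  all_ok <- rmcas[4:5, ]
  expect_true(all(apply_rmca_filters(all_ok)$status == "kept"))
  expect_equal(nrow(apply_rmca_filters(rmcas[0, ])), 0)
})

test_that("regional quartiles interpolate and transfer across blocks", {
  rmcas <- tibble::tibble(
    assemblage_id = paste0("a", 1:5),
    area_km2 = c(10, 20, 30, 40, 50) * 1000,
    status = factor("kept"),
    block = "north"
  )
  q <- regional_quartiles(rmcas, transfer_map = list(north = c("r1", "r2")))
  expect_equal(nrow(q), 2)  # both regions share the block quartiles
  expect_equal(unique(q$q1), 20000)
  expect_equal(unique(q$q2), 30000)
  expect_equal(unique(q$q3), 40000)
  expect_equal(unique(q$n_raw), 5)

  single <- rmcas[3, ]
  q1 <- regional_quartiles(single, transfer_map = list(north = "r1"))
  expect_equal(c(q1$q1, q1$q2, q1$q3), rep(30000, 3))

  expect_error(
    regional_quartiles(rmcas, transfer_map = list(south = "r9")),
    "south"
  )
})

test_that("raw-material records resolve to phases by attribution", {
  rec <- tibble::tibble(
    assemblage_id = c("a1", "a2", "a3", "a4"),
    share_percent = 100,
    attributions = c("GI1DA", "GS1", "GI1DA;GS1", "FP_GENERIC")
  )
  gi <- select_raw_materials(rec, "GI1DA")
  gs <- select_raw_materials(rec, "GS1")
  expect_equal(gi$assemblage_id, c("a1", "a3"))
  expect_equal(gs$assemblage_id, c("a2", "a3"))
  # generically attributed assemblages feed no phase-specific quartile
  expect_false("a4" %in% c(gi$assemblage_id, gs$assemblage_id))
})
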