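# build a lec_grid directly from a function of the cell centres
field_grid <- function(side_km, cell_km, f) {
  w <- square_window(side_km)
  gx <- seq(cell_km * km / 2, side_km * km, by = cell_km * km)
  z <- outer(gx, gx, f)
  structure(list(x = gx, y = gx, z = z, cell_km = cell_km, window = w),
            class = "lec_grid")
}

test_that("constant field switches from zero to full window area", {
  g <- field_grid(50, 5, function(x, y) 0 * x + 7)
  cv <- extract_isopleths(g, levels = c(1, 6.99, 7, 10))
  expect_equal(cv$area_km2[1:2], c(0, 0))
  expect_equal(cv$area_km2[3:4], c(2500, 2500))
})

test_that("radial field recovers the analytic disc area", {
  # f = distance (km) from the window centre; the level-L region is a disc
  g <- field_grid(100, 0.5, function(x, y)
    sqrt((x - 50 * km)^2 + (y - 50 * km)^2) / km)
  cv <- extract_isopleths(g, levels = c(10, 20, 30, 40))
  for (i in 1:4) {
    expect_lt(abs(cv$area_km2[i] - pi * cv$level_km[i]^2) /
                (pi * cv$level_km[i]^2), 0.02)
  }
})

test_that("areas, captures and level sets are nested in the level", {
  for (seed in c(1, 2, 3)) {
    set.seed(seed)
    g <- field_grid(60, 2, function(x, y) 0 * x)
    g$z[] <- runif(length(g$z), 0, 12)
    sites <- tibble::tibble(x = runif(40, 0, 60 * km), y = runif(40, 0, 60 * km))
    lv <- seq(1, 12, by = 1)
    cv <- extract_isopleths(g, lv, sites = sites)
    expect_true(all(diff(cv$area_km2) >= 0))
    expect_true(all(diff(cv$capture) >= 0))
    expect_true(all(cv$capture >= 0 & cv$capture <= 1))
    m_prev <- colognepop:::level_mask(g, lv[1])
    for (L in lv[-1]) {
      m <- colognepop:::level_mask(g, L)
      expect_true(all(m[m_prev]))  # set inclusion
      m_prev <- m
    }
  }
})

test_that("contour polygons measure the same region as the cell count", {
  g <- field_grid(100, 1, function(x, y)
    sqrt((x - 50 * km)^2 + (y - 50 * km)^2) / km)
  polys <- isopleth_polygons(g, 25)
  expect_gt(length(polys), 0)
  poly_area <- sum(vapply(polys, shoelace, numeric(1))) / 1e6
  cell_area <- extract_isopleths(g, 25)$area_km2
  expect_lt(abs(poly_area - cell_area) / cell_area, 0.05)
})

test_that("halving the cell size changes a smooth-field area by under 5%", {
  f <- function(x, y) sqrt((x - 50 * km)^2 + (y - 50 * km)^2) / km
  a2 <- extract_isopleths(field_grid(100, 2, f), 30)$area_km2
  a1 <- extract_isopleths(field_grid(100, 1, f), 30)$area_km2
  expect_lt(abs(a1 - a2) / a2, 0.05)
})

test_that("mask utilities agree on simple geometries", {
  g <- field_grid(40, 2, function(x, y) 0 * x)
  disc <- colognepop:::disc_polygon(20 * km, 20 * km, 10 * km)
  m <- polygons_mask(g, list(disc))
  expect_lt(abs(sum(m) * 4 - pi * 100) / (pi * 100), 0.05)
  expect_equal(jaccard_masks(m, m), 1)
  expect_equal(jaccard_masks(m, !m), 0)
})
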