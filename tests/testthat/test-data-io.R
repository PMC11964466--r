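test_that("read_sites validates records and reports rejections", {
  w <- square_window(100)
  good <- data.frame(
    id = c("s1", "s2", "s3"),
    x = c(10, 50, 90) * km, y = c(10, 50, 90) * km,
    region = "r", attributions = c("GI1DA", "GS1", "GI1DA;GS1"),
    evidence = "excavation"
  )
  tbl <- read_sites(write_site_csv(good), window = w)
  expect_equal(nrow(tbl), 3)
  expect_equal(nrow(attr(tbl, "rejected")), 0)

  bad_coord <- good
  bad_coord$x[2] <- "NA"
  expect_error(read_sites(write_site_csv(bad_coord), window = w), "s2")

  outside <- good
  outside$x[3] <- 500 * km
  tbl2 <- read_sites(write_site_csv(outside), window = w)
  expect_equal(nrow(tbl2), 2)
  rej <- attr(tbl2, "rejected")
  expect_equal(rej$id, "s3")
  expect_match(rej$reason, "outside")

  expect_error(read_sites(write_site_csv(good[, -1])), "id")

  dup <- good
  dup$x <- dup$x[1]; dup$y <- dup$y[1]
  tbl3 <- read_sites(write_site_csv(dup), window = w)
  expect_equal(sum(tbl3$dup_coord), 2)
})

test_that("dataset selection follows the phase/attribution rules", {
  sites <- census_sites()
  expect_equal(nrow(select_dataset(sites, "GI1DA", "A")), 1356)
  expect_equal(nrow(select_dataset(sites, "GS1", "A")), 1003)
  expect_equal(nrow(select_dataset(sites, "GI1DA", "B")), 988)
  expect_equal(nrow(select_dataset(sites, "GS1", "B")), 560)

  # B never selects more than A, for both phases
  for (ph in c("GI1DA", "GS1")) {
    expect_lte(nrow(select_dataset(sites, ph, "B")),
               nrow(select_dataset(sites, ph, "A")))
  }

  # a record attributed to both phases appears in both B selections
  both <- tibble::tibble(id = "b1", x = 1, y = 1, region = "r",
                         attributions = "GI1DA;GS1", evidence = "surface")
  expect_equal(nrow(select_dataset(both, "GI1DA", "B")), 1)
  expect_equal(nrow(select_dataset(both, "GS1", "B")), 1)

  empty <- sites[0, ]
  expect_equal(nrow(select_dataset(empty, "GI1DA", "A")), 0)
})

test_that("attribution census reports assemblage and site tallies", {
  sites <- tibble::tibble(
    id = c("a", "b", "c"),
    x = c(1, 1, 2), y = c(1, 1, 2), region = "r",
    attributions = c("GI1DA", "GI1DA", "GS1"), evidence = "excavation"
  )
  cen <- attribution_census(sites)
  expect_equal(cen$n_assemblages[cen$flag == "GI1DA"], 2)
  expect_equal(cen$n_sites[cen$flag == "GI1DA"], 1)  # shared coordinates
})

test_that("GeoJSON writer and reader round-trip geometries", {
  path <- tempfile(fileext = ".geojson")

  set.seed(99)
  pts <- lapply(1:10, function(i) runif(2, 0, 1e6))
  names(pts) <- paste0("p", 1:10)
  write_geojson(pts, path)
  back <- read_geojson(path)
  for (i in 1:10) expect_equal(back[[i]], pts[[i]], tolerance = 1e-9)

  sq <- rect_window(0, 1000, 0, 1000)
  write_geojson(list(sq = sq), path)
  back2 <- read_geojson(path)
  expect_equal(length(back2), 1)
  expect_equal(polygon_area(back2$sq), polygon_area(sq))

  write_geojson(list(), path)
  expect_equal(length(read_geojson(path)), 0)

  bad <- rect_window(0, 1, 0, 1); bad[1, 1] <- NA
  expect_error(write_geojson(list(b = bad), path), "b")
})
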