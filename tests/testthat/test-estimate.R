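test_that("single-region arithmetic matches the published convention", {
  gb <- estimate_region("Great Britain", 51900, 2670, 5117, 5896, 17)
  expect_equal(round_half_up(gb$n_groups_q2, 1), 10.1)
  expect_equal(round_half_up(gb$n_people_q2), 431)
  expect_equal(round_half_up(gb$density_q2, 3), 0.008)

  cz <- estimate_region("Czech Rep. & SE Germany", 115900, 1057, 1948, 2626, 10)
  expect_equal(round_half_up(cz$n_groups_q2, 1), 59.5)
  expect_equal(round_half_up(cz$n_people_q2), 2529)
  expect_equal(round_half_up(cz$density_q2, 3), 0.022)

  # odi = 2q gives exactly two groups of 42.5 people
  r <- estimate_region("toy", 2000, 1000, 1000, 1000)
  expect_equal(r$n_groups_q2, 2)
  expect_equal(r$n_people_q2, 85)
  expect_equal(r$density_q2, 42.5 / 1000)

  expect_error(estimate_region("bad", 100, 0, 1, 2), "positive")
})

test_that("estimates scale with area and decrease in the quartile", {
  a <- estimate_region("a", 30000, 1500, 3000, 6000)
  b <- estimate_region("b", 60000, 1500, 3000, 6000)
  expect_equal(b$n_groups_q2, 2 * a$n_groups_q2)
  expect_equal(b$n_people_q2, 2 * a$n_people_q2)
  expect_equal(b$density_q2, a$density_q2)

  # people strictly decreasing in the dividing quartile
  expect_true(a$n_people_q1 > a$n_people_q2)
  expect_true(a$n_people_q2 > a$n_people_q3)
})

test_that("quartile bracketing holds for every published region", {
  for (tb in 1:2) {
    est <- estimate_table(published_inputs(tb))
    d <- format_estimate_table(est)
    reg <- d[!d$region %in% c("Sum Core Area", "Total Area of Calculation"), ]
    wide <- tidyr::pivot_wider(reg[, c("region", "q", "n_people")],
                               names_from = "q", values_from = "n_people")
    expect_true(all(wide$`3` <= wide$`2` & wide$`2` <= wide$`1`))
  }
})

test_that("totals come from unrounded rows, not from rounded cells", {
  est <- estimate_table(published_inputs(1))
  d <- format_estimate_table(est)
  reg <- d[!d$region %in% c("Sum Core Area", "Total Area of Calculation"), ]
  sum_cells <- sum(reg$n_people[reg$q == 2])
  total <- d$n_people[d$region == "Sum Core Area" & d$q == 2]
  expect_equal(total, 8126)
  expect_equal(sum_cells, 8128)  # the rounded-cell sum differs
  expect_lte(abs(sum_cells - total), 12)  # by at most one per region
})

test_that("phase comparison reports ratios and rejects region mismatches", {
  t1 <- estimate_table(published_inputs(1))
  same <- compare_phases(t1, t1)
  expect_equal(same$people_ratio, 1)
  expect_equal(same$area_change_pct, 0)
  expect_true(all(same$by_region$people_change_pct == 0))

  other <- published_inputs(2)
  other$region[1] <- "Atlantis"
  t2 <- estimate_table(other)
  expect_error(compare_phases(t1, t2), "Atlantis")
})

test_that("perturbing one input flags exactly that region's cells", {
  inputs <- published_inputs(1)
  inputs$odi_km2[inputs$region == "Italy"] <- 20050  # + 5000 km2
  rep <- reproduce_tables(1, inputs = inputs)
  bad_regions <- unique(rep$diff$region[!rep$diff$quantized])
  expect_true("Italy" %in% bad_regions)
  expect_true(all(bad_regions %in%
                    c("Italy", "Sum Core Area", "Total Area of Calculation")))
})

test_that("tidy, glance and autoplot views work on estimate tables", {
  est <- estimate_table(published_inputs(1), phase = "GI1DA", dataset = "A")
  td <- tidy(est)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 12 * 3 + 6)
  gl <- glance(est)
  expect_equal(gl$n_people_q2, 8126)
  expect_equal(gl$density_tac_q2, 0.003)
  expect_s3_class(ggplot2::autoplot(est), "ggplot")
})
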