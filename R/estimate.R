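## Demographic estimation: ODI areas / RMCA quartiles -> groups, people,
## densities.  All derived quantities are kept unrounded internally; display
## rounding follows the published convention exactly: groups to 1 decimal,
## people to the nearest integer of unrounded groups x group size, densities
## to 3 decimals of unrounded people / area, totals from unrounded row values
## (so the rounded total can differ from the sum of rounded cells), ties
## rounded half-up.

#' Round half-up (ties away from the next lower value)
#' @param x numeric.
#' @param digits decimal places.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Demographic estimate for one region
#'
#' Divides the region's optimally-describing-isoline area by each catchment
#' quartile to obtain group counts, multiplies by the ethnographic group size
#' for people, and divides people by the area for the within-Core-Area
#' density.  Q1 (small catchments) gives the maximum estimate, Q3 the
#' minimum, Q2 the mean estimate used for comparisons.
#'
#' @param region region name.
#' @param odi_km2 Core Area (ODI) size in km^2.
#' @param q1,q2,q3 catchment quartiles in km^2 (all > 0).
#' @param n_raw number of catchments behind the quartiles (carried through).
#' @param group_size persons per group (default 42.5).
#' @return one-row tibble with unrounded columns `n_groups_q*, n_people_q*,
#'   density_q*` plus the inputs.
#' @export
estimate_region <- function(region, odi_km2, q1, q2, q3, n_raw = NA_integer_,
                            group_size = CP_GROUP_SIZE) {
  qs <- c(q1, q2, q3)
  if (any(!is.finite(qs)) || any(qs <= 0)) {
    stop("quartiles must be positive for region ", region, call. = FALSE)
  }
  stopifnot(odi_km2 >= 0, group_size > 0)
  g <- odi_km2 / qs
  p <- g * group_size
  d <- if (odi_km2 > 0) p / odi_km2 else rep(0, 3)
  tibble::tibble(
    region = region, odi_km2 = odi_km2,
    q1 = q1, q2 = q2, q3 = q3, n_raw = n_raw,
    n_groups_q1 = g[1], n_groups_q2 = g[2], n_groups_q3 = g[3],
    n_people_q1 = p[1], n_people_q2 = p[2], n_people_q3 = p[3],
    density_q1 = d[1], density_q2 = d[2], density_q3 = d[3]
  )
}

#' Assemble regional rows into an estimate table
#'
#' @param rows tibble of rows from [estimate_region()] (or a data frame with
#'   columns `region, odi_km2, q1, q2, q3[, n_raw]`, which is converted).
#' @param tac_area_km2 Total Area of Calculation in km^2 (default 2.6e6).
#' @param group_size persons per group (used when `rows` needs converting).
#' @param phase,dataset metadata labels carried on the result.
#' @return object of class `cologne_estimate`: list with `rows` (unrounded),
#'   `totals` (per-quartile unrounded totals, Core-Area density and
#'   Total-Area-of-Calculation density), and metadata.
#' @export
estimate_table <- function(rows, tac_area_km2 = CP_TAC_AREA_KM2,
                           group_size = CP_GROUP_SIZE,
                           phase = NA_character_, dataset = NA_character_) {
  stopifnot(nrow(rows) >= 1)
  if (!"n_people_q2" %in% names(rows)) {
    blocks <- if ("block" %in% names(rows)) rows$block
    rows <- purrr::pmap_dfr(
      rows[, c("region", "odi_km2", "q1", "q2", "q3",
               intersect("n_raw", names(rows)))],
      estimate_region, group_size = group_size
    )
    if (!is.null(blocks)) rows$block <- blocks
  }
  total_area <- sum(rows$odi_km2)
  totals <- purrr::map_dfr(c("q1", "q2", "q3"), function(q) {
    p <- sum(rows[[paste0("n_people_", q)]])
    tibble::tibble(
      quartile = toupper(q),
      n_groups = sum(rows[[paste0("n_groups_", q)]]),
      n_people = p,
      density_core = p / total_area,
      density_tac = p / tac_area_km2
    )
  })
  structure(
    list(rows = rows, totals = totals, total_area_km2 = total_area,
         tac_area_km2 = tac_area_km2, group_size = group_size,
         phase = phase, dataset = dataset),
    class = "cologne_estimate"
  )
}

#' @export
print.cologne_estimate <- function(x, ...) {
  cat("<cologne_estimate>",
      if (!is.na(x$phase)) paste0(" phase ", x$phase),
      if (!is.na(x$dataset)) paste0(" dataset ", x$dataset),
      ": ", nrow(x$rows), " regions, total Core Area ",
      format(round(x$total_area_km2)), " km^2\n", sep = "")
  print(format_estimate_table(x), n = Inf)
  invisible(x)
}

#' Published-style rounded view of an estimate table
#'
#' One row per region and quartile with the published rounding (groups 1
#' decimal, people integer, density 3 decimals), followed by the sum rows and
#' the Total-Area-of-Calculation densities computed from unrounded totals.
#'
#' @param x `cologne_estimate`.
#' @return tibble with `region, q, odi_km2, rmca_km2, n_raw, n_groups,
#'   n_people, d_population`.
#' @export
format_estimate_table <- function(x) {
  per_q <- purrr::map_dfr(1:3, function(k) {
    qv <- paste0("q", k)
    rmca <- x$rows[[qv]]
    grp <- round_half_up(x$rows[[paste0("n_groups_", qv)]], 1)
    ppl <- round_half_up(x$rows[[paste0("n_people_", qv)]])
    dens <- round_half_up(x$rows[[paste0("density_", qv)]], 3)
    tibble::tibble(
      region = x$rows$region,
      q = k,
      odi_km2 = x$rows$odi_km2,
      rmca_km2 = rmca,
      n_raw = x$rows$n_raw,
      n_groups = grp,
      n_people = ppl,
      d_population = dens
    )
  })
  per_q <- dplyr::arrange(per_q, match(.data$region, x$rows$region), .data$q)
  ## catchment counts are per block; regions sharing a block (quartile
  ## transfer) must not double-count them in the sum row
  n_raw_total <- if ("block" %in% names(x$rows)) {
    sum(x$rows$n_raw[!duplicated(x$rows$block)])
  } else {
    sum(x$rows$n_raw)
  }
  sums <- tibble::tibble(
    region = "Sum Core Area", q = 1:3,
    odi_km2 = x$total_area_km2, rmca_km2 = NA_real_,
    n_raw = n_raw_total,
    n_groups = round_half_up(x$totals$n_groups),
    n_people = round_half_up(x$totals$n_people),
    d_population = round_half_up(x$totals$density_core, 3)
  )
  tac <- tibble::tibble(
    region = "Total Area of Calculation", q = 1:3,
    odi_km2 = x$tac_area_km2, rmca_km2 = NA_real_, n_raw = NA_integer_,
    n_groups = NA_real_, n_people = NA_real_,
    d_population = round_half_up(x$totals$density_tac, 3)
  )
  dplyr::bind_rows(per_q, sums, tac)
}

#' @method tidy cologne_estimate
#' @export
tidy.cologne_estimate <- function(x, ...) format_estimate_table(x)

#' @method glance cologne_estimate
#' @export
glance.cologne_estimate <- function(x, ...) {
  t2 <- x$totals[x$totals$quartile == "Q2", ]
  tibble::tibble(
    phase = x$phase, dataset = x$dataset,
    n_regions = nrow(x$rows),
    total_area_km2 = x$total_area_km2,
    n_people_q2 = round_half_up(t2$n_people),
    n_people_q1 = round_half_up(x$totals$n_people[x$totals$quartile == "Q1"]),
    n_people_q3 = round_half_up(x$totals$n_people[x$totals$quartile == "Q3"]),
    density_core_q2 = round_half_up(t2$density_core, 3),
    density_tac_q2 = round_half_up(t2$density_tac, 3)
  )
}

#' Totals rounded to the nearest hundred
#'
#' Reporting option mirroring prose summaries of the bracketing (Q1/Q3)
#' totals.
#'
#' @param x `cologne_estimate`.
#' @param quartile `"Q1"`, `"Q2"` or `"Q3"`.
#' @return people total rounded to the nearest hundred.
#' @export
people_total_hundreds <- function(x, quartile = "Q2") {
  p <- x$totals$n_people[x$totals$quartile == toupper(quartile)]
  round_half_up(p / 100) * 100
}

#' Compare two phase estimates
#'
#' @param t1,t2 `cologne_estimate` objects over the same regions (t1 the
#'   earlier phase).
#' @param quartile quartile used for the people comparison (default Q2).
#' @return list with `by_region` (tibble of per-region changes), and totals:
#'   `people_ratio` (t2/t1), `people_change_pct`, `area_change_pct`,
#'   `density_per_100km2` for both tables.
#' @export
compare_phases <- function(t1, t2, quartile = "Q2") {
  r1 <- t1$rows; r2 <- t2$rows
  if (!setequal(r1$region, r2$region)) {
    stop("region mismatch: ",
         paste(c(setdiff(r1$region, r2$region), setdiff(r2$region, r1$region)),
               collapse = ", "), call. = FALSE)
  }
  qcol <- paste0("n_people_", tolower(quartile))
  m <- dplyr::inner_join(r1, r2, by = "region", suffix = c("_1", "_2"))
  by_region <- tibble::tibble(
    region = m$region,
    people_1 = m[[paste0(qcol, "_1")]],
    people_2 = m[[paste0(qcol, "_2")]],
    people_change_pct = 100 * (m[[paste0(qcol, "_2")]] / m[[paste0(qcol, "_1")]] - 1),
    area_1 = m$odi_km2_1,
    area_2 = m$odi_km2_2,
    area_change_pct = 100 * (m$odi_km2_2 / m$odi_km2_1 - 1)
  )
  p1 <- t1$totals$n_people[t1$totals$quartile == toupper(quartile)]
  p2 <- t2$totals$n_people[t2$totals$quartile == toupper(quartile)]
  list(
    by_region = by_region,
    people_ratio = p2 / p1,
    people_change_pct = 100 * (p2 / p1 - 1),
    area_change_pct = 100 * (t2$total_area_km2 / t1$total_area_km2 - 1),
    density_per_100km2 = c(t1 = 100 * p1 / t1$total_area_km2,
                           t2 = 100 * p2 / t2$total_area_km2)
  )
}

## ------------------------------------------------------- reproduction -----

#' Packaged inputs of the published estimate tables
#'
#' ODI areas, catchment quartiles and catchment counts per region for both
#' phases (dataset A), as printed.
#'
#' @param table 1 (interstadial GI-1d-a) or 2 (stadial GS-1).
#' @return tibble `region, phase, dataset, odi_km2, q1, q2, q3, n_raw`.
#' @export
published_inputs <- function(table = 1) {
  path <- system.file("extdata", "published_table_inputs.csv",
                      package = "colognepop", mustWork = TRUE)
  tbl <- tibble::as_tibble(utils::read.csv(path))
  tbl[tbl$table == table, setdiff(names(tbl), "table")]
}

#' Packaged expected derived cells of the published tables
#'
#' Every printed derived cell (per-region and sum rows).  Cells whose printed
#' value cannot be obtained from the printed (rounded) quartile inputs --
#' because the original computation divided by unrounded quartiles -- are
#' flagged `quantized`; their printed value differs by one unit in the last
#' printed digit from the value derivable from the printed inputs.
#'
#' @param table 1 or 2.
#' @return tibble `region, q, column, printed, quantized`.
#' @export
published_expected <- function(table = 1) {
  path <- system.file("extdata", "published_table_expected.csv",
                      package = "colognepop", mustWork = TRUE)
  tbl <- tibble::as_tibble(utils::read.csv(path))
  tbl$quantized <- as.logical(tbl$quantized)
  tbl[tbl$table == table, setdiff(names(tbl), "table")]
}

#' Recompute a published table and diff it cell by cell
#'
#' Rebuilds the estimate table from the packaged printed inputs and compares
#' every derived cell (after display rounding) with the packaged printed
#' value.
#'
#' @param table 1 or 2.
#' @param inputs optional replacement input tibble (same layout as
#'   [published_inputs()]), e.g. with a perturbed ODI for sensitivity checks.
#' @return list with `estimate` (`cologne_estimate`), `cells` (tibble of all
#'   compared cells: `region, q, column, printed, computed, match,
#'   quantized`) and `diff` (the mismatching subset).
#' @export
reproduce_tables <- function(table = 1, inputs = NULL) {
  if (is.null(inputs)) inputs <- published_inputs(table)
  est <- estimate_table(inputs,
                        phase = inputs$phase[1], dataset = inputs$dataset[1])
  disp <- format_estimate_table(est)
  exp <- published_expected(table)

  long <- tidyr::pivot_longer(
    disp[, c("region", "q", "n_groups", "n_people", "d_population")],
    c("n_groups", "n_people", "d_population"),
    names_to = "column", values_to = "computed"
  )
  cells <- dplyr::inner_join(exp, long, by = c("region", "q", "column"))
  cells$match <- abs(cells$printed - cells$computed) < 1e-9
  list(estimate = est, cells = cells,
       diff = cells[!cells$match, , drop = FALSE])
}
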