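## Raw-material catchment areas (RMCAs): per-assemblage convex hulls around a
## 5 km site buffer and the assemblage's raw-material sources, the exclusion
## filters, and regional quartiles with adjacency transfer.

#' Filter raw-material records by share percentage
#'
#' Removes records whose share of the assemblage is below `min_share`
#' percent, and records documented by single pieces, before any catchment is
#' built.
#'
#' @param records tibble with `assemblage_id`, `share_percent` and optionally
#'   `single_piece`.
#' @param min_share minimum share in percent (default 1).
#' @return list with `kept`, `excluded` (tibbles; `excluded` has a `reason`
#'   column) and `report` (per-assemblage counts of kept/excluded records).
#' @export
filter_shares <- function(records, min_share = CP_MIN_SHARE) {
  records <- tibble::as_tibble(records)
  single <- if ("single_piece" %in% names(records)) {
    isTRUE_v(records$single_piece)
  } else rep(FALSE, nrow(records))
  low <- records$share_percent < min_share
  reason <- dplyr::case_when(
    single ~ "single_piece",
    low ~ "share_below_min",
    TRUE ~ NA_character_
  )
  kept <- records[is.na(reason), , drop = FALSE]
  excluded <- records[!is.na(reason), , drop = FALSE]
  excluded$reason <- reason[!is.na(reason)]
  report <- dplyr::count(
    dplyr::mutate(records, status = ifelse(is.na(reason), "kept", reason)),
    .data$assemblage_id, .data$status
  )
  list(kept = kept, excluded = excluded, report = report)
}

isTRUE_v <- function(x) !is.na(x) & as.logical(x)

#' Build the raw-material catchment of one assemblage
#'
#' The catchment is the convex hull of a `buffer_km` disc around the site
#' (discretised at 360 vertices) together with the source points.  The number
#' of distinct source-to-site distances is counted at 1 m resolution; it
#' drives the single-distance exclusion filter.
#'
#' @param site_x,site_y site coordinates (metres).
#' @param sources tibble/data.frame with `source_x`, `source_y` (metres); may
#'   have zero rows.
#' @param buffer_km site buffer radius in km (default 5).
#' @return list with `hull` (ring matrix, metres), `area_km2`,
#'   `n_sources` and `n_distinct_distances`.
#' @export
build_rmca <- function(site_x, site_y, sources = NULL, buffer_km = CP_BUFFER_KM) {
  stopifnot(is.finite(site_x), is.finite(site_y))
  buf <- disc_polygon(site_x, site_y, buffer_km * 1000)
  if (is.null(sources) || nrow(sources) == 0) {
    sx <- numeric(0); sy <- numeric(0)
  } else {
    sx <- sources$source_x; sy <- sources$source_y
  }
  d_m <- sqrt((sx - site_x)^2 + (sy - site_y)^2)
  hull <- convex_hull(c(buf[, 1], sx), c(buf[, 2], sy))
  list(
    hull = hull,
    area_km2 = polygon_area(hull) / 1e6,
    n_sources = length(sx),
    n_distinct_distances = length(unique(round(d_m)))
  )
}

#' Build catchments for every assemblage of a raw-material table
#'
#' @param sites tibble with `id`, `x`, `y` (one row per assemblage).
#' @param records kept raw-material records (after [filter_shares()]) with
#'   `assemblage_id`, `source_x`, `source_y`.
#' @param buffer_km site buffer radius in km.
#' @return tibble with one row per assemblage present in `sites`:
#'   `assemblage_id, area_km2, n_sources, n_distinct_distances, hull`
#'   (list-column of ring matrices).
#' @export
build_rmcas <- function(sites, records, buffer_km = CP_BUFFER_KM) {
  purrr::map_dfr(seq_len(nrow(sites)), function(i) {
    src <- records[records$assemblage_id == sites$id[i], , drop = FALSE]
    r <- build_rmca(sites$x[i], sites$y[i], src, buffer_km = buffer_km)
    tibble::tibble(
      assemblage_id = sites$id[i],
      area_km2 = r$area_km2,
      n_sources = r$n_sources,
      n_distinct_distances = r$n_distinct_distances,
      hull = list(r$hull)
    )
  })
}

#' Apply the catchment exclusion filters
#'
#' Assigns each catchment a status: `excluded_single_distance` when it
#' comprises fewer than `min_distinct` distinct source-to-site distances,
#' otherwise `excluded_small` when its area is below `min_area_km2`,
#' otherwise `kept`.  Every input row appears in exactly one class.
#'
#' @param rmcas tibble from [build_rmcas()].
#' @param min_area_km2 minimum catchment area (default 500).
#' @param min_distinct minimum number of distinct distances (default 2).
#' @return the input tibble with a `status` factor column.
#' @export
apply_rmca_filters <- function(rmcas, min_area_km2 = CP_MIN_AREA_KM2,
                               min_distinct = 2) {
  status <- dplyr::case_when(
    rmcas$n_distinct_distances < min_distinct ~ "excluded_single_distance",
    rmcas$area_km2 < min_area_km2 ~ "excluded_small",
    TRUE ~ "kept"
  )
  rmcas$status <- factor(status, levels = c("kept", "excluded_single_distance",
                                            "excluded_small"))
  rmcas
}

#' Regional RMCA quartiles with adjacency transfer
#'
#' Kept catchments are grouped into blocks; each block's quartiles (Q1, Q2,
#' Q3 by sorted-order linear interpolation, R's default quantile type 7) are
#' shared by all estimate regions mapped to that block via the transfer map.
#' The transfer map encodes the protocol's rule that regions with little or
#' no raw-material data borrow quartiles from adjacent areas.
#'
#' @param rmcas filtered tibble (only rows with `status == "kept"` are used)
#'   with a `block` column naming each catchment's block.
#' @param transfer_map named list: block name -> character vector of estimate
#'   regions that use the block's quartiles.
#' @return tibble with one row per estimate region: `region, block, q1, q2,
#'   q3, n_raw`.
#' @export
regional_quartiles <- function(rmcas, transfer_map) {
  if ("status" %in% names(rmcas)) {
    rmcas <- rmcas[rmcas$status == "kept", , drop = FALSE]
  }
  stopifnot("block" %in% names(rmcas))
  purrr::imap_dfr(transfer_map, function(regions, block) {
    a <- rmcas$area_km2[rmcas$block == block]
    if (length(a) < 1) {
      stop("no kept catchments resolve to block '", block,
           "' (regions: ", paste(regions, collapse = ", "), ")", call. = FALSE)
    }
    q <- stats::quantile(a, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    tibble::tibble(region = regions, block = block,
                   q1 = q[1], q2 = q[2], q3 = q[3], n_raw = length(a))
  })
}

#' Phase selection for raw-material records
#'
#' Records from assemblages attributed to both phases (or generically to a
#' larger bin covering both) contribute to both phase-specific quartile
#' pools; records from assemblages only generically attributed contribute to
#' neither.
#'
#' @param records tibble with an `attributions` column.
#' @param phase `"GI1DA"` or `"GS1"`.
#' @return the subset of `records` contributing to the phase.
#' @export
select_raw_materials <- function(records, phase = c("GI1DA", "GS1")) {
  phase <- match.arg(phase)
  flags <- parse_attributions(records$attributions)
  keep <- vapply(flags, function(v) phase %in% v, logical(1))
  records[keep, , drop = FALSE]
}
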