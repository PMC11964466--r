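## End-to-end orchestration: simulate / run / reproduce, each a thin wrapper
## over the module functions, writing plain-text outputs plus a
## machine-readable provenance record sufficient to re-execute the run.
## A command-line wrapper around these functions ships in
## inst/scripts/cologne-protocol.

cp_default_params <- function() {
  list(cell_km = 10, level_step_km = 1, min_capture = CP_MIN_CAPTURE,
       plateau_tol = 0.10, idw_power = 2, buffer_km = CP_BUFFER_KM,
       min_area_km2 = CP_MIN_AREA_KM2, min_share = CP_MIN_SHARE,
       min_distinct = 2, group_size = CP_GROUP_SIZE,
       tac_area_km2 = CP_TAC_AREA_KM2)
}

read_config <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  params <- utils::modifyList(cp_default_params(), config$params %||% list())
  config$params <- params
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

require_keys <- function(config, keys) {
  miss <- keys[vapply(keys, function(k) is.null(config[[k]]), logical(1))]
  if (length(miss)) {
    stop("config misses required key(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
}

write_provenance <- function(out_dir, stage, config, counts) {
  rec <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("colognepop")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    params = config$params,
    inputs = config[setdiff(names(config), "params")],
    counts = counts
  )
  jsonlite::write_json(rec, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(rec)
}

#' Simulate a synthetic study dataset to disk
#'
#' @param config list or JSON file with keys `window` (bbox
#'   `c(xmin,xmax,ymin,ymax)` in metres or a GeoJSON path), `seed`, and the
#'   simulator settings of [simulate_sites()] / [simulate_raw_materials()]
#'   (`kappa, mu, sigma_km, background, centres, phase_mix, raw_materials`).
#' @param out_dir output directory (created if absent).
#' @return invisibly, list with the `site_simulation`, the raw-material
#'   tibble (or NULL) and written paths.
#' @export
cp_simulate <- function(config, out_dir) {
  config <- read_config(config)
  require_keys(config, c("window", "seed"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  window <- load_window(config$window)
  sim <- simulate_sites(
    window,
    kappa = config$kappa %||% 0, mu = config$mu %||% 0,
    sigma_km = config$sigma_km %||% 10,
    background = config$background %||% 0,
    centres = if (!is.null(config$centres)) matrix(unlist(config$centres), ncol = 2, byrow = TRUE),
    phase_mix = unlist(config$phase_mix %||%
                         c(GI1DA = 0.5, GS1 = 0.5, FP_GENERIC = 0,
                           FP_PB_GENERIC = 0, GS1_PB = 0)),
    seed = config$seed
  )
  utils::write.csv(sim$sites, file.path(out_dir, "sites.csv"), row.names = FALSE)
  write_geojson(stats::setNames(truth_discs(sim),
                                paste0("truth", seq_len(nrow(sim$parents)))),
                file.path(out_dir, "truth_discs.geojson"))
  rm_tbl <- NULL
  if (isTRUE(config$raw_materials) && nrow(sim$sites) > 0) {
    rm_tbl <- simulate_raw_materials(sim$sites, seed = config$seed)
    utils::write.csv(rm_tbl, file.path(out_dir, "raw_materials.csv"),
                     row.names = FALSE)
  }
  message("simulated ", nrow(sim$sites), " sites (seed ", config$seed, ")")
  write_provenance(out_dir, "simulate", config,
                   list(n_sites = nrow(sim$sites),
                        n_raw_records = if (is.null(rm_tbl)) 0L else nrow(rm_tbl)))
  invisible(list(simulation = sim, raw_materials = rm_tbl, out_dir = out_dir))
}

load_window <- function(w) {
  if (is.character(w)) {
    g <- read_geojson(w)
    return(if (length(g) == 1) g[[1]] else unname(g))
  }
  if (is.numeric(w) && length(w) == 4) {
    return(rect_window(w[1], w[2], w[3], w[4]))
  }
  w
}

#' Run the full estimation pipeline
#'
#' Reads sites (and optionally raw materials), selects the phase/dataset,
#' delimits Core Areas, builds and filters catchments, derives quartiles and
#' produces the demographic estimate table, logging per-stage record counts.
#'
#' @param config list or JSON file with keys `sites` (CSV path), `window`
#'   (bbox or GeoJSON path), `phase`, `dataset`; optional `raw_materials`
#'   (CSV path), `params` (see the core-area and catchment functions),
#'   `seed`.
#' @param out_dir output directory.
#' @return invisibly, list with `core_areas`, `rmcas`, `quartiles`,
#'   `estimate` and the provenance record.
#' @export
cp_run <- function(config, out_dir) {
  config <- read_config(config)
  require_keys(config, c("sites", "window", "phase", "dataset"))
  p <- config$params
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  window <- load_window(config$window)

  sites <- read_sites(config$sites, window = window)
  sel <- select_dataset(sites, phase = config$phase, dataset = config$dataset)
  if (nrow(sel) < 3) stop("fewer than 3 records after selection", call. = FALSE)

  geo <- sel[!duplicated(sel[c("x", "y")]), , drop = FALSE]
  ca <- build_core_areas(geo, window, cell_km = p$cell_km,
                         level_step_km = p$level_step_km,
                         min_capture = p$min_capture,
                         plateau_tol = p$plateau_tol, idw_power = p$idw_power)
  utils::write.csv(ca$regions[[1]]$curve[, c("level_km", "area_km2", "capture")],
                   file.path(out_dir, "isopleth_curve.csv"), row.names = FALSE)
  polys <- purrr::imap(ca$regions, function(r, nm) r$polygons)
  write_geojson(stats::setNames(unlist(polys, recursive = FALSE),
                                paste0("core", seq_along(unlist(polys, recursive = FALSE)))),
                file.path(out_dir, "core_areas.geojson"))

  counts <- list(records_read = nrow(sites), records_selected = nrow(sel),
                 distinct_locations = nrow(geo),
                 sites_captured = sum(ca$summary$n_inside))

  est <- NULL; quart <- NULL; rmcas <- NULL
  if (!is.null(config$raw_materials)) {
    rm_tbl <- tibble::as_tibble(utils::read.csv(config$raw_materials))
    rm_sel <- select_raw_materials(rm_tbl, phase = config$phase)
    fs <- filter_shares(rm_sel, min_share = p$min_share)
    ids <- intersect(unique(fs$kept$assemblage_id), sel$id)
    rmcas <- build_rmcas(sel[match(ids, sel$id), , drop = FALSE],
                         fs$kept, buffer_km = p$buffer_km)
    rmcas <- apply_rmca_filters(rmcas, min_area_km2 = p$min_area_km2,
                                min_distinct = p$min_distinct)
    rmcas$block <- "all"
    quart <- regional_quartiles(rmcas, transfer_map = list(all = "window"))
    utils::write.csv(rmcas[, setdiff(names(rmcas), "hull")],
                     file.path(out_dir, "rmcas.csv"), row.names = FALSE)
    est <- estimate_table(
      tibble::tibble(region = "window", odi_km2 = ca$total_area_km2,
                     q1 = quart$q1, q2 = quart$q2, q3 = quart$q3,
                     n_raw = quart$n_raw),
      tac_area_km2 = polygon_area(window) / 1e6,
      group_size = p$group_size,
      phase = config$phase, dataset = config$dataset
    )
    utils::write.csv(format_estimate_table(est),
                     file.path(out_dir, "estimate.csv"), row.names = FALSE)
    counts$raw_records <- nrow(rm_tbl)
    counts$raw_records_phase <- nrow(rm_sel)
    counts$raw_records_kept <- nrow(fs$kept)
    counts$rmcas_kept <- sum(rmcas$status == "kept")
    counts$rmcas_total <- nrow(rmcas)
  }
  prov <- write_provenance(out_dir, "run", config, counts)
  message("pipeline complete: ", counts$records_selected, "/",
          counts$records_read, " records selected, Core Area ",
          round(ca$total_area_km2), " km^2")
  invisible(list(core_areas = ca, rmcas = rmcas, quartiles = quart,
                 estimate = est, provenance = prov))
}

#' Reproduce a published estimate table and report the diff
#'
#' @param table 1 or 2.
#' @param quiet suppress the printed diff summary.
#' @return invisibly, the [reproduce_tables()] result; an attribute
#'   `"clean"` is TRUE when every non-quantized cell matched.
#' @export
cp_reproduce <- function(table = 1, quiet = FALSE) {
  rep <- reproduce_tables(table)
  hard <- rep$diff[!rep$diff$quantized, , drop = FALSE]
  if (!quiet) {
    message("table ", table, ": ", sum(rep$cells$match), "/",
            nrow(rep$cells), " printed cells match; ",
            nrow(rep$diff), " mismatch(es), of which ",
            nrow(hard), " outside the documented quantized set")
    if (nrow(rep$diff)) {
      print(rep$diff[, c("region", "q", "column", "printed", "computed",
                         "quantized")], n = Inf)
    }
  }
  attr(rep, "clean") <- nrow(hard) == 0
  invisible(rep)
}
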