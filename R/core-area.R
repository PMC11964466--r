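## Core Area delineation: LEC sampling -> IDW interpolation -> isopleth
## extraction -> ODI selection, run independently for each calibration region
## so the isoline level can adapt to regional differences in site density.

#' Delimit Core Areas from a site pattern
#'
#' Runs the full delineation chain per calibration region and merges the
#' results.  When no calibration regions are supplied the whole window is one
#' region.  When estimate regions are supplied, the Core Area surface is
#' additionally apportioned to them (area of core cells per estimate-region
#' polygon).
#'
#' @param sites tibble with `x`, `y` (metres).
#' @param window study-window polygon (metres).
#' @param calibration_regions named list of polygons partitioning the window;
#'   default: the window itself.
#' @param estimate_regions optional named list of polygons over which the
#'   merged Core Areas are measured.
#' @param cell_km interpolation cell size (km, default 10).
#' @param level_step_km isopleth level spacing (km, default 1); the ladder
#'   runs from one step up to the 95th percentile of sample radii.
#' @param min_capture,plateau_tol ODI rule parameters, see [select_odi()].
#' @param idw_power IDW power, see [interpolate_lec()].
#' @return object of class `core_area_set`: list with `summary` (tibble: one
#'   row per calibration region with `region, odi_level_km, area_km2,
#'   n_sites, n_inside, capture, fallback`), `regions` (per-region grids,
#'   masks, curves, polygons), `estimate_areas` (tibble or NULL) and overall
#'   `capture`.
#' @export
build_core_areas <- function(sites, window, calibration_regions = NULL,
                             estimate_regions = NULL, cell_km = 10,
                             level_step_km = 1,
                             min_capture = CP_MIN_CAPTURE, plateau_tol = 0.10,
                             idw_power = 2) {
  if (is.null(calibration_regions)) calibration_regions <- list(window = window)
  if (is.null(names(calibration_regions))) {
    names(calibration_regions) <- paste0("region", seq_along(calibration_regions))
  }
  regions <- purrr::imap(calibration_regions, function(poly, nm) {
    sub <- sites[points_in_polygon(sites$x, sites$y, poly), , drop = FALSE]
    res <- tryCatch({
      lec <- compute_lec(sub, poly)
      grid <- interpolate_lec(lec, poly, cell_km = cell_km, power = idw_power)
      top <- stats::quantile(lec$radius_km, 0.95, names = FALSE)
      levels <- seq(level_step_km, max(top, level_step_km), by = level_step_km)
      if (max(levels) < top) levels <- c(levels, max(levels) + level_step_km)
      curve <- extract_isopleths(grid, levels, sites = sub)
      odi <- select_odi(curve, min_capture = min_capture,
                        plateau_tol = plateau_tol)
      list(lec = lec, grid = grid, curve = odi$curve, odi = odi,
           mask = level_mask(grid, odi$level_km),
           polygons = isopleth_polygons(grid, odi$level_km),
           n_sites = nrow(sub))
    }, error = function(e) {
      stop("calibration region '", nm, "': ", conditionMessage(e),
           call. = FALSE)
    })
    res
  })

  summary <- purrr::imap_dfr(regions, function(r, nm) {
    tibble::tibble(
      region = nm,
      odi_level_km = r$odi$level_km,
      area_km2 = r$odi$area_km2,
      n_sites = r$n_sites,
      n_inside = round(r$odi$capture * r$n_sites),
      capture = r$odi$capture,
      fallback = r$odi$fallback
    )
  })
  total_sites <- sum(summary$n_sites)
  overall_capture <- if (total_sites > 0) sum(summary$n_inside) / total_sites else NA_real_

  estimate_areas <- NULL
  if (!is.null(estimate_regions)) {
    estimate_areas <- purrr::imap_dfr(estimate_regions, function(poly, nm) {
      a <- 0
      for (r in regions) {
        g <- r$grid
        cent <- expand.grid(x = g$x, y = g$y)
        in_est <- matrix(points_in_polygon(cent$x, cent$y, poly),
                         nrow = length(g$x))
        a <- a + sum(r$mask & in_est) * g$cell_km^2
      }
      tibble::tibble(region = nm, core_area_km2 = a)
    })
  }

  structure(
    list(summary = summary, regions = regions,
         estimate_areas = estimate_areas, capture = overall_capture,
         total_area_km2 = sum(summary$area_km2),
         params = list(cell_km = cell_km, level_step_km = level_step_km,
                       min_capture = min_capture, plateau_tol = plateau_tol,
                       idw_power = idw_power)),
    class = "core_area_set"
  )
}

#' @export
print.core_area_set <- function(x, ...) {
  cat("<core_area_set> ", nrow(x$summary), " calibration region(s), total ",
      format(round(x$total_area_km2)), " km^2, overall capture ",
      sprintf("%.1f%%", 100 * x$capture), "\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @method tidy core_area_set
#' @export
tidy.core_area_set <- function(x, ...) x$summary

#' @method glance core_area_set
#' @export
glance.core_area_set <- function(x, ...) {
  tibble::tibble(
    n_regions = nrow(x$summary),
    total_area_km2 = x$total_area_km2,
    capture = x$capture,
    any_fallback = any(x$summary$fallback)
  )
}
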