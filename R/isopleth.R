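## Isopleth extraction from an interpolated LEC grid.  The level-L region is
## the set of cells whose interpolated radius does not exceed L km (high site
## density = small empty circles); its area and the fraction of sites it
## captures are both non-decreasing in L by set inclusion.

#' Extract isopleth areas and site capture per level
#'
#' @param grid `lec_grid` from [interpolate_lec()].
#' @param levels ascending radii (km) at which to evaluate the isopleths.
#' @param sites optional tibble with `x`, `y` (metres) for capture fractions;
#'   a site counts as captured at level L when the value of its grid cell is
#'   `<= L` (sites on the isoline are inside).
#' @return tibble of class `isopleth_curve` with columns `level_km, area_km2,
#'   delta_area_km2, capture, n_inside`.
#' @export
extract_isopleths <- function(grid, levels, sites = NULL) {
  stopifnot(inherits(grid, "lec_grid"), length(levels) >= 1)
  if (is.unsorted(levels, strictly = TRUE)) {
    stop("levels must be strictly ascending", call. = FALSE)
  }
  cell_area <- grid$cell_km^2
  zin <- grid$z[!is.na(grid$z)]
  sv <- if (!is.null(sites) && nrow(sites) > 0) {
    grid_value_at(grid, sites$x, sites$y)
  }
  area <- vapply(levels, function(L) sum(zin <= L) * cell_area, numeric(1))
  n_in <- if (is.null(sv)) rep(NA_integer_, length(levels)) else {
    vapply(levels, function(L) sum(sv <= L, na.rm = TRUE), integer(1))
  }
  capture <- if (is.null(sv)) rep(NA_real_, length(levels)) else {
    n_in / nrow(sites)
  }
  out <- tibble::tibble(
    level_km = levels,
    area_km2 = area,
    delta_area_km2 = diff(c(0, area)),
    capture = capture,
    n_inside = n_in
  )
  class(out) <- c("isopleth_curve", class(out))
  out
}

#' Contour polygons of a level set
#'
#' Marching-squares contours (via [grDevices::contourLines()]) of the region
#' where the interpolated radius is at most `level`; cells outside the window
#' are treated as high so contours close along the window boundary.
#'
#' @param grid `lec_grid`.
#' @param level radius in km.
#' @return list of ring matrices (metres); may be empty.
#' @export
isopleth_polygons <- function(grid, level) {
  z <- grid$z
  hi <- max(c(level * 2, z + 1), na.rm = TRUE)
  z[is.na(z)] <- hi
  ## pad so contours close at the grid border
  cell <- grid$cell_km * 1000
  x <- c(grid$x[1] - cell, grid$x, grid$x[length(grid$x)] + cell)
  y <- c(grid$y[1] - cell, grid$y, grid$y[length(grid$y)] + cell)
  zp <- matrix(hi, nrow = length(x), ncol = length(y))
  zp[2:(length(x) - 1), 2:(length(y) - 1)] <- z
  cl <- grDevices::contourLines(x = x, y = y, z = zp, levels = level)
  lapply(cl, function(c0) cbind(x = c0$x, y = c0$y))
}

#' Binary core mask of a grid at a level
#' @keywords internal
level_mask <- function(grid, level) {
  m <- !is.na(grid$z) & grid$z <= level
  m
}

#' Jaccard index between two cell masks on the same grid
#'
#' @param m1,m2 logical matrices of identical dimension.
#' @return intersection area over union area (0 when both empty).
#' @export
jaccard_masks <- function(m1, m2) {
  stopifnot(identical(dim(m1), dim(m2)))
  u <- sum(m1 | m2)
  if (u == 0) return(0)
  sum(m1 & m2) / u
}

#' Mask of grid cells covered by a set of polygons
#' @param grid `lec_grid`.
#' @param polys list of ring matrices (metres).
#' @export
polygons_mask <- function(grid, polys) {
  cent <- expand.grid(x = grid$x, y = grid$y)
  inside <- points_in_polygon(cent$x, cent$y, polys)
  matrix(inside, nrow = length(grid$x)) & !is.na(grid$z)
}
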