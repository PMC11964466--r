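## Largest-Empty-Circle sampling of a site pattern.
##
## The locally largest circles containing no site are centred at Voronoi
## vertices of the pattern; their radii (distance to the nearest site) form an
## inverse density measure.  Where Voronoi edges leave the study window,
## additional samples are placed at the crossing points so that density near
## coasts/borders is anchored by boundary values rather than extrapolated from
## interior vertices.

#' Sample Largest-Empty-Circle radii over a window
#'
#' Computes the Voronoi diagram of the (deduplicated) sites, keeps every
#' Voronoi vertex inside the window plus the points where Voronoi edges cross
#' the window boundary, and assigns each sample the distance to its nearest
#' site.
#'
#' @param sites tibble with columns `x`, `y` (metres); exact duplicate
#'   coordinates are removed (count reported via attribute `"n_duplicates"`).
#' @param window polygon (metres).
#' @return tibble of class `lec_samples` with columns `cx, cy` (metres),
#'   `radius_km` and `origin` (`"voronoi_vertex"` or `"window_boundary"`).
#' @export
compute_lec <- function(sites, window) {
  pts <- unique(data.frame(x = sites$x, y = sites$y))
  n_dup <- nrow(sites) - nrow(pts)
  if (nrow(pts) < 3) {
    stop("degenerate input: need at least 3 distinct sites, got ", nrow(pts),
         call. = FALSE)
  }
  if (is_collinear(pts$x, pts$y)) {
    stop("degenerate input: sites are collinear", call. = FALSE)
  }
  bb <- polygon_bbox(window)
  pad <- max(bb["xmax"] - bb["xmin"], bb["ymax"] - bb["ymin"])
  rw <- c(bb["xmin"] - pad, bb["xmax"] + pad, bb["ymin"] - pad, bb["ymax"] + pad)
  dd <- deldir::deldir(pts$x, pts$y, rw = rw, suppressMsge = TRUE)
  seg <- dd$dirsgs

  ## Voronoi vertices: segment endpoints not created by clipping at rw.
  v1 <- seg[!seg$bp1, c("x1", "y1")]
  v2 <- seg[!seg$bp2, c("x2", "y2")]
  names(v1) <- names(v2) <- c("x", "y")
  verts <- unique(round(rbind(v1, v2), 6))
  inside <- points_in_polygon(verts$x, verts$y, window)
  verts <- verts[inside, , drop = FALSE]

  ## Boundary samples: crossings of Voronoi edges with the window boundary.
  cross <- purrr::map(seq_len(nrow(seg)), function(i) {
    segment_polygon_crossings(c(seg$x1[i], seg$y1[i]),
                              c(seg$x2[i], seg$y2[i]), window)
  })
  cross <- do.call(rbind, cross)
  ## window vertices complete the boundary candidates: along any boundary
  ## segment the distance to the fixed nearest site is convex, so boundary
  ## maxima sit at edge crossings or at polygon vertices
  corners <- do.call(rbind, as_rings(window))
  cross <- rbind(cross, corners)
  bnd <- unique(round(data.frame(x = cross[, 1], y = cross[, 2]), 6))

  samples <- rbind(
    if (nrow(verts)) data.frame(verts, origin = "voronoi_vertex"),
    if (nrow(bnd)) data.frame(bnd, origin = "window_boundary")
  )
  if (is.null(samples) || nrow(samples) == 0) {
    stop("no LEC samples fall inside the window", call. = FALSE)
  }
  r <- nearest_site_distance(samples$x, samples$y, pts$x, pts$y)
  out <- tibble::tibble(cx = samples$x, cy = samples$y,
                        radius_km = r / 1000, origin = samples$origin)
  attr(out, "n_duplicates") <- n_dup
  class(out) <- c("lec_samples", class(out))
  out
}

#' Brute-force largest empty circle by exhaustive grid search
#'
#' Independent oracle: evaluates the nearest-site distance on a regular grid
#' of candidate centres inside the window and returns the best candidate.
#' Used in tests to validate the Voronoi construction.
#'
#' @param sites tibble with `x`, `y` (metres).
#' @param window polygon.
#' @param step_km candidate grid spacing (km).
#' @return list with `cx, cy` (metres) and `radius_km` of the best candidate.
#' @export
lec_grid_search <- function(sites, window, step_km = 0.1) {
  bb <- polygon_bbox(window)
  step <- step_km * 1000
  gx <- seq(bb["xmin"], bb["xmax"], by = step)
  gy <- seq(bb["ymin"], bb["ymax"], by = step)
  cand <- expand.grid(x = gx, y = gy)
  cand <- cand[points_in_polygon(cand$x, cand$y, window), , drop = FALSE]
  d <- nearest_site_distance(cand$x, cand$y, sites$x, sites$y)
  i <- which.max(d)
  list(cx = cand$x[i], cy = cand$y[i], radius_km = d[i] / 1000)
}
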