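## Plain planar geometry on two-column coordinate matrices (metres, equal-area
## projection).  A "window" or region polygon is a single closed ring given as
## a matrix/data.frame with columns x, y (closing vertex optional), or a list
## of such rings for a multi-part window.  Holes are not supported.

#' Normalise a polygon argument to a list of rings
#'
#' @param poly matrix/data.frame with columns x,y, or a list of these.
#' @return list of two-column matrices, each an open ring (no repeated last
#'   vertex).
#' @keywords internal
as_rings <- function(poly) {
  if (is.null(poly)) stop("polygon is NULL", call. = FALSE)
  if (!is.list(poly) || is.data.frame(poly)) poly <- list(poly)
  lapply(poly, function(r) {
    r <- as.matrix(as.data.frame(r)[, 1:2])
    storage.mode(r) <- "double"
    if (nrow(r) < 3) stop("polygon ring needs >= 3 vertices", call. = FALSE)
    if (all(r[1, ] == r[nrow(r), ])) r <- r[-nrow(r), , drop = FALSE]
    colnames(r) <- c("x", "y")
    r
  })
}

#' Shoelace area of a polygon
#'
#' @param poly polygon (ring or list of rings), coordinates in metres.
#' @return area in square metres (sum over rings, absolute value per ring).
#' @export
polygon_area <- function(poly) {
  sum(vapply(as_rings(poly), function(r) {
    x <- r[, 1]; y <- r[, 2]
    j <- c(2:length(x), 1)
    abs(sum(x * y[j] - x[j] * y)) / 2
  }, numeric(1)))
}

#' Test points for inclusion in a polygon
#'
#' @param x,y point coordinates (metres).
#' @param poly polygon (ring or list of rings).
#' @return logical vector, TRUE when the point falls in any ring.
#' @export
points_in_polygon <- function(x, y, poly) {
  rings <- as_rings(poly)
  pts <- cbind(x, y)
  inside <- rep(FALSE, nrow(pts))
  for (r in rings) {
    bnd <- rbind(r, r[1, ], c(NA, NA))
    inside <- inside | mgcv::in.out(bnd, pts)
  }
  inside
}

#' Bounding box of a polygon
#' @keywords internal
polygon_bbox <- function(poly) {
  r <- do.call(rbind, as_rings(poly))
  c(xmin = min(r[, 1]), xmax = max(r[, 1]), ymin = min(r[, 2]), ymax = max(r[, 2]))
}

#' Regular polygon approximating a disc
#'
#' @param cx,cy centre (metres).
#' @param radius radius (metres).
#' @param n number of vertices (360 keeps the area within 0.005\% of the disc).
#' @keywords internal
disc_polygon <- function(cx, cy, radius, n = 360) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(x = cx + radius * cos(th), y = cy + radius * sin(th))
}

#' Axis-aligned rectangle ring
#' @param xmin,xmax,ymin,ymax extent in metres.
#' @export
rect_window <- function(xmin, xmax, ymin, ymax) {
  cbind(x = c(xmin, xmax, xmax, xmin), y = c(ymin, ymin, ymax, ymax))
}

#' Distance from each query point to its nearest site
#'
#' Chunked so that the full distance matrix never materialises for large
#' query sets.
#'
#' @param qx,qy query coordinates (metres).
#' @param sx,sy site coordinates (metres).
#' @param chunk query chunk size.
#' @return numeric vector of distances in metres.
#' @keywords internal
nearest_site_distance <- function(qx, qy, sx, sy, chunk = 2048L) {
  n <- length(qx)
  out <- numeric(n)
  for (i0 in seq(1L, n, by = chunk)) {
    i1 <- min(i0 + chunk - 1L, n)
    dx <- outer(qx[i0:i1], sx, "-")
    dy <- outer(qy[i0:i1], sy, "-")
    out[i0:i1] <- sqrt(.rowMins(dx * dx + dy * dy))
  }
  out
}

.rowMins <- function(m) {
  do.call(pmin, c(as.data.frame(m), list(na.rm = TRUE)))
}

#' Intersections of a segment with the boundary of a polygon
#'
#' @param p1,p2 numeric length-2 endpoints of the segment.
#' @param poly polygon.
#' @return matrix of crossing points (possibly 0 rows).
#' @keywords internal
segment_polygon_crossings <- function(p1, p2, poly) {
  out <- matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("x", "y")))
  d <- p2 - p1
  for (r in as_rings(poly)) {
    a <- r
    b <- r[c(2:nrow(r), 1), , drop = FALSE]
    e <- b - a
    ## solve p1 + t*d = a + s*e for each edge; denominator = cross(d, e)
    den <- d[1] * e[, 2] - d[2] * e[, 1]
    w <- cbind(a[, 1] - p1[1], a[, 2] - p1[2])
    t <- (w[, 1] * e[, 2] - w[, 2] * e[, 1]) / den
    s <- (w[, 1] * d[2] - w[, 2] * d[1]) / den
    ok <- is.finite(t) & is.finite(s) & t >= 0 & t <= 1 & s >= 0 & s <= 1
    if (any(ok)) {
      out <- rbind(out, cbind(x = p1[1] + t[ok] * d[1], y = p1[2] + t[ok] * d[2]))
    }
  }
  out
}

#' Convex hull vertices of a point set
#' @keywords internal
convex_hull <- function(x, y) {
  i <- grDevices::chull(x, y)
  cbind(x = x[i], y = y[i])
}

#' Are points collinear (within a relative tolerance)?
#' @keywords internal
is_collinear <- function(x, y, tol = 1e-9) {
  if (length(x) < 3) return(TRUE)
  xc <- x - mean(x); yc <- y - mean(y)
  s <- svd(cbind(xc, yc), nu = 0, nv = 0)$d
  s[2] <= tol * max(s[1], .Machine$double.eps)
}
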