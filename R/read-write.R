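## Site-table and GeoJSON input/output.
##
## Site tables are delimited files with a header naming at least
## id, x, y, region, attributions (";"-separated flags) and optionally
## evidence ("excavation" or "surface").  Coordinates are metres in a single
## equal-area projection so every downstream quantity is a true area.

#' Read and validate a site table
#'
#' Reads a CSV/TSV of assemblage records, validates each record against the
#' domain invariants (finite coordinates, known attribution flags, non-empty
#' attribution set) and, when a study window is supplied, rejects records
#' falling outside it.  Rejections are reported, never silently dropped.
#' Exact duplicate coordinates are retained in the table but flagged so
#' geometry stages can deduplicate them.
#'
#' @param path delimited file with header `id,x,y,region,attributions[,evidence]`.
#' @param window optional study-window polygon (metres); records outside it are
#'   moved to the rejection report.
#' @param sep field separator; `","` for CSV (default), `"\t"` for TSV.
#' @return tibble of accepted records with columns `id, x, y, region,
#'   attributions, evidence, dup_coord`; attribute `"rejected"` holds a tibble
#'   of rejected records with a `reason` column.
#' @export
read_sites <- function(path, window = NULL, sep = ",") {
  raw <- utils::read.csv(path, sep = sep, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  need <- c("id", "x", "y", "region", "attributions")
  if (anyDuplicated(names(raw))) {
    stop("duplicate column(s) in site table: ",
         paste(unique(names(raw)[duplicated(names(raw))]), collapse = ", "),
         call. = FALSE)
  }
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("site table misses column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"evidence" %in% names(raw)) raw$evidence <- "excavation"
  tbl <- tibble::as_tibble(raw[c(need, "evidence")])

  xs <- suppressWarnings(as.numeric(tbl$x))
  ys <- suppressWarnings(as.numeric(tbl$y))
  bad_num <- !is.finite(xs) | !is.finite(ys)
  if (any(bad_num)) {
    stop("non-numeric/non-finite coordinate(s) for id(s): ",
         paste(tbl$id[bad_num], collapse = ", "), call. = FALSE)
  }
  tbl$x <- xs
  tbl$y <- ys

  flags <- parse_attributions(tbl$attributions)
  unknown <- setdiff(unique(unlist(flags)), CP_FLAGS)
  if (length(unknown)) {
    stop("unknown attribution flag(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  reason <- rep(NA_character_, nrow(tbl))
  reason[lengths(flags) == 0] <- "empty attributions"
  if (!is.null(window)) {
    outside <- !points_in_polygon(tbl$x, tbl$y, window)
    reason[is.na(reason) & outside] <- "outside study window"
  }

  keep <- is.na(reason)
  rejected <- tbl[!keep, , drop = FALSE]
  rejected$reason <- reason[!keep]
  tbl <- tbl[keep, , drop = FALSE]
  tbl$dup_coord <- duplicated(tbl[c("x", "y")])
  attr(tbl, "rejected") <- rejected
  tbl
}

#' Split ";"-separated attribution strings into flag vectors
#' @keywords internal
parse_attributions <- function(a) {
  lapply(strsplit(as.character(a), ";", fixed = TRUE),
         function(v) unique(v[nzchar(trimws(v))]))
}

#' Select the records of a phase/dataset combination
#'
#' Dataset B keeps only assemblages whose attributions include the selected
#' phase flag (an assemblage attributed to both phases appears in both phase
#' selections).  Dataset A additionally keeps generically attributed
#' assemblages: the Final Palaeolithic and Final Palaeolithic/Preboreal bins
#' for either phase, and the late-stadial/Preboreal bin for the stadial phase
#' only.
#'
#' @param sites tibble with an `attributions` column (";"-separated flags).
#' @param phase `"GI1DA"` (interstadial) or `"GS1"` (stadial).
#' @param dataset `"A"` (all sites) or `"B"` (chronologically subdivided only).
#' @return tibble of selected records.
#' @export
select_dataset <- function(sites, phase = c("GI1DA", "GS1"),
                           dataset = c("A", "B")) {
  phase <- match.arg(phase)
  dataset <- match.arg(dataset)
  flags <- parse_attributions(sites$attributions)
  keep_flags <- phase
  if (dataset == "A") {
    keep_flags <- c(keep_flags, "FP_GENERIC", "FP_PB_GENERIC",
                    if (phase == "GS1") "GS1_PB")
  }
  keep <- vapply(flags, function(v) any(v %in% keep_flags), logical(1))
  sites[keep, , drop = FALSE]
}

#' Tally assemblages and distinct sites per attribution flag
#'
#' Records are assemblages; several assemblages may share one site (same
#' coordinates), so both tallies are reported.
#'
#' @param sites tibble as returned by [read_sites()].
#' @return tibble with columns `flag, n_assemblages, n_sites`.
#' @export
attribution_census <- function(sites) {
  flags <- parse_attributions(sites$attributions)
  purrr::map_dfr(CP_FLAGS, function(f) {
    sel <- vapply(flags, function(v) f %in% v, logical(1))
    tibble::tibble(
      flag = f,
      n_assemblages = sum(sel),
      n_sites = nrow(unique(sites[sel, c("x", "y")]))
    )
  })
}

## ---------------------------------------------------------------- GeoJSON --

#' Write geometries to a GeoJSON FeatureCollection
#'
#' @param geoms named list of geometries: a length-2 numeric (point), a ring
#'   matrix (polygon) or a list of ring matrices (multipolygon).
#' @param path output file.
#' @param properties optional data.frame/tibble of per-feature properties.
#' @return `path`, invisibly.
#' @export
write_geojson <- function(geoms, path, properties = NULL) {
  features <- purrr::imap(geoms, function(g, nm) {
    geom <- geojson_geometry(g, nm)
    props <- list(name = nm)
    if (!is.null(properties)) {
      i <- if (is.character(nm) && nm %in% rownames(properties)) nm
           else match(nm, names(geoms))
      props <- c(props, as.list(properties[i, , drop = FALSE]))
    }
    list(type = "Feature", properties = props, geometry = geom)
  })
  fc <- list(type = "FeatureCollection", features = unname(features))
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

geojson_geometry <- function(g, nm) {
  close_ring <- function(r) {
    r <- as_rings(r)[[1]]
    unname(lapply(seq_len(nrow(r) + 1L), function(i) {
      j <- if (i > nrow(r)) 1L else i
      c(r[j, 1], r[j, 2])
    }))
  }
  if (is.numeric(g) && length(g) == 2 && is.null(dim(g))) {
    list(type = "Point", coordinates = c(g[[1]], g[[2]]))
  } else if (is.matrix(g) || is.data.frame(g)) {
    if (!isTRUE(all(is.finite(as.matrix(as.data.frame(g)[, 1:2]))))) {
      stop("invalid geometry for feature ", nm, call. = FALSE)
    }
    list(type = "Polygon", coordinates = list(close_ring(g)))
  } else if (is.list(g)) {
    list(type = "MultiPolygon",
         coordinates = lapply(g, function(r) list(close_ring(r))))
  } else {
    stop("invalid geometry for feature ", nm, call. = FALSE)
  }
}

#' Read a GeoJSON FeatureCollection
#'
#' Supports Point, Polygon and MultiPolygon features (outer rings only).
#'
#' @param path GeoJSON file.
#' @return named list of geometries in the representation accepted by
#'   [write_geojson()]; feature properties attached as attribute
#'   `"properties"`.
#' @export
read_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  stopifnot(identical(fc$type, "FeatureCollection"))
  props <- list()
  geoms <- lapply(fc$features, function(f) {
    g <- f$geometry
    coords <- g$coordinates
    ring_mat <- function(ring) {
      m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
      colnames(m) <- c("x", "y")
      if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
      m
    }
    switch(g$type,
      Point = c(coords[[1]], coords[[2]]),
      Polygon = ring_mat(coords[[1]]),
      MultiPolygon = lapply(coords, function(poly) ring_mat(poly[[1]])),
      stop("unsupported GeoJSON geometry: ", g$type, call. = FALSE)
    )
  })
  names(geoms) <- vapply(fc$features, function(f) {
    nm <- f$properties$name
    if (is.null(nm)) "" else as.character(nm)
  }, character(1))
  attr(geoms, "properties") <- lapply(fc$features, `[[`, "properties")
  geoms
}
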