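## Synthetic site patterns and raw-material assemblages with known ground
## truth.  Site patterns follow a Thomas process (Poisson parents, Gaussian
## offspring) over a polygonal window, optionally with fixed parent locations
## and a uniform Poisson background; attribution flags are drawn i.i.d. from a
## configurable mix.  All intensities are per square kilometre, offspring
## spread in kilometres, coordinates in metres.

#' Simulate a clustered site pattern
#'
#' Thomas process: parents are either supplied (`centres`) or drawn as a
#' Poisson process of intensity `kappa` per km\eqn{^2} uniformly in the
#' window; each parent receives `Pois(mu)` offspring displaced by an isotropic
#' Gaussian with standard deviation `sigma_km`.  An independent uniform
#' Poisson background of intensity `background` per km\eqn{^2} is added.
#' Offspring falling outside the window are discarded (no edge wrapping).
#' Ground truth for recovery experiments is the set of discs of radius
#' `3 * sigma_km` around the parents, covering about 99\% of each cluster's
#' mass.
#'
#' @param window polygon (metres).
#' @param kappa parent intensity per km^2 (ignored when `centres` given).
#' @param mu mean number of offspring per parent.
#' @param sigma_km offspring displacement standard deviation (km).
#' @param background uniform background intensity per km^2.
#' @param centres optional matrix of fixed parent locations (metres).
#' @param phase_mix named probabilities over the attribution flags
#'   `GI1DA, GS1, FP_GENERIC, FP_PB_GENERIC, GS1_PB`; must sum to 1.
#' @param p_both probability that a record attributed to a phase carries both
#'   phase flags (clearly assigned to both phases).
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return object of class `site_simulation`: list with `sites` (tibble in the
#'   [read_sites()] layout), `parents` (matrix, metres) and `truth_radius_km`.
#' @export
simulate_sites <- function(window, kappa = 0, mu = 0, sigma_km = 10,
                           background = 0, centres = NULL,
                           phase_mix = c(GI1DA = 0.5, GS1 = 0.5,
                                         FP_GENERIC = 0, FP_PB_GENERIC = 0,
                                         GS1_PB = 0),
                           p_both = 0, seed = 1L) {
  area_km2 <- polygon_area(window) / 1e6
  if (area_km2 <= 0) stop("window has zero area", call. = FALSE)
  stopifnot(kappa >= 0, mu >= 0, sigma_km >= 0, background >= 0, p_both >= 0)
  phase_mix <- phase_mix[CP_FLAGS]
  phase_mix[is.na(phase_mix)] <- 0
  names(phase_mix) <- CP_FLAGS
  if (abs(sum(phase_mix) - 1) > 1e-8) {
    stop("phase_mix probabilities must sum to 1", call. = FALSE)
  }
  set.seed(as.integer(seed))

  if (is.null(centres)) {
    n_par <- stats::rpois(1, kappa * area_km2)
    parents <- runif_in_polygon(n_par, window)
  } else {
    parents <- as.matrix(as.data.frame(centres)[, 1:2])
  }

  pts <- matrix(numeric(0), ncol = 2)
  if (nrow(parents) > 0 && mu > 0) {
    n_off <- stats::rpois(nrow(parents), mu)
    if (sum(n_off) > 0) {
      px <- rep(parents[, 1], n_off)
      py <- rep(parents[, 2], n_off)
      pts <- cbind(px + stats::rnorm(sum(n_off), 0, sigma_km * 1000),
                   py + stats::rnorm(sum(n_off), 0, sigma_km * 1000))
      pts <- pts[points_in_polygon(pts[, 1], pts[, 2], window), , drop = FALSE]
    }
  }
  n_bg <- stats::rpois(1, background * area_km2)
  if (n_bg > 0) pts <- rbind(pts, runif_in_polygon(n_bg, window))

  n <- nrow(pts)
  attr_str <- character(0)
  if (n > 0) {
    flag <- sample(CP_FLAGS, n, replace = TRUE, prob = phase_mix)
    attr_str <- flag
    if (p_both > 0) {
      both <- flag %in% CP_PHASES & stats::runif(n) < p_both
      attr_str[both] <- "GI1DA;GS1"
    }
  }
  sites <- tibble::tibble(
    id = if (n > 0) sprintf("sim%04d", seq_len(n)) else character(0),
    x = if (n > 0) pts[, 1] else numeric(0),
    y = if (n > 0) pts[, 2] else numeric(0),
    region = "sim",
    attributions = attr_str,
    evidence = "excavation"
  )
  structure(
    list(sites = sites, parents = parents, truth_radius_km = 3 * sigma_km,
         seed = as.integer(seed)),
    class = "site_simulation"
  )
}

#' @export
print.site_simulation <- function(x, ...) {
  cat("<site_simulation> ", nrow(x$sites), " sites, ",
      nrow(x$parents), " parents, truth radius ", x$truth_radius_km,
      " km, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Ground-truth cluster discs of a simulation
#'
#' @param sim `site_simulation` object.
#' @return list of disc polygons (360-gon, metres), one per parent.
#' @export
truth_discs <- function(sim) {
  lapply(seq_len(nrow(sim$parents)), function(i) {
    disc_polygon(sim$parents[i, 1], sim$parents[i, 2],
                 sim$truth_radius_km * 1000)
  })
}

#' Uniform points in a polygon by rejection from the bounding box
#' @keywords internal
runif_in_polygon <- function(n, poly) {
  out <- matrix(numeric(0), ncol = 2)
  if (n == 0) return(out)
  bb <- polygon_bbox(poly)
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 16L)
    cand <- cbind(stats::runif(m, bb["xmin"], bb["xmax"]),
                  stats::runif(m, bb["ymin"], bb["ymax"]))
    ok <- points_in_polygon(cand[, 1], cand[, 2], poly)
    out <- rbind(out, cand[ok, , drop = FALSE])
  }
  unname(out[seq_len(n), , drop = FALSE])
}

#' Simulate raw-material records for a set of assemblages
#'
#' Each assemblage receives between `n_sources[1]` and `n_sources[2]` sources
#' at exponential-tailed distances (mean `distance_scale_km`) in uniform
#' directions.  Share percentages are Dirichlet-distributed (symmetric
#' concentration `concentration`); in a fraction `sub_share_frac` of
#' assemblages one extra trace material is forced below the 1\% reporting
#' threshold so the share filter is exercised.
#'
#' @param sites tibble with `id`, `x`, `y`, `attributions`.
#' @param n_sources integer range `c(min, max)` of sources per assemblage.
#' @param distance_scale_km mean source-to-site distance (km).
#' @param concentration symmetric Dirichlet concentration of shares.
#' @param sub_share_frac fraction of assemblages given a forced sub-1\% trace
#'   material.
#' @param single_piece_frac fraction of source records flagged as documented by
#'   a single piece.
#' @param seed integer seed.
#' @return tibble with columns `assemblage_id, site_id, source_x, source_y,
#'   share_percent, attributions, single_piece`.
#' @export
simulate_raw_materials <- function(sites, n_sources = c(1L, 5L),
                                   distance_scale_km = 40,
                                   concentration = 1,
                                   sub_share_frac = 0.1,
                                   single_piece_frac = 0,
                                   seed = 1L) {
  stopifnot(nrow(sites) > 0, distance_scale_km > 0)
  set.seed(as.integer(seed))
  rows <- purrr::map_dfr(seq_len(nrow(sites)), function(i) {
    k <- if (n_sources[1] >= n_sources[2]) n_sources[1]
         else sample(seq(n_sources[1], n_sources[2]), 1)
    d <- stats::rexp(k, rate = 1 / (distance_scale_km * 1000))
    th <- stats::runif(k, 0, 2 * pi)
    g <- stats::rgamma(k, shape = concentration)
    share <- 100 * g / sum(g)
    forced <- stats::runif(1) < sub_share_frac
    if (forced) {
      trace <- stats::runif(1, 0.05, 0.95)
      share <- c(share * (100 - trace) / 100, trace)
      d <- c(d, stats::rexp(1, rate = 1 / (distance_scale_km * 1000)))
      th <- c(th, stats::runif(1, 0, 2 * pi))
      k <- k + 1L
    }
    tibble::tibble(
      assemblage_id = sites$id[i],
      site_id = sites$id[i],
      source_x = sites$x[i] + d * cos(th),
      source_y = sites$y[i] + d * sin(th),
      share_percent = share,
      attributions = sites$attributions[i],
      single_piece = FALSE,
      forced_trace = c(rep(FALSE, k - forced), if (forced) TRUE)
    )
  })
  if (single_piece_frac > 0) {
    rows$single_piece <- stats::runif(nrow(rows)) < single_piece_frac
  }
  rows
}
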