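## Selection of the optimally describing isoline (ODI).  The rule follows the
## protocol's diagnostic diagram: scan the areal-increment sequence of the
## isopleth curve for its first peak or plateau and take the first such level
## that still captures at least `min_capture` of the sites; when no peak or
## plateau qualifies, fall back to the first level reaching the capture
## threshold and flag the result.

#' Select the optimally describing isoline level
#'
#' A level is a *peak* of the increment sequence when its areal increment is
#' at least as large as both neighbours (the last level never counts as a
#' peak on its own).  A level is a *plateau* when its increment differs from
#' the previous one by at most `plateau_tol` times the maximum increment.
#'
#' @param curve `isopleth_curve` from [extract_isopleths()] (needs `capture`).
#' @param min_capture minimum fraction of sites the ODI must enclose
#'   (default 0.70).
#' @param plateau_tol relative tolerance defining a plateau (default 0.10).
#' @return list of class `odi_selection`: `level_km`, `area_km2`, `capture`,
#'   `fallback` (TRUE when no qualifying peak/plateau existed) and the
#'   annotated `curve`.
#' @export
select_odi <- function(curve, min_capture = CP_MIN_CAPTURE, plateau_tol = 0.10) {
  stopifnot(nrow(curve) >= 1)
  if (all(is.na(curve$capture))) {
    stop("isopleth curve has no capture fractions; pass sites to extract_isopleths()",
         call. = FALSE)
  }
  inc <- curve$delta_area_km2
  n <- length(inc)
  mx <- max(inc)
  peak <- vapply(seq_len(n), function(i) {
    left_ok <- i == 1L || inc[i] >= inc[i - 1L]
    right_ok <- i < n && inc[i] >= inc[i + 1L]
    left_ok && right_ok
  }, logical(1))
  plateau <- c(FALSE, abs(diff(inc)) <= plateau_tol * mx)
  eligible <- (peak | plateau) & curve$capture >= min_capture
  if (any(eligible)) {
    i <- which(eligible)[1]
    fallback <- FALSE
  } else if (any(curve$capture >= min_capture)) {
    i <- which(curve$capture >= min_capture)[1]
    fallback <- TRUE
  } else {
    stop("no ODI: site capture never reaches ", min_capture, call. = FALSE)
  }
  curve$is_peak <- peak
  curve$is_plateau <- plateau
  curve$selected <- seq_len(n) == i
  structure(
    list(level_km = curve$level_km[i], area_km2 = curve$area_km2[i],
         capture = curve$capture[i], fallback = fallback, curve = curve),
    class = "odi_selection"
  )
}

#' @export
print.odi_selection <- function(x, ...) {
  cat("<odi_selection> level ", x$level_km, " km, area ",
      format(round(x$area_km2)), " km^2, capture ",
      sprintf("%.1f%%", 100 * x$capture),
      if (x$fallback) " [fallback]", "\n", sep = "")
  invisible(x)
}
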