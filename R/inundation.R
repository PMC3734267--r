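#' Bathtub sea-level-rise inundation mask
#'
#' The bathtub model floods every cell whose elevation is at or below the
#' sea-level-rise increment, ignoring hydrodynamics: cell inundated iff
#' `elevation <= rise`. Missing (`NA`) cells are never inundated. With
#' `require_sea_connectivity = TRUE` the mask is restricted to cells
#' 4-connected (through other flooded cells) to the sea, where sea cells are
#' grid-boundary cells with elevation at or below 0; this removes inland
#' depressions below the flood level that have no path to open water.
#'
#' @param grid `sivva_grid` of elevation in metres above current sea level.
#' @param rise Sea-level-rise increment in metres (>= 0).
#' @param require_sea_connectivity Restrict to sea-connected cells?
#' @return Logical matrix, same shape as the grid.
#' @export
bathtub_mask <- function(grid, rise, require_sea_connectivity = FALSE) {
  stopifnot(inherits(grid, "sivva_grid"))
  if (!is.numeric(rise) || length(rise) != 1 || rise < 0) {
    abort("`rise` must be a single non-negative number.")
  }
  elev <- grid$values
  if (all(is.na(elev))) abort("Elevation grid is entirely missing.")
  wet <- !is.na(elev) & elev <= rise
  if (!require_sea_connectivity) {
    return(wet)
  }
  nr <- nrow(elev); nc <- ncol(elev)
  boundary <- matrix(FALSE, nr, nc)
  boundary[c(1, nr), ] <- TRUE
  boundary[, c(1, nc)] <- TRUE
  reached <- boundary & !is.na(elev) & elev <= 0 & wet
  # flood fill by repeated 4-neighbour dilation within the wet set
  repeat {
    grown <- reached
    grown[-1, ] <- grown[-1, ] | reached[-nr, ]
    grown[-nr, ] <- grown[-nr, ] | reached[-1, ]
    grown[, -1] <- grown[, -1] | reached[, -nc]
    grown[, -nc] <- grown[, -nc] | reached[, -1]
    grown <- grown & wet
    if (identical(grown, reached)) break
    reached <- grown
  }
  reached
}

#' Percent of a taxon range inundated
#'
#' @param range Logical matrix (or `sivva_grid` of logicals) marking the
#'   taxon's range cells.
#' @param inundation Logical matrix from [bathtub_mask()], co-registered.
#' @return Percent of range cells inundated, in [0, 100].
#' @export
percent_range_inundated <- function(range, inundation) {
  r <- if (inherits(range, "sivva_grid")) range$values else range
  w <- if (inherits(inundation, "sivva_grid")) inundation$values else inundation
  if (!identical(dim(r), dim(w))) abort("Range and inundation masks differ in shape.")
  r <- !is.na(r) & r > 0
  if (!any(r)) abort("Range mask is empty.")
  100 * sum(r & w, na.rm = TRUE) / sum(r)
}

#' Categorical vulnerability scales
#'
#' `slr_category()` maps a percent-of-range-inundated value onto the
#' four-level sea-level-rise scale (Low 0-25%, Moderate 26-50%, High 51-75%,
#' Very high 76-100%). `criterion_category()` maps a combined 3-6 criterion
#' score onto the five-level scale (Neutral = 3, Low 3-3.75, Moderate
#' 3.75-4.5, High 4.5-5.25, Very high 5.25-6). Because inputs are continuous,
#' the published integer ranges are implemented as half-open intervals:
#' Low = [0, 25], Moderate = (25, 50], High = (50, 75], Very high = (75, 100]
#' (so 57 is High and 50 Moderate), and Neutral = {3}, Low = (3, 3.75],
#' Moderate = (3.75, 4.5], High = (4.5, 5.25], Very high = (5.25, 6].
#' Criterion scores below 3 denote beneficial responses and are handled by
#' the caller (labelled "Positive" in [make_table2()]).
#'
#' @param pct Percent values in [0, 100].
#' @param score Combined criterion scores in [3, 6].
#' @return Character vector of category labels.
#' @export
#' @examples
#' slr_category(c(57, 50, 0)) # High, Moderate, Low
#' criterion_category(c(3, 4, 6)) # Neutral, Moderate, Very high
slr_category <- function(pct) {
  if (any(!is.finite(pct)) || any(pct < 0 | pct > 100)) {
    abort("`pct` must lie in [0, 100].")
  }
  as.character(cut(
    pct, breaks = c(0, 25, 50, 75, 100),
    labels = c("Low", "Moderate", "High", "Very high"),
    include.lowest = TRUE, right = TRUE
  ))
}

#' @rdname slr_category
#' @export
criterion_category <- function(score) {
  if (any(!is.finite(score)) || any(score < 3 | score > 6)) {
    abort("`score` must lie in [3, 6]; beneficial (<3) scores are the caller's job.")
  }
  out <- as.character(cut(
    score, breaks = c(3, 3.75, 4.5, 5.25, 6),
    labels = c("Low", "Moderate", "High", "Very high"),
    right = TRUE
  ))
  out[score == 3] <- "Neutral"
  out
}

#' Geometric centre of a range mask
#'
#' The range centroid is the coordinate mean of the centres of all range
#' cells.
#'
#' @param range Logical matrix or `sivva_grid` of range membership.
#' @param grid `sivva_grid` supplying the georeferencing when `range` is a
#'   bare matrix.
#' @return Named numeric vector `c(x = , y = )`.
#' @export
range_centroid <- function(range, grid = NULL) {
  if (inherits(range, "sivva_grid")) {
    grid <- range
    r <- range$values
  } else {
    if (is.null(grid)) abort("Supply `grid` when `range` is a bare matrix.")
    r <- range
  }
  r <- !is.na(r) & r > 0
  if (!any(r)) abort("Range mask is empty.")
  cc <- cell_centres(grid)
  c(x = mean(cc$x[r]), y = mean(cc$y[r]))
}

#' Euclidean distance from a point to the nearest coast cell
#'
#' Minimum straight-line distance from `point` to the centre of any coast
#' cell, in grid units. `log_distance_to_coast()` applies the natural log
#' after flooring the distance at half a cell size, so a centroid sitting on
#' the coastline maps to `log(cellsize / 2)` rather than `-Inf`.
#'
#' @param point Numeric `c(x, y)` (e.g. from [range_centroid()]).
#' @param coast Logical matrix or `sivva_grid` marking coastline cells.
#' @param grid `sivva_grid` supplying georeferencing for a bare matrix.
#' @return A single non-negative distance.
#' @export
distance_to_coast <- function(point, coast, grid = NULL) {
  if (inherits(coast, "sivva_grid")) {
    grid <- coast
    cm <- coast$values
  } else {
    if (is.null(grid)) abort("Supply `grid` when `coast` is a bare matrix.")
    cm <- coast
  }
  cm <- !is.na(cm) & cm > 0
  if (!any(cm)) abort("Coast mask is empty.")
  cc <- cell_centres(grid)
  min(sqrt((cc$x[cm] - point[[1]])^2 + (cc$y[cm] - point[[2]])^2))
}

#' @rdname distance_to_coast
#' @export
log_distance_to_coast <- function(point, coast, grid = NULL) {
  cs <- if (inherits(coast, "sivva_grid")) coast$cellsize else grid$cellsize
  log(max(distance_to_coast(point, coast, grid), cs / 2))
}

#' Sea-level-rise exposure metrics for a set of taxon ranges
#'
#' Convenience wrapper running the full exposure chain for each range:
#' bathtub mask at `rise`, percent of range inundated, its categorical
#' label, range centroid, and (log) distance to coast.
#'
#' @param elevation `sivva_grid` of elevation.
#' @param ranges Named list of logical range matrices (names = taxon ids).
#' @param coast Logical coast mask.
#' @param rise Sea-level rise in metres (default 1).
#' @param require_sea_connectivity Passed to [bathtub_mask()].
#' @return Tibble: `taxon_id`, `rise`, `pct_inundated`, `slr_category`,
#'   `centroid_x`, `centroid_y`, `dist_coast`, `log_dist_coast`.
#' @export
exposure_metrics <- function(elevation, ranges, coast, rise = 1,
                             require_sea_connectivity = FALSE) {
  wet <- bathtub_mask(elevation, rise, require_sea_connectivity)
  purrr::imap_dfr(ranges, function(r, taxon) {
    ctr <- range_centroid(r, elevation)
    d <- distance_to_coast(ctr, coast, elevation)
    pct <- percent_range_inundated(r, wet)
    tibble::tibble(
      taxon_id = taxon, rise = rise,
      pct_inundated = pct, slr_category = slr_category(pct),
      centroid_x = ctr[["x"]], centroid_y = ctr[["y"]],
      dist_coast = d,
      log_dist_coast = log(max(d, elevation$cellsize / 2))
    )
  })
}
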