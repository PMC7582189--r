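#' Count settlements by risk class
#'
#' Each village is assigned the class of its containing cell (half-open cell
#' convention, see [locate_points()]); villages falling outside the extent or
#' on nodata cells are dropped and counted.
#'
#' @param villages a [generate_villages()] object, or a two-column matrix of
#'   x, y.
#' @param class_map a [classify_risk()] result.
#' @return list with `n_high`, `n_moderate`, `n_not_at_risk`, `n_dropped`
#'   (summing to the total number of villages).
#' @export
villages_at_risk <- function(villages, class_map) {
  pts <- if (inherits(villages, "village_points")) villages$points else
    as.matrix(villages)
  if (!length(class_map$grid)) stop("class map is empty")
  if (NROW(pts) == 0L)
    return(list(n_high = 0L, n_moderate = 0L, n_not_at_risk = 0L,
                n_dropped = 0L))
  fake <- list(layers = list(x = class_map$grid), transform = class_map$transform)
  class(fake) <- "env_stack"
  loc <- locate_points(fake, pts)
  cls <- rep(NA_integer_, NROW(pts))
  cls[loc$inside] <- class_map$grid[loc$cell[loc$inside]]
  list(n_high = sum(cls == 2L, na.rm = TRUE),
       n_moderate = sum(cls == 1L, na.rm = TRUE),
       n_not_at_risk = sum(cls == 0L, na.rm = TRUE),
       n_dropped = sum(is.na(cls)))
}

#' Suitable area of a binary or class map
#'
#' Area of all cells with class at or above 1 (suitable / at risk).  On an
#' equal-area grid pass a scalar `cell_area_km2`; on a geographic grid pass a
#' per-row vector of cell areas (e.g. scaled by the cosine of the row-centre
#' latitude).
#'
#' @param map integer matrix from [binarize()], or a [classify_risk()]
#'   result.
#' @param cell_area_km2 positive scalar, or vector with one entry per grid
#'   row.
#' @return area in km^2.
#' @export
suitable_area <- function(map, cell_area_km2) {
  g <- if (inherits(map, "risk_class_map")) map$grid else map
  if (any(cell_area_km2 <= 0)) stop("`cell_area_km2` must be positive")
  suit <- !is.na(g) & g >= 1L
  if (length(cell_area_km2) == 1L) return(sum(suit) * cell_area_km2)
  if (length(cell_area_km2) != nrow(g))
    stop("per-row `cell_area_km2` must have one entry per grid row")
  sum(rowSums(suit) * cell_area_km2)
}

#' Per-row cell areas of a geographic grid
#'
#' For a grid in degrees, the area of a cell in row `r` is the equatorial
#' cell area scaled by the cosine of the latitude of the row centre.
#'
#' @param n_rows number of grid rows.
#' @param transform geometry `c(x_origin, y_origin_top, dx, dy)` in degrees.
#' @param km_per_degree kilometres per degree at the equator (default
#'   111.32).
#' @return numeric vector of per-row cell areas in km^2.
#' @export
geographic_cell_areas <- function(n_rows, transform, km_per_degree = 111.32) {
  lat <- transform[2L] - (seq_len(n_rows) - 0.5) * transform[4L]
  transform[3L] * transform[4L] * km_per_degree^2 * cos(lat * pi / 180)
}

#' Settlement-exposure table across species
#'
#' Combines per-species village counts and suitable areas into one table of
#' the usual "villages at high risk / moderate risk / area" shape.
#'
#' @param species_results named list; each element a list with `villages`
#'   (from [villages_at_risk()]) and `area_km2`.
#' @return data.frame with columns `species`, `villages_high`,
#'   `villages_moderate`, `area_km2`.
#' @export
exposure_table <- function(species_results) {
  data.frame(
    species = names(species_results),
    villages_high = vapply(species_results,
                           function(r) as.integer(r$villages$n_high), integer(1L)),
    villages_moderate = vapply(species_results,
                               function(r) as.integer(r$villages$n_moderate),
                               integer(1L)),
    area_km2 = vapply(species_results, function(r) r$area_km2, numeric(1L)),
    row.names = NULL)
}
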