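#' Ensemble (weighted mean) of suitability surfaces
#'
#' Cellwise weighted mean of several surfaces on identical geometry; weights
#' are normalized to sum to 1 (equal by default).  Passing the per-model
#' maximized TSS values as weights gives the skill-weighted ensemble variant.
#'
#' @param surfaces list of [suitability_surface()] objects with identical
#'   geometry.
#' @param weights optional positive numeric vector, one per surface.
#' @param species_id label for the output surface.
#' @return a `suitability_surface` with `method = "ensemble"`.
#' @export
ensemble_mean <- function(surfaces, weights = NULL, species_id = NULL) {
  stopifnot(length(surfaces) >= 1L)
  check_same_geometry(surfaces)
  if (is.null(weights)) weights <- rep(1, length(surfaces))
  if (length(weights) != length(surfaces) || any(weights <= 0))
    stop("`weights` must be positive, one per surface")
  weights <- weights / sum(weights)
  g <- Reduce(`+`, Map(function(s, w) w * s$grid, surfaces, weights))
  if (is.null(species_id)) species_id <- surfaces[[1L]]$species_id
  structure(list(grid = g, mask = surfaces[[1L]]$mask,
                 transform = surfaces[[1L]]$transform,
                 species_id = species_id, method = "ensemble"),
            class = "suitability_surface")
}

#' Multiplicative multi-species risk surface
#'
#' The joint risk surface is the cellwise product of the per-species ensemble
#' suitabilities: a cell is high-risk only where *all* contributing species
#' find suitable habitat.  Any nodata contributor makes the cell nodata; the
#' product is order-invariant and never exceeds the smallest contributor.
#'
#' @param ensembles list of at least two [suitability_surface()] objects with
#'   identical geometry.
#' @return object of class `risk_surface`: list with `grid` in `[0, 1]`,
#'   `mask`, `transform`, `contributing_species`.
#' @export
risk_product <- function(ensembles) {
  if (length(ensembles) < 2L)
    stop("risk surface needs at least 2 species surfaces; got ",
         length(ensembles))
  check_same_geometry(ensembles)
  g <- Reduce(`*`, lapply(ensembles, `[[`, "grid"))
  mask <- Reduce(`|`, lapply(ensembles, function(s) s$mask | is.na(s$grid)))
  g[mask] <- NA_real_
  structure(list(grid = g, mask = mask,
                 transform = ensembles[[1L]]$transform,
                 contributing_species = vapply(ensembles, `[[`, character(1L),
                                               "species_id")),
            class = "risk_surface")
}

check_same_geometry <- function(surfaces) {
  ref <- surfaces[[1L]]
  for (s in surfaces[-1L])
    if (!identical(dim(s$grid), dim(ref$grid)) ||
        !isTRUE(all.equal(s$transform, ref$transform)))
      stop("surfaces differ in geometry")
  invisible(TRUE)
}

#' Binarize a suitability surface
#'
#' Suitable (1) where the value is at or above the threshold (closed rule),
#' unsuitable (0) below; nodata stays nodata.  The threshold is typically the
#' maxSSS threshold from [max_sss_threshold()].
#'
#' @param surface a [suitability_surface()] (or `risk_surface`).
#' @param threshold cut-off in (0, 1).
#' @return integer matrix of 0/1 with `NA` on nodata.
#' @export
binarize <- function(surface, threshold) {
  if (threshold <= 0 || threshold >= 1) stop("`threshold` must be in (0, 1)")
  g <- surface$grid
  out <- ifelse(g >= threshold, 1L, 0L)
  out[is.na(g)] <- NA_integer_
  out
}

#' Three-class risk map
#'
#' Classifies a surface into 0 = not at risk (`value < t_suitable`),
#' 1 = moderate (`t_suitable <= value < t_high`), 2 = high
#' (`value >= t_high`, closed upper rule).
#'
#' @param surface a [suitability_surface()] or `risk_surface`.
#' @param t_suitable,t_high class thresholds with
#'   `0 < t_suitable < t_high < 1`.
#' @return object of class `risk_class_map`: list with integer `grid`
#'   (0/1/2, `NA` nodata), `mask`, `transform`, `thresholds`.
#' @export
classify_risk <- function(surface, t_suitable, t_high) {
  if (!(0 < t_suitable && t_suitable < t_high && t_high < 1))
    stop("need 0 < t_suitable < t_high < 1")
  g <- surface$grid
  cls <- ifelse(g >= t_high, 2L, ifelse(g >= t_suitable, 1L, 0L))
  cls[is.na(g)] <- NA_integer_
  structure(list(grid = cls, mask = is.na(g), transform = surface$transform,
                 thresholds = c(t_suitable = t_suitable, t_high = t_high)),
            class = "risk_class_map")
}
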