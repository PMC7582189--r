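#' Generate a synthetic environmental landscape
#'
#' Builds a stack of spatially autocorrelated, mutually correlated standard
#' Gaussian layers, emulating the statistical structure of a real predictor
#' stack (climate, vegetation, human footprint, topographic heterogeneity)
#' without any external rasters.
#'
#' Each layer is a linear mix of one shared white-noise field and one
#' layer-specific field, smoothed with a Gaussian kernel whose standard
#' deviation is the layer's `autocorrelation_length` (in cells), then
#' standardized to mean 0, sd 1 over non-nodata cells.  A layer with target
#' correlation `r` gets mixing weight `sign(r) * sqrt(|r|)` on the shared
#' field, so two layers with targets `r_i`, `r_j` have pairwise correlation
#' `sign(r_i) sign(r_j) sqrt(|r_i r_j|)`; with a common target `r >= 0` every
#' pair correlates at `r` (exactly in expectation when autocorrelation
#' lengths are shared).
#'
#' @param n_rows,n_cols grid dimensions, at least 8.
#' @param layer_specs data frame (or list coercible to one) with columns
#'   `name`, `autocorrelation_length` (cells; 0 = white noise) and
#'   `target_correlation` (absolute value below 0.9).  See
#'   [default_layer_specs()].
#' @param seed integer seed; the landscape is a pure function of the
#'   arguments and the seed.
#' @param nodata_mask optional logical matrix marking nodata cells.
#' @param cell_size cell edge length in km (projected equal-area geometry).
#' @return an [env_stack()].
#' @examples
#' st <- generate_landscape(50, 50, default_layer_specs(), seed = 1)
#' sapply(st$layers, sd)
#' @export
generate_landscape <- function(n_rows, n_cols, layer_specs = default_layer_specs(),
                               seed, nodata_mask = NULL, cell_size = 1) {
  if (n_rows < 8 || n_cols < 8) stop("grid must be at least 8 x 8")
  specs <- as.data.frame(layer_specs, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "autocorrelation_length", "target_correlation")
                %in% names(specs)))
  if (any(abs(specs$target_correlation) >= 0.9))
    stop("|target_correlation| must be < 0.9")
  set.seed(seed)
  common <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  layers <- vector("list", nrow(specs))
  names(layers) <- specs$name
  for (i in seq_len(nrow(specs))) {
    a <- sign(specs$target_correlation[i]) * sqrt(abs(specs$target_correlation[i]))
    own <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
    f <- gaussian_smooth(a * common + sqrt(1 - a^2) * own,
                         specs$autocorrelation_length[i])
    keep <- if (is.null(nodata_mask)) f else f[!nodata_mask]
    f <- (f - mean(keep)) / stats::sd(keep)
    layers[[i]] <- f
  }
  env_stack(layers,
            transform = c(0, n_rows * cell_size, cell_size, cell_size),
            nodata_mask = nodata_mask)
}

#' Default predictor specifications for the synthetic landscape
#'
#' Seven layers named after the predictor families used in venomous-snake
#' suitability modelling (temperature seasonality, annual precipitation,
#' precipitation seasonality, driest-quarter precipitation, NDVI, human
#' footprint, topographic heterogeneity), with a shared autocorrelation
#' length of 8 cells and a common pairwise correlation of 0.3 — low enough
#' that every variance inflation factor stays well under the screening
#' threshold (about 1.3 for seven equicorrelated layers).
#'
#' @return data.frame with columns `name`, `autocorrelation_length`,
#'   `target_correlation`.
#' @export
default_layer_specs <- function() {
  data.frame(
    name = c("bio4", "bio12", "bio15", "bio17", "ndvi", "hfp", "sd_elev"),
    autocorrelation_length = 8,
    target_correlation = 0.3,
    stringsAsFactors = FALSE)
}

# Separable Gaussian blur; sd = length in cells; length 0 returns the input.
# Rows of the smoothing operator are renormalized so edges are unbiased.
gaussian_smooth <- function(mat, length) {
  if (length <= 0) return(mat)
  smoother <- function(n) {
    idx <- seq_len(n)
    k <- exp(-outer(idx, idx, `-`)^2 / (2 * length^2))
    k / rowSums(k)
  }
  smoother(nrow(mat)) %*% mat %*% t(smoother(ncol(mat)))
}

#' Define a virtual species with known suitability truth
#'
#' True habitat suitability is logistic-linear in the stack's layers:
#' `plogis(intercept + sum_j coefficients[j] * layer_j)`, evaluated cellwise.
#' Because the truth is known, downstream models can be validated by
#' parameter and surface recovery.
#'
#' @param stack an [env_stack()].
#' @param coefficients named numeric vector; names must be layer names of
#'   `stack` (log-odds of suitability per unit of the standardized layer).
#' @param intercept scalar log-odds offset controlling overall prevalence.
#' @param species_id text label.
#' @return object of class `virtual_species` with elements `species_id`,
#'   `coefficients`, `intercept`, `true_suitability` (matrix in `[0, 1]`,
#'   `NA` on nodata), and `stack_transform`.
#' @export
define_virtual_species <- function(stack, coefficients, intercept = 0,
                                   species_id = "sp") {
  bad <- setdiff(names(coefficients), layer_names(stack))
  if (length(bad))
    stop("unknown layer name(s): ", paste(bad, collapse = ", "))
  d <- dim(stack)
  eta <- matrix(intercept, d[1L], d[2L])
  for (nm in names(coefficients))
    eta <- eta + coefficients[[nm]] * stack$layers[[nm]]
  suit <- stats::plogis(eta)
  suit[stack$mask] <- NA_real_
  structure(list(species_id = species_id, coefficients = coefficients,
                 intercept = intercept, true_suitability = suit,
                 stack_transform = stack$transform),
            class = "virtual_species")
}

#' Sample presence points proportionally to true suitability
#'
#' Cells are drawn with replacement with probability proportional to the
#' species' true suitability (nodata cells excluded); each presence is placed
#' at its cell centre.  This emulates opportunistic occurrence records whose
#' density follows habitat quality.
#'
#' @param vs a [define_virtual_species()] object.
#' @param n number of presences (the study organisms had 37–89 records).
#' @param seed integer seed.
#' @param deduplicate if `TRUE`, thin to at most one presence per cell
#'   (returned count may then be below `n`); off by default.
#' @return object of class `occurrence_set`: list with `species_id`, `points`
#'   (n x 2 matrix of x, y) and `source_tag`.
#' @export
sample_presences <- function(vs, n, seed, deduplicate = FALSE) {
  stopifnot(n >= 1)
  suit <- as.vector(vs$true_suitability)
  ok <- which(!is.na(suit) & suit > 0)
  if (length(ok) == 0L || sum(suit[ok]) <= 0)
    stop("true suitability is zero everywhere; cannot sample presences")
  set.seed(seed)
  cells <- ok[sample.int(length(ok), n, replace = TRUE, prob = suit[ok])]
  if (deduplicate) cells <- unique(cells)
  fake_stack <- list(layers = list(x = vs$true_suitability),
                     transform = vs$stack_transform)
  class(fake_stack) <- "env_stack"
  pts <- cell_centers(fake_stack, cells)
  structure(list(species_id = vs$species_id, points = pts,
                 source_tag = "synthetic"),
            class = "occurrence_set")
}

#' Scatter settlement points uniformly over the valid extent
#'
#' Villages are placed uniformly at random over non-nodata cells (uniform
#' cell choice, then uniform position within the cell, which is exactly
#' uniform over the valid area on an equal-area grid).
#'
#' @param stack an [env_stack()].
#' @param n number of villages (`n = 0` gives an empty set).
#' @param seed integer seed.
#' @return object of class `village_points`: list with `points` (n x 2
#'   matrix) and unique `ids`.
#' @export
generate_villages <- function(stack, n, seed) {
  stopifnot(n >= 0)
  ok <- valid_cells(stack)
  if (length(ok) == 0L) stop("stack is fully masked; no valid extent")
  set.seed(seed)
  if (n == 0L) {
    pts <- cbind(x = numeric(0), y = numeric(0))
  } else {
    cells <- ok[sample.int(length(ok), n, replace = TRUE)]
    ctr <- cell_centers(stack, cells)
    tr <- stack$transform
    pts <- cbind(x = ctr[, 1L] + stats::runif(n, -0.5, 0.5) * tr[3L],
                 y = ctr[, 2L] + stats::runif(n, -0.5, 0.5) * tr[4L])
  }
  structure(list(points = pts,
                 ids = sprintf("v%06d", seq_len(n))),
            class = "village_points")
}

#' Write point sets as CSV
#'
#' Occurrences are written with header `species,x,y`; villages with
#' `id,x,y`.
#'
#' @param x an `occurrence_set` or `village_points` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_points_csv <- function(x, path) {
  df <- if (inherits(x, "occurrence_set")) {
    data.frame(species = x$species_id, x = x$points[, 1L], y = x$points[, 2L])
  } else if (inherits(x, "village_points")) {
    data.frame(id = x$ids, x = x$points[, 1L], y = x$points[, 2L])
  } else stop("unsupported point set class")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
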