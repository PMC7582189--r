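#' Topographic heterogeneity (moving-window SD of elevation)
#'
#' Each cell receives the sample standard deviation of elevation over the
#' `window` x `window` neighbourhood centred on it, the standard measure of
#' terrain roughness used as a topographic predictor.  Edge cells use the
#' truncated window so the output extent equals the input extent.  Nodata
#' cells stay nodata and are excluded from their neighbours' windows; a cell
#' whose window holds fewer than two valid values gets 0.
#'
#' @param elevation numeric matrix (`NA` = nodata).
#' @param window odd window edge length, at least 3.
#' @return matrix of the same dimensions.
#' @examples
#' topographic_heterogeneity(matrix(1:25, 5), window = 3)
#' @export
topographic_heterogeneity <- function(elevation, window = 3) {
  if (window %% 2 != 1 || window < 3) stop("`window` must be an odd integer >= 3")
  h <- (window - 1L) %/% 2L
  na <- is.na(elevation)
  x <- elevation; x[na] <- 0
  n  <- box_sum(matrix(as.numeric(!na), nrow(elevation)), h)
  s1 <- box_sum(x, h)
  s2 <- box_sum(x^2, h)
  v <- (s2 - s1^2 / pmax(n, 1)) / pmax(n - 1, 1)
  out <- sqrt(pmax(v, 0))
  out[n < 2] <- 0
  out[na] <- NA_real_
  out
}

# Moving-window sum with truncated edges, via running sums along each
# dimension in turn.
box_sum <- function(mat, h) {
  run <- function(m) {
    n <- nrow(m)
    cs <- rbind(0, apply(m, 2L, cumsum))
    hi <- pmin(seq_len(n) + h, n) + 1L
    lo <- pmax(seq_len(n) - h, 1L)
    cs[hi, , drop = FALSE] - cs[lo, , drop = FALSE]
  }
  t(run(t(run(mat))))
}

#' Extract predictor values at points
#'
#' Builds the design matrix behind collinearity screening and model fitting:
#' row *i* holds the layer values of the cell containing point *i* (half-open
#' cell convention, see [locate_points()]).  Points falling outside the
#' extent or on nodata cells are dropped and counted.
#'
#' @param stack an [env_stack()].
#' @param points two-column matrix/data frame of x, y, or an
#'   `occurrence_set` / `village_points` object.
#' @param provenance text tag stored on the result (`"occurrences"`,
#'   `"background"`, `"cells"`, ...).
#' @return numeric matrix with one named column per layer; attributes
#'   `n_dropped` (points lost to the mask or extent), `cells` (cell index per
#'   retained row) and `provenance`.
#' @export
extract_at_points <- function(stack, points, provenance = "points") {
  if (inherits(points, "occurrence_set") || inherits(points, "village_points"))
    points <- points$points
  if (NROW(points) == 0L) stop("`points` is empty")
  loc <- locate_points(stack, points)
  keep <- loc$inside & !is.na(loc$cell) & !stack$mask[loc$cell]
  if (!any(keep))
    stop("all points fall outside the extent or on nodata cells")
  cells <- loc$cell[keep]
  m <- vapply(stack$layers, function(l) l[cells], numeric(length(cells)))
  if (length(cells) == 1L) m <- matrix(m, nrow = 1L,
                                       dimnames = list(NULL, layer_names(stack)))
  attr(m, "n_dropped") <- sum(!keep)
  attr(m, "cells") <- cells
  attr(m, "provenance") <- provenance
  m
}

# Design matrix of every valid cell in the stack.
extract_all_cells <- function(stack) {
  cells <- valid_cells(stack)
  m <- vapply(stack$layers, function(l) l[cells], numeric(length(cells)))
  attr(m, "cells") <- cells
  attr(m, "provenance") <- "cells"
  m
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)`, with `R^2_j` from the ordinary least squares
#' regression of column *j* on all other columns (plus intercept).  Exactly
#' collinear columns are reported as `Inf` rather than raising an error.
#'
#' @param m numeric matrix with at least two named columns and more rows than
#'   columns.
#' @return named numeric vector of VIFs (>= 1, or `Inf`).
#' @examples
#' compute_vif(matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b"))))
#' @export
compute_vif <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2L) stop("need at least 2 columns")
  if (nrow(m) <= ncol(m)) stop("need more rows than columns")
  vif <- vapply(seq_len(ncol(m)), function(j) {
    y <- m[, j]
    sst <- sum((y - mean(y))^2)
    if (sst == 0) return(Inf)  # constant column: flagged, not an error
    fit <- stats::lm.fit(cbind(1, m[, -j, drop = FALSE]), y)
    r2 <- 1 - sum(fit$residuals^2) / sst
    if (r2 >= 1 - 1e-10) Inf else 1 / (1 - r2)
  }, numeric(1L))
  names(vif) <- colnames(m)
  vif
}

#' Stepwise VIF screening
#'
#' Iteratively removes the variable with the largest VIF, recomputing VIFs
#' after every drop, until all remaining VIFs fall below `threshold` or fewer
#' than two variables remain.  This is the usual collinearity screen applied
#' to a candidate predictor pool before suitability modelling.
#'
#' @param m numeric matrix of candidate predictors (named columns).
#' @param threshold VIF threshold, greater than 1; the default 5 retains any
#'   predictor set whose collinearity is as low as a typical screened
#'   bioclim/NDVI/footprint stack (VIFs of roughly 1.3–3.3).
#' @return object of class `vif_report`: list with `vif` (final VIFs of the
#'   retained set), `retained`, `dropped` (in drop order), `threshold`.
#' @export
vif_screen <- function(m, threshold = 5) {
  if (threshold <= 1) stop("`threshold` must exceed 1")
  m <- as.matrix(m)
  dropped <- character(0)
  repeat {
    if (ncol(m) < 2L) { vif <- stats::setNames(rep(1, ncol(m)), colnames(m)); break }
    vif <- compute_vif(m)
    if (max(vif) < threshold) break
    worst <- colnames(m)[which.max(vif)]
    dropped <- c(dropped, worst)
    m <- m[, setdiff(colnames(m), worst), drop = FALSE]
  }
  structure(list(vif = vif, retained = colnames(m), dropped = dropped,
                 threshold = threshold),
            class = "vif_report")
}

#' @export
print.vif_report <- function(x, ...) {
  cat(sprintf("VIF screen (threshold %g): %d retained, %d dropped\n",
              x$threshold, length(x$retained), length(x$dropped)))
  print(round(x$vif, 3))
  if (length(x$dropped)) cat("dropped:", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' Write a VIF report as JSON and CSV
#'
#' The CSV mirrors a variable/VIF/retained table; the JSON carries the full
#' report.
#'
#' @param report a [vif_screen()] result.
#' @param path_json,path_csv output paths (either may be `NULL` to skip).
#' @return `report`, invisibly.
#' @export
write_vif_report <- function(report, path_json = NULL, path_csv = NULL) {
  if (!is.null(path_json))
    jsonlite::write_json(
      list(threshold = report$threshold, vif = as.list(report$vif),
           retained = report$retained, dropped = report$dropped),
      path_json, auto_unbox = TRUE, digits = 10)
  if (!is.null(path_csv)) {
    vars <- c(report$retained, report$dropped)
    utils::write.csv(
      data.frame(variable = vars,
                 vif = round(unname(report$vif[match(vars, names(report$vif))]), 4),
                 retained = vars %in% report$retained),
      path_csv, row.names = FALSE, quote = FALSE)
  }
  invisible(report)
}
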