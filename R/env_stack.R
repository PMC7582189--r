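#' Multi-layer environmental stack
#'
#' An `env_stack` holds aligned gridded environmental predictors sharing one
#' geometry and one nodata mask.  Layers are plain numeric matrices (rows =
#' grid rows from the top, columns = grid columns from the left); masked cells
#' are `NA` in every layer.  The affine geometry is the vector
#' `c(x_origin, y_origin, cell_size_x, cell_size_y)` where `(x_origin,
#' y_origin)` is the *top-left corner* of the grid in map units and both cell
#' sizes are positive.  The default synthetic geometry is a projected
#' equal-area grid with cell sizes in km, so every cell covers the same area.
#'
#' @param layers named list of numeric matrices, all with identical
#'   dimensions.  Names are the layer names and must be unique.
#' @param transform numeric length-4: `c(x_origin, y_origin, cell_size_x,
#'   cell_size_y)`; `y_origin` is the top edge.
#' @param nodata_mask logical matrix, `TRUE` where there is no data; defaults
#'   to all `FALSE`.  The mask is imposed on every layer (`NA`).
#' @param crs_tag text tag describing the coordinate system; either
#'   `"projected-equal-area"` (default, map units = km) or a free-form
#'   geographic tag.
#' @return an object of class `env_stack` with elements `layers`, `mask`,
#'   `transform`, `crs_tag`.
#' @examples
#' st <- env_stack(list(a = matrix(rnorm(100), 10)))
#' dim(st)
#' @export
env_stack <- function(layers, transform = NULL, nodata_mask = NULL,
                      crs_tag = "projected-equal-area") {
  if (!is.list(layers) || length(layers) == 0L)
    stop("`layers` must be a non-empty named list of matrices")
  nm <- names(layers)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
    stop("layer names must be present and unique")
  d <- dim(layers[[1L]])
  for (l in layers)
    if (!is.matrix(l) || !identical(dim(l), d))
      stop("all layers must be matrices with identical dimensions")
  if (is.null(transform)) transform <- c(0, d[1L], 1, 1)
  transform <- as.numeric(transform)
  if (length(transform) != 4L || any(transform[3:4] <= 0))
    stop("`transform` must be c(x_origin, y_origin, dx, dy) with dx, dy > 0")
  if (is.null(nodata_mask)) nodata_mask <- matrix(FALSE, d[1L], d[2L])
  if (!is.logical(nodata_mask) || !identical(dim(nodata_mask), d))
    stop("`nodata_mask` must be a logical matrix matching the layer dimensions")
  layers <- lapply(layers, function(l) { l[nodata_mask] <- NA_real_; l })
  structure(list(layers = layers, mask = nodata_mask,
                 transform = transform, crs_tag = crs_tag),
            class = "env_stack")
}

#' @export
dim.env_stack <- function(x) dim(x$layers[[1L]])

#' @export
print.env_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("env_stack: %d layers, %d x %d cells, %d masked (%s)\n",
              length(x$layers), d[1L], d[2L], sum(x$mask), x$crs_tag))
  cat("layers:", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

layer_names <- function(stack) names(stack$layers)

#' Map coordinates of cell centres
#'
#' @param stack an `env_stack`.
#' @param cells integer vector of cell indices in R's column-major matrix
#'   order.
#' @return two-column matrix of `x`, `y` centre coordinates.
#' @keywords internal
cell_centers <- function(stack, cells) {
  d <- dim(stack)
  tr <- stack$transform
  r <- (cells - 1L) %% d[1L] + 1L
  c <- (cells - 1L) %/% d[1L] + 1L
  cbind(x = tr[1L] + (c - 0.5) * tr[3L],
        y = tr[2L] - (r - 0.5) * tr[4L])
}

#' Locate points in grid cells
#'
#' Uses the half-open cell convention: a cell owns `x` in `[left, right)` and
#' `y` in `(top, bottom]` (y decreasing downwards), so no point belongs to two
#' cells and a point exactly on a shared corner is assigned deterministically.
#'
#' @param stack an `env_stack` (only its geometry is used).
#' @param points two-column matrix or data frame of `x`, `y` coordinates.
#' @return data.frame with columns `row`, `col`, `cell` (column-major index),
#'   and `inside` (logical; `FALSE` when the point falls off the grid).
#' @keywords internal
locate_points <- function(stack, points) {
  points <- as.matrix(points[, 1:2, drop = FALSE])
  d <- dim(stack)
  tr <- stack$transform
  col <- floor((points[, 1L] - tr[1L]) / tr[3L]) + 1L
  row <- ceiling((tr[2L] - points[, 2L]) / tr[4L])
  inside <- col >= 1L & col <= d[2L] & row >= 1L & row <= d[1L]
  cell <- ifelse(inside, (col - 1L) * d[1L] + row, NA_integer_)
  data.frame(row = row, col = col, cell = cell, inside = inside)
}

valid_cells <- function(stack) which(!stack$mask)

#' Write and read single layers as ESRI ASCII grids
#'
#' Plain-text raster interchange.  `write_ascii_grid()` stores one matrix with
#' the stack geometry in the standard ESRI ASCII (.asc) header;
#' `read_ascii_grid()` reads it back as a list with `grid` and `transform`.
#'
#' @param grid numeric matrix (`NA` = nodata).
#' @param transform stack geometry `c(x_origin, y_origin, dx, dy)`
#'   (top-left origin); the format itself records the lower-left corner.
#' @param path file path.
#' @param digits significant digits written (fixed so reruns are
#'   byte-identical).
#' @return `write_ascii_grid()` returns `path` invisibly; `read_ascii_grid()`
#'   returns `list(grid, transform)`.
#' @export
write_ascii_grid <- function(grid, transform, path, digits = 7) {
  if (transform[3L] != transform[4L])
    stop("ESRI ASCII grids require square cells")
  nr <- nrow(grid); nc <- ncol(grid)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.10g", transform[1L]),
    sprintf("yllcorner %.10g", transform[2L] - nr * transform[4L]),
    sprintf("cellsize %.10g", transform[3L]),
    "NODATA_value -9999"), con)
  g <- grid
  g[is.na(g)] <- -9999
  fmt <- paste0("%.", digits, "g")
  for (r in seq_len(nr))
    writeLines(paste(sprintf(fmt, g[r, ]), collapse = " "), con)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- function(i) as.numeric(strsplit(hdr[i], "\\s+")[[1L]][2L])
  nc <- as.integer(kv(1L)); nr <- as.integer(kv(2L))
  xll <- kv(3L); yll <- kv(4L); cs <- kv(5L); nd <- kv(6L)
  vals <- scan(path, skip = 6L, quiet = TRUE)
  g <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  g[g == nd] <- NA_real_
  list(grid = g, transform = c(xll, yll + nr * cs, cs, cs))
}

#' Write an `env_stack` to a directory of ASCII grids
#'
#' One `<layer>.asc` file per layer, plus `stack.json` recording layer order,
#' geometry and CRS tag.
#'
#' @param stack an `env_stack`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_env_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in layer_names(stack))
    write_ascii_grid(stack$layers[[nm]], stack$transform,
                     file.path(dir, paste0(nm, ".asc")))
  meta <- list(layer_names = layer_names(stack),
               transform = stack$transform, crs_tag = stack$crs_tag)
  jsonlite::write_json(meta, file.path(dir, "stack.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_env_stack
#' @export
read_env_stack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "stack.json"),
                              simplifyVector = TRUE)
  layers <- lapply(meta$layer_names, function(nm)
    read_ascii_grid(file.path(dir, paste0(nm, ".asc")))$grid)
  names(layers) <- meta$layer_names
  mask <- Reduce(`|`, lapply(layers, is.na))
  env_stack(layers, transform = meta$transform, nodata_mask = mask,
            crs_tag = meta$crs_tag)
}
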