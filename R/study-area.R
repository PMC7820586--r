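#' Define a rectangular study area on a regular grid
#'
#' A study area is the common georeference for every raster, point set and
#' aggregation in the pipeline: a north-up regular grid in an abstract
#' projected CRS (map units are metres), with an optional in-area mask.
#' Rows are stored top-down (row 1 is the northern edge), matching the usual
#' raster convention of an upper-left origin.
#'
#' @param width,height extent of the area in map units; both must be > 0.
#' @param cell grid resolution in map units per pixel.
#' @param xmin,ymin coordinates of the lower-left corner.
#' @param mask optional logical matrix (`nrow x ncol` as implied by the
#'   extent and cell size) marking in-area cells; default all `TRUE`.
#' @return An object of class `study_area`.
#' @export
study_area <- function(width, height, cell, xmin = 0, ymin = 0, mask = NULL) {
  if (!is.numeric(width) || !is.numeric(height) || width <= 0 || height <= 0)
    stop_spatrisk("parameter", "study area extent must be strictly positive in both axes")
  if (!is.numeric(cell) || cell <= 0)
    stop_spatrisk("parameter", "cell_size must be > 0")
  nr <- as.integer(round(height / cell))
  nc <- as.integer(round(width / cell))
  if (nr < 1L || nc < 1L)
    stop_spatrisk("parameter", "extent smaller than one cell")
  if (is.null(mask)) mask <- matrix(TRUE, nr, nc)
  if (!is.matrix(mask) || !is.logical(mask) || nrow(mask) != nr || ncol(mask) != nc)
    stop_spatrisk("parameter", sprintf("mask must be a %d x %d logical matrix", nr, nc))
  if (!any(mask))
    stop_spatrisk("parameter", "mask must contain at least one in-area cell")
  structure(
    list(xmin = xmin, ymin = ymin, cell = cell,
         nrow = nr, ncol = nc,
         xmax = xmin + nc * cell, ymax = ymin + nr * cell,
         mask = mask),
    class = "study_area")
}

#' @export
print.study_area <- function(x, ...) {
  cat(sprintf("<study_area> %d x %d cells @ %g map units, extent [%g, %g] x [%g, %g], %d in-mask cells\n",
              x$nrow, x$ncol, x$cell, x$xmin, x$xmax, x$ymin, x$ymax, sum(x$mask)))
  invisible(x)
}

#' Coordinates of all cell centers of a study area
#'
#' @param area a `study_area`.
#' @param mask_only return only in-mask cells.
#' @return data.frame with columns `row`, `col`, `x`, `y`.
#' @export
cell_centers <- function(area, mask_only = FALSE) {
  stopifnot(inherits(area, "study_area"))
  rows <- rep(seq_len(area$nrow), times = area$ncol)
  cols <- rep(seq_len(area$ncol), each = area$nrow)
  out <- data.frame(
    row = rows, col = cols,
    x = area$xmin + (cols - 0.5) * area$cell,
    y = area$ymax - (rows - 0.5) * area$cell)
  if (mask_only) out <- out[as.vector(area$mask), , drop = FALSE]
  out
}

#' Locate points on the grid of a study area
#'
#' Point-in-cell assignment uses half-open intervals `[x0, x0 + w)` in x and
#' `(y0 - h, y0]` in y, so a point on a shared cell edge belongs to exactly
#' one cell and is never counted twice.
#'
#' @param area a `study_area`.
#' @param x,y point coordinates in map units.
#' @return data.frame with `row`, `col` (NA for points outside the extent)
#'   and `inside` (TRUE when the containing cell exists and is in the mask).
#' @export
locate_cells <- function(area, x, y) {
  stopifnot(inherits(area, "study_area"), length(x) == length(y))
  col <- floor((x - area$xmin) / area$cell) + 1
  row <- floor((area$ymax - y) / area$cell) + 1
  # top edge of the area belongs to row 1, right edge is outside (half-open)
  row[y == area$ymax] <- 1
  bad <- row < 1 | row > area$nrow | col < 1 | col > area$ncol |
    !is.finite(x) | !is.finite(y)
  row[bad] <- NA_integer_
  col[bad] <- NA_integer_
  inside <- !bad
  inside[inside] <- area$mask[cbind(row[inside], col[inside])]
  data.frame(row = as.integer(row), col = as.integer(col), inside = inside)
}

#' Construct a criterion raster over a study area
#'
#' A criterion raster is one environmental variable gridded on a study
#' area's grid; out-of-mask cells are nodata (`NA`).
#'
#' @param area a `study_area`.
#' @param values numeric matrix matching the area grid.
#' @param name variable name.
#' @return An object of class `criterion_raster`.
#' @export
criterion_raster <- function(area, values, name = "criterion") {
  stopifnot(inherits(area, "study_area"))
  if (!is.matrix(values) || nrow(values) != area$nrow || ncol(values) != area$ncol)
    stop_spatrisk("parameter", "values must match the study-area grid")
  values[!area$mask] <- NA_real_
  structure(list(area = area, values = values, name = name),
            class = "criterion_raster")
}

#' @export
print.criterion_raster <- function(x, ...) {
  v <- x$values[x$area$mask]
  cat(sprintf("<criterion_raster> '%s' %d x %d, valid range [%.4g, %.4g]\n",
              x$name, x$area$nrow, x$area$ncol, min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
  invisible(x)
}

#' Extract raster values at point locations
#'
#' @param raster a `criterion_raster`.
#' @param x,y point coordinates.
#' @return numeric vector; NA for points outside the mask / on nodata.
#' @export
raster_value_at <- function(raster, x, y) {
  stopifnot(inherits(raster, "criterion_raster"))
  loc <- locate_cells(raster$area, x, y)
  out <- rep(NA_real_, length(x))
  ok <- loc$inside
  out[ok] <- raster$values[cbind(loc$row[ok], loc$col[ok])]
  out
}

same_grid <- function(a, b, tol = 1e-9) {
  abs(a$xmin - b$xmin) < tol && abs(a$ymin - b$ymin) < tol &&
    abs(a$cell - b$cell) < tol && a$nrow == b$nrow && a$ncol == b$ncol
}

#' Case point set
#'
#' Labeled point locations: presences (label 1) and pseudo-absences
#' (label 0), optionally carrying a train/test partition.
#'
#' @param x,y coordinates in map units.
#' @param label 0/1 vector (default all 1).
#' @param partition optional character vector `"train"`/`"test"`/NA.
#' @return An object of class `case_points` (a data.frame).
#' @export
case_points <- function(x, y, label = 1, partition = NA_character_) {
  stopifnot(length(x) == length(y))
  label <- rep_len(as.integer(label), length(x))
  if (!all(label %in% c(0L, 1L)))
    stop_spatrisk("parameter", "labels must be 0 or 1")
  partition <- rep_len(as.character(partition), length(x))
  bad <- !is.na(partition) & !partition %in% c("train", "test")
  if (any(bad)) stop_spatrisk("parameter", "partition must be 'train', 'test' or NA")
  structure(data.frame(x = x, y = y, label = label, partition = partition,
                       stringsAsFactors = FALSE),
            class = c("case_points", "data.frame"))
}

# internal error constructor: every package error carries a class so the CLI
# can map error families to exit codes
stop_spatrisk <- function(kind, msg, ...) {
  stop(structure(
    class = c(paste0("spatrisk_", kind, "_error"), "spatrisk_error",
              "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))))
}
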