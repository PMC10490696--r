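#' Categorical land-cover raster
#'
#' A light-weight container for one epoch of a categorical land-cover map on a
#' regular equal-area grid: an integer matrix of class codes plus the cell
#' area. Code `nodata` (default 0) marks cells outside the study mask.
#'
#' @param values Integer matrix of class codes.
#' @param cell_area Cell area in km^2 (default 1).
#' @param nodata Integer nodata code (default 0).
#' @param classes Named integer vector of valid class codes
#'   (default [lc_classes()]).
#' @return An object of class `lc_raster`.
#' @export
lc_raster <- function(values, cell_area = 1, nodata = 0L,
                      classes = lc_classes()) {
  if (!is.matrix(values))
    stop("`values` must be a matrix of class codes", call. = FALSE)
  storage.mode(values) <- "integer"
  bad <- setdiff(unique(as.vector(values)), c(as.integer(nodata), unname(classes)))
  if (length(bad))
    stop("unknown class code(s) in raster: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!is.numeric(cell_area) || length(cell_area) != 1L || cell_area <= 0)
    stop("`cell_area` must be a single positive number (km^2)", call. = FALSE)
  structure(
    list(values = values, cell_area = cell_area,
         nodata = as.integer(nodata), classes = classes),
    class = "lc_raster")
}

#' @export
print.lc_raster <- function(x, ...) {
  v <- x$values
  n_valid <- sum(v != x$nodata)
  cat(sprintf("<lc_raster> %d x %d cells, %.3g km^2/cell, %d valid (%.1f%%)\n",
              nrow(v), ncol(v), x$cell_area, n_valid,
              100 * n_valid / length(v)))
  tab <- tabulate(v[v != x$nodata], nbins = max(x$classes))
  names(tab)[x$classes] <- names(x$classes)
  print(tab[x$classes])
  invisible(x)
}

#' @export
dim.lc_raster <- function(x) dim(x$values)

#' Multi-epoch landscape series
#'
#' An ordered set of co-registered [lc_raster] maps, one per epoch.
#'
#' @param rasters List of `lc_raster` objects sharing shape, cell area and
#'   nodata code.
#' @param epochs Numeric year labels, strictly increasing, one per raster.
#' @return An object of class `landscape_series`.
#' @export
landscape_series <- function(rasters, epochs) {
  if (!length(rasters) || length(rasters) != length(epochs))
    stop("`rasters` and `epochs` must be non-empty and of equal length",
         call. = FALSE)
  if (any(diff(epochs) <= 0))
    stop("`epochs` must be strictly increasing", call. = FALSE)
  d <- dim(rasters[[1L]]$values)
  for (r in rasters) {
    if (!inherits(r, "lc_raster")) stop("all elements must be lc_raster")
    if (!identical(dim(r$values), d))
      stop("all rasters must share the same shape", call. = FALSE)
    if (r$cell_area != rasters[[1L]]$cell_area ||
        r$nodata != rasters[[1L]]$nodata)
      stop("all rasters must share cell_area and nodata", call. = FALSE)
  }
  structure(list(rasters = rasters, epochs = as.numeric(epochs),
                 cell_area = rasters[[1L]]$cell_area,
                 nodata = rasters[[1L]]$nodata),
            class = "landscape_series")
}

#' @export
print.landscape_series <- function(x, ...) {
  cat(sprintf("<landscape_series> %d epochs (%s), %d x %d cells, %.3g km^2/cell\n",
              length(x$epochs), paste(x$epochs, collapse = ", "),
              nrow(x$rasters[[1L]]$values), ncol(x$rasters[[1L]]$values),
              x$cell_area))
  invisible(x)
}

#' Extract the raster for a given epoch
#'
#' @param series A [landscape_series].
#' @param year Epoch year label present in `series$epochs`.
#' @return The `lc_raster` for that epoch.
#' @export
epoch_raster <- function(series, year) {
  i <- match(year, series$epochs)
  if (is.na(i))
    stop("epoch ", year, " not in series (have: ",
         paste(series$epochs, collapse = ", "), ")", call. = FALSE)
  series$rasters[[i]]
}

#' Write / read a landscape series as TIFF rasters plus sidecar metadata
#'
#' Each epoch is stored as a single-band 8-bit grayscale TIFF of class codes
#' (nodata = 0) and a plain-text `series.meta` sidecar records epoch years,
#' file names, cell area, nodata code and class codes. Epoch order on read is
#' taken from the metadata, never from file-name order.
#'
#' @param series A [landscape_series].
#' @param dir Directory to write into (created if absent).
#' @return `write_series()` returns `dir` invisibly; `read_series()` returns
#'   the reconstructed [landscape_series].
#' @export
write_series <- function(series, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- sprintf("lc_%s.tif", format(series$epochs, trim = TRUE))
  for (i in seq_along(series$epochs)) {
    v <- series$rasters[[i]]$values
    tiff::writeTIFF(v / 255, file.path(dir, files[i]), bits.per.sample = 8L)
  }
  cl <- series$rasters[[1L]]$classes
  meta <- c(
    sprintf("epochs: %s", paste(series$epochs, collapse = ",")),
    sprintf("files: %s", paste(files, collapse = ",")),
    sprintf("cell_area_km2: %.17g", series$cell_area),
    sprintf("nodata: %d", series$nodata),
    sprintf("classes: %s", paste(sprintf("%s=%d", names(cl), cl), collapse = ",")),
    "crs: local equal-area grid")
  writeLines(meta, file.path(dir, "series.meta"))
  invisible(dir)
}

#' @rdname write_series
#' @export
read_series <- function(dir) {
  meta_path <- file.path(dir, "series.meta")
  if (!file.exists(meta_path))
    stop("no series.meta found in ", dir, call. = FALSE)
  lines <- readLines(meta_path)
  kv <- strsplit(lines, ": ", fixed = TRUE)
  meta <- stats::setNames(
    vapply(kv, function(p) paste(p[-1L], collapse = ": "), character(1)),
    vapply(kv, `[[`, character(1), 1L))
  epochs <- as.numeric(strsplit(meta[["epochs"]], ",")[[1L]])
  files <- strsplit(meta[["files"]], ",")[[1L]]
  cell_area <- as.numeric(meta[["cell_area_km2"]])
  nodata <- as.integer(meta[["nodata"]])
  cl_pairs <- strsplit(strsplit(meta[["classes"]], ",")[[1L]], "=", fixed = TRUE)
  classes <- stats::setNames(
    vapply(cl_pairs, function(p) as.integer(p[2L]), integer(1)),
    vapply(cl_pairs, `[[`, character(1), 1L))
  rasters <- lapply(files, function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("raster file missing: ", p, call. = FALSE)
    v <- round(tiff::readTIFF(p) * 255)
    lc_raster(matrix(as.integer(v), nrow(v), ncol(v)),
              cell_area = cell_area, nodata = nodata, classes = classes)
  })
  d <- dim(rasters[[1L]]$values)
  for (r in rasters)
    if (!identical(dim(r$values), d))
      stop("raster shape mismatch among series files", call. = FALSE)
  landscape_series(rasters, epochs)
}
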