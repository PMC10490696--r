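#' Per-epoch class area table
#'
#' Counts valid cells per class per epoch and multiplies by the cell area.
#'
#' @param series A [landscape_series].
#' @return A data.frame with column `year` and one column per class, areas in
#'   km^2. Class `area_table`.
#' @export
area_table <- function(series) {
  if (!inherits(series, "landscape_series"))
    stop("`series` must be a landscape_series", call. = FALSE)
  cl <- series$rasters[[1L]]$classes
  rows <- lapply(series$rasters, function(r) {
    v <- r$values[r$values != r$nodata]
    if (!length(v)) stop("raster mask is empty", call. = FALSE)
    tabulate(v, nbins = max(cl))[cl] * r$cell_area
  })
  out <- data.frame(year = series$epochs,
                    do.call(rbind, rows))
  names(out)[-1L] <- names(cl)
  structure(out, class = c("area_table", "data.frame"),
            cell_area = series$cell_area, units = "km^2")
}

#' Single land-use dynamic index
#'
#' Annualized relative area change of one class over a period:
#' `K = (Ua - Ub) / Ua * 1/T * 100` (percent per year), where `Ua` and `Ub`
#' are the class areas at the start and end of the period and `T` its length
#' in years. As printed, the formula is negative for an area increase, so both
#' the signed value and its magnitude `K_abs` are returned; reported dynamic
#' degrees are conventionally magnitudes.
#'
#' @param Ua,Ub Start and end areas (same units, `Ua > 0`); vectorized.
#' @param T_years Period length in years (> 0).
#' @return A data.frame with columns `Ua`, `Ub`, `T`, `K_signed`, `K_abs`.
#' @export
#' @examples
#' dynamic_index(67.03, 98.78, 5) # |K| = 9.47 %/yr
dynamic_index <- function(Ua, Ub, T_years) {
  if (any(!is.finite(Ua)) || any(Ua <= 0))
    stop("dynamic index undefined: Ua must be positive", call. = FALSE)
  if (any(Ub < 0)) stop("`Ub` must be >= 0", call. = FALSE)
  if (any(T_years <= 0)) stop("`T_years` must be > 0", call. = FALSE)
  k <- (Ua - Ub) / Ua / T_years * 100
  data.frame(Ua = Ua, Ub = Ub, T = T_years, K_signed = k, K_abs = abs(k))
}

#' Dynamic indices for every class and consecutive epoch pair
#'
#' @param areas An [area_table] (or any data.frame whose first column is
#'   `year` and remaining columns are class areas).
#' @return Long data.frame: `class`, `start`, `end`, `T`, `K_signed`, `K_abs`.
#' @export
dynamic_index_table <- function(areas) {
  yrs <- areas$year
  cls <- setdiff(names(areas), "year")
  out <- list()
  for (cn in cls) {
    a <- areas[[cn]]
    for (i in seq_len(length(yrs) - 1L)) {
      di <- dynamic_index(a[i], a[i + 1L], yrs[i + 1L] - yrs[i])
      out[[length(out) + 1L]] <- data.frame(
        class = cn, start = yrs[i], end = yrs[i + 1L],
        T = di$T, K_signed = di$K_signed, K_abs = di$K_abs)
    }
  }
  do.call(rbind, out)
}

#' Class-to-class area transfer matrix
#'
#' `S[i, j]` is the area occupied by class `i` at the start epoch and class
#' `j` at the end epoch. Row sums equal start-epoch class areas, column sums
#' equal end-epoch class areas, and the grand total equals the masked area —
#' all exactly, because the matrix is a cross-tabulation of the shared mask.
#' Cells valid in one epoch and nodata in the other are counted in neither
#' (with a warning).
#'
#' @param start,end Co-registered [lc_raster] objects.
#' @param period Optional label (e.g. `c(1990, 2005)`), stored as attribute.
#' @return Numeric class-by-class matrix (km^2) of class `transfer_matrix`.
#' @export
transfer_matrix <- function(start, end, period = NULL) {
  check_pair(start, end)
  cl <- start$classes
  m1 <- start$values != start$nodata
  m2 <- end$values != end$nodata
  if (any(m1 != m2))
    warning(sum(m1 != m2),
            " cell(s) valid in one epoch only; excluded from the matrix")
  keep <- m1 & m2
  f <- factor(start$values[keep], levels = cl)
  g <- factor(end$values[keep], levels = cl)
  S <- unclass(table(f, g)) * start$cell_area
  dimnames(S) <- list(from = names(cl), to = names(cl))
  structure(S, class = c("transfer_matrix", class(S)),
            period = period, units = "km^2")
}

#' @export
print.transfer_matrix <- function(x, digits = 4, ...) {
  p <- attr(x, "period")
  cat("<transfer_matrix>",
      if (!is.null(p)) paste0(p[1L], "-", p[2L]), "(km^2)\n")
  print(round(unclass(x), digits))
  invisible(x)
}

check_pair <- function(start, end) {
  if (!inherits(start, "lc_raster") || !inherits(end, "lc_raster"))
    stop("`start` and `end` must be lc_raster objects", call. = FALSE)
  if (!identical(dim(start$values), dim(end$values)))
    stop("rasters are not co-registered (shape mismatch)", call. = FALSE)
  if (start$cell_area != end$cell_area || start$nodata != end$nodata)
    stop("rasters differ in cell_area or nodata code", call. = FALSE)
  invisible(TRUE)
}

# Shared block aggregation for intensity / density. Returns one row per
# analysis-grid block with covered area, changed area and block indices.
block_change <- function(start, end, block_size, focus = NULL) {
  check_pair(start, end)
  cell_side <- sqrt(start$cell_area) * 1000 # m
  bs <- block_size / cell_side
  if (bs < 1) stop("block smaller than one cell", call. = FALSE)
  if (abs(bs - round(bs)) > 1e-9)
    stop("`block_size` must be a positive multiple of the cell size",
         call. = FALSE)
  bs <- as.integer(round(bs))
  d <- dim(start$values)
  valid <- start$values != start$nodata & end$values != end$nodata
  changed <- valid & (start$values != end$values)
  if (!is.null(focus)) {
    cl <- start$classes
    codes <- if (is.numeric(focus)) as.integer(focus) else unname(cl[focus])
    if (anyNA(codes)) stop("unknown focus class", call. = FALSE)
    touching <- (start$values %in% codes) | (end$values %in% codes)
    changed <- changed & touching
  }
  br <- ((seq_len(d[1L]) - 1L) %/% bs) + 1L
  bc <- ((seq_len(d[2L]) - 1L) %/% bs) + 1L
  bi <- outer(br, bc, function(r, c) (c - 1L) * max(br) + r)
  lev <- sort(unique(as.vector(bi)))
  fa <- factor(as.vector(bi), levels = lev)
  covered <- as.vector(tapply(as.vector(valid), fa, sum))
  dS <- as.vector(tapply(as.vector(changed), fa, sum))
  block_row <- ((lev - 1L) %% max(br)) + 1L
  block_col <- ((lev - 1L) %/% max(br)) + 1L
  full <- bs * bs
  cells <- as.vector(tapply(rep(1L, length(fa)), fa, sum))
  data.frame(block_row = block_row, block_col = block_col,
             cell_id = sprintf("B%03d_%03d", block_row, block_col),
             Sgrid = covered * start$cell_area,
             dS = dS * start$cell_area,
             edge = cells < full)
}

#' Gridded transformation intensity
#'
#' Tiles the rasters into square analysis blocks (default 10 km x 10 km) and
#' computes per block `R = dS / (Sgrid * T) * 100` (percent of block area per
#' year), where `dS` is the area of cells whose class changed between the two
#' epochs (optionally restricted to transitions touching the `focus` classes)
#' and `Sgrid` the valid area actually covered by the block. Edge blocks use
#' their real covered area and are flagged.
#'
#' @param start,end Co-registered [lc_raster] objects.
#' @param T_years Period length in years (> 0).
#' @param block_size Block side in metres (default 10000), a positive multiple
#'   of the cell size.
#' @param focus Optional class names or codes; only changes touching these
#'   classes count towards `dS`.
#' @return Data.frame with one row per block (`block_row`, `block_col`,
#'   `cell_id`, `Sgrid`, `dS`, `edge`, `R`), class `intensity_grid`.
#' @export
transfer_intensity <- function(start, end, T_years, block_size = 10000,
                               focus = NULL) {
  if (T_years <= 0) stop("`T_years` must be > 0", call. = FALSE)
  g <- block_change(start, end, block_size, focus)
  g$R <- ifelse(g$Sgrid > 0, g$dS / (g$Sgrid * T_years) * 100, 0)
  structure(g, class = c("intensity_grid", "data.frame"),
            T_years = T_years, block_size = block_size, focus = focus)
}

#' Per-block change density
#'
#' As [transfer_intensity] but without the time normalization: the fraction
#' `dS / Sgrid` of block area whose class changed (restricted to transitions
#' touching `focus_class`). Used as the spatial-balance sampling weight input.
#'
#' @inheritParams transfer_intensity
#' @param focus_class Class name or code the change must touch (default
#'   `"NAW"`).
#' @return Data.frame with per-block `density` in \[0, 1\].
#' @export
change_density <- function(start, end, block_size = 10000,
                           focus_class = "NAW") {
  g <- block_change(start, end, block_size, focus_class)
  g$density <- ifelse(g$Sgrid > 0, g$dS / g$Sgrid, 0)
  g
}

#' Convert an intensity grid to a block matrix
#'
#' @param grid Output of [transfer_intensity] or [change_density].
#' @param what Column to pivot (default `"R"`).
#' @return Numeric matrix indexed by block row/column.
#' @export
intensity_matrix <- function(grid, what = "R") {
  m <- matrix(NA_real_, max(grid$block_row), max(grid$block_col))
  m[cbind(grid$block_row, grid$block_col)] <- grid[[what]]
  m
}
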