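#' Block-level feature and response grid
#'
#' Aggregates the eleven drivers and the wetland-change response onto the
#' square analysis grid for one period. Continuous drivers (ELE, SLO, TEM,
#' PRE, DRN, PDD, GDP) are averaged over the valid cells of each block; the
#' four land-class drivers (DRA, PAF, WOL, GRL) are the block area fraction of
#' that class at the period start. The response is
#' `y = 100 * (NAW area at end - NAW area at start) / block valid area`,
#' the percentage of block area by which natural wetland changed, bounded in
#' \[-100, 100\].
#'
#' @param series A [landscape_series] containing both period endpoints.
#' @param drivers Named list of `driver_field` objects covering the seven
#'   continuous drivers (extra entries are ignored; land-class drivers always
#'   come from the rasters).
#' @param period `c(start_year, end_year)`.
#' @param block_size Block side in metres (default 10000).
#' @return Data.frame with `cell_id`, `block_row`, `block_col`, the eleven
#'   driver columns in [driver_names()] order, and `y`. Class `feature_grid`.
#' @export
build_feature_grid <- function(series, drivers, period, block_size = 10000) {
  start <- epoch_raster(series, period[1L])
  end <- epoch_raster(series, period[2L])
  need <- continuous_driver_names()
  missing_drv <- setdiff(need, names(drivers))
  if (length(missing_drv))
    stop("missing continuous driver field(s): ",
         paste(missing_drv, collapse = ", "), call. = FALSE)
  cell_side <- sqrt(start$cell_area) * 1000
  bs <- as.integer(round(block_size / cell_side))
  if (bs < 1 || abs(block_size / cell_side - bs) > 1e-9)
    stop("`block_size` must be a positive multiple of the cell size",
         call. = FALSE)
  d <- dim(start$values)
  br <- ((seq_len(d[1L]) - 1L) %/% bs) + 1L
  bc <- ((seq_len(d[2L]) - 1L) %/% bs) + 1L
  bi <- outer(br, bc, function(r, c) (c - 1L) * max(br) + r)
  lev <- sort(unique(as.vector(bi)))
  fa <- factor(as.vector(bi), levels = lev)
  valid <- as.vector(start$values != start$nodata & end$values != end$nodata)
  area_valid <- as.vector(tapply(valid, fa, sum)) * start$cell_area

  agg_mean <- function(vals) {
    s <- as.vector(tapply(ifelse(valid, vals, 0), fa, sum))
    n <- as.vector(tapply(valid, fa, sum))
    ifelse(n > 0, s / n, NA_real_)
  }
  frac_of <- function(raster, code) {
    hit <- as.vector(raster$values == code) & valid
    s <- as.vector(tapply(hit, fa, sum)) * start$cell_area
    ifelse(area_valid > 0, s / area_valid, NA_real_)
  }

  cl <- start$classes
  feats <- list()
  for (nm in need) {
    fld <- drivers[[nm]]
    if (!identical(dim(fld$values), d))
      stop("driver field ", nm, " not co-registered with the series",
           call. = FALSE)
    feats[[nm]] <- agg_mean(as.vector(fld$values))
  }
  for (nm in land_driver_names()) feats[[nm]] <- frac_of(start, cl[[nm]])

  naw_start <- frac_of(start, cl[["NAW"]]) * area_valid
  naw_end_hit <- as.vector(end$values == cl[["NAW"]]) & valid
  naw_end <- as.vector(tapply(naw_end_hit, fa, sum)) * start$cell_area
  y <- ifelse(area_valid > 0, 100 * (naw_end - naw_start) / area_valid,
              NA_real_)

  block_row <- ((lev - 1L) %% max(br)) + 1L
  block_col <- ((lev - 1L) %/% max(br)) + 1L
  out <- data.frame(cell_id = sprintf("B%03d_%03d", block_row, block_col),
                    block_row = block_row, block_col = block_col)
  for (nm in driver_names()) out[[nm]] <- feats[[nm]]
  out$y <- y
  out <- out[stats::complete.cases(out), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("feature_grid", "data.frame"),
            period = period, block_size = block_size)
}

#' Spatial-balance sampling weights
#'
#' Selection weight proportional to the wetland-change density of each block,
#' with blocks below the density threshold set to weight zero, normalized to
#' sum one. The threshold is the `tau_percentile`-th percentile of the nonzero
#' densities (so with a uniform positive density no block is excluded).
#'
#' @param grid A [build_feature_grid] result.
#' @param density A [change_density] result on the same analysis grid.
#' @param tau_percentile Percentile (0-100) of nonzero density below which
#'   blocks get weight 0 (default 5).
#' @return Numeric weight vector aligned with `grid` rows, summing to 1.
#' @export
balance_weights <- function(grid, density, tau_percentile = 5) {
  i <- match(grid$cell_id, density$cell_id)
  if (anyNA(i))
    stop("`density` is not aligned with `grid` (missing blocks)", call. = FALSE)
  dens <- density$density[i]
  if (all(dens == 0))
    stop("all block densities are zero; remove the threshold or widen the ",
         "period - no wetland change to weight on", call. = FALSE)
  # type = 1 keeps tau an observed density value, so a 5th-percentile
  # threshold drops at most 5% of the nonzero blocks
  tau <- stats::quantile(dens[dens > 0], tau_percentile / 100,
                         names = FALSE, type = 1)
  w <- ifelse(dens < tau, 0, dens)
  if (sum(w) == 0) w <- dens # threshold removed everything: fall back
  w / sum(w)
}

#' Draw a spatially balanced sample of blocks
#'
#' Weighted sampling without replacement, with greedy rejection of candidates
#' whose block-centre Euclidean distance (in block units) to an already
#' accepted block is strictly less than `min_separation`. Draws continue until
#' `n` rows are accepted or the eligible pool is exhausted.
#'
#' @param grid A [build_feature_grid] result.
#' @param weights Weight vector from [balance_weights] (length `nrow(grid)`).
#' @param n Number of sample rows requested (default 500).
#' @param seed Optional integer seed; identical seeds give identical samples.
#' @param min_separation Minimum accepted-pair distance in block units
#'   (default 1; distances strictly below are rejected).
#' @param period_tag Optional label (`"DEG"`, `"RES"`, `"COM"`) stored on the
#'   result.
#' @return The sampled rows of `grid` plus a `weight` column; class
#'   `sample_set` with attributes `seed` and `period_tag`.
#' @export
draw_samples <- function(grid, weights, n = 500, seed = NULL,
                         min_separation = 1, period_tag = NULL) {
  stopifnot(length(weights) == nrow(grid))
  eligible <- which(weights > 0)
  if (n > length(eligible))
    stop("requested n = ", n, " but only ", length(eligible),
         " blocks have positive weight", call. = FALSE)
  with_seed(seed, {
    pool <- eligible
    accepted <- integer(0)
    while (length(accepted) < n && length(pool)) {
      j <- pool[sample.int(length(pool), 1L, prob = weights[pool])]
      pool <- pool[pool != j]
      if (min_separation > 0 && length(accepted)) {
        dd <- sqrt((grid$block_row[accepted] - grid$block_row[j])^2 +
                   (grid$block_col[accepted] - grid$block_col[j])^2)
        if (any(dd < min_separation)) next
      }
      accepted <- c(accepted, j)
    }
    out <- grid[accepted, , drop = FALSE]
    out$weight <- weights[accepted]
    rownames(out) <- NULL
    structure(out, class = c("sample_set", "data.frame"),
              seed = seed, period_tag = period_tag,
              period = attr(grid, "period"))
  })
}

#' Train/validation split
#'
#' Seeded random partition into `ceiling(train_fraction * n)` training rows
#' and the remainder for validation.
#'
#' @param samples A data.frame (typically a [draw_samples] result).
#' @param train_fraction Fraction in (0, 1), default 0.8.
#' @param seed Optional integer seed.
#' @return List with elements `train` and `validation`.
#' @export
split_samples <- function(samples, train_fraction = 0.8, seed = NULL) {
  n <- nrow(samples)
  if (n < 5L) stop("need at least 5 rows to split", call. = FALSE)
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("`train_fraction` must be in (0, 1)", call. = FALSE)
  with_seed(seed, {
    n_train <- ceiling(train_fraction * n)
    idx <- sample.int(n, n_train)
    list(train = samples[idx, , drop = FALSE],
         validation = samples[-idx, , drop = FALSE])
  })
}
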