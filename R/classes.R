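#' Canonical land-cover class codes
#'
#' The eight reclassified land categories used throughout the package, with
#' their fixed integer raster codes: dryland (DRA), paddy field (PAF),
#' woodland (WOL), grassland (GRL), unused land (UNL), construction land
#' (COL), natural wetland (NAW), reservoirs and ponds (REP). Code 0 is
#' reserved for nodata.
#'
#' @return Named integer vector of length 8.
#' @export
#' @examples
#' lc_classes()
lc_classes <- function() {
  c(DRA = 1L, PAF = 2L, WOL = 3L, GRL = 4L,
    UNL = 5L, COL = 6L, NAW = 7L, REP = 8L)
}

#' Canonical driver names
#'
#' The eleven driving-factor abbreviations used as model features:
#' elevation (ELE), slope (SLO), temperature (TEM), precipitation (PRE),
#' distance to road network (DRN), population density distribution (PDD),
#' gross domestic product (GDP), and the area fractions of dryland (DRA),
#' paddy field (PAF), woodland (WOL) and grassland (GRL).
#'
#' @return Character vector of length 11, in canonical order.
#' @export
driver_names <- function() {
  c("ELE", "SLO", "TEM", "PRE", "DRN", "PDD", "GDP",
    "DRA", "PAF", "WOL", "GRL")
}

# drivers that are continuous fields (the other four are land-class fractions
# derived from the start-epoch raster)
continuous_driver_names <- function() {
  c("ELE", "SLO", "TEM", "PRE", "DRN", "PDD", "GDP")
}

land_driver_names <- function() c("DRA", "PAF", "WOL", "GRL")

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so library calls do not perturb user-level streams.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
      stop("`seed` must be a single finite number", call. = FALSE)
    set.seed(as.integer(seed))
  }
  code
}
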