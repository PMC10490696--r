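#' Transition specification for the landscape simulator
#'
#' Defines a driver-modulated annual Markov process on the eight land-cover
#' classes. `baseline` holds per-ordered-pair annual transition probabilities;
#' transitions into the natural-wetland class (NAW, wetland gain) and out of it
#' (wetland loss) are additionally shifted on the log-odds scale by
#' `sum(effect[d] * z_d)` over the standardized driver surfaces `z_d`, plus
#' optional Gaussian noise on the log-odds. This keeps per-cell probabilities
#' valid without ad-hoc clipping and gives attribution a known ground truth.
#'
#' @param baseline 8 x 8 numeric matrix of annual transition probabilities in
#'   \[0, 1\] (diagonal ignored; row/column order follows [lc_classes()]).
#' @param gain_effects Named numeric vector of log-odds coefficients applied to
#'   every transition into NAW (names must be driver names).
#' @param loss_effects Named numeric vector applied to every transition out of
#'   NAW.
#' @param noise_sd Standard deviation of per-cell Gaussian noise on the
#'   log-odds (default 0).
#' @param classes Named integer class codes (default [lc_classes()]).
#' @return An object of class `transition_spec`.
#' @export
transition_spec <- function(baseline, gain_effects = numeric(),
                            loss_effects = numeric(), noise_sd = 0,
                            classes = lc_classes()) {
  k <- length(classes)
  if (!is.matrix(baseline) || !identical(dim(baseline), c(k, k)))
    stop("`baseline` must be a ", k, " x ", k, " matrix", call. = FALSE)
  if (any(baseline < 0 | baseline > 1))
    stop("baseline rates must lie in [0, 1]", call. = FALSE)
  diag(baseline) <- 0
  for (nm in list(gain_effects, loss_effects))
    if (length(nm) && is.null(names(nm)))
      stop("driver effects must be named vectors", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  dimnames(baseline) <- list(names(classes), names(classes))
  structure(list(classes = classes, baseline = baseline,
                 gain_effects = gain_effects, loss_effects = loss_effects,
                 noise_sd = noise_sd),
            class = "transition_spec")
}

#' Default transition specification
#'
#' A realistic desk-scale parameterization: slow background exchange among the
#' upland classes (about 0.2%/yr), moderate baseline wetland gain from
#' grassland, dryland and unused land (0.8%/yr each) and wetland loss to
#' dryland and paddy field (1.5%/yr each), with precipitation (PRE) strongly favouring wetland
#' gain, temperature (TEM) weakly favouring gain, and distance-to-road (DRN)
#' reducing wetland loss (cells far from roads keep their wetlands).
#'
#' @param gain_effects,loss_effects,noise_sd Override the defaults.
#' @return A [transition_spec].
#' @export
default_transition_spec <- function(
    gain_effects = c(PRE = 1.5, TEM = 0.5),
    loss_effects = c(DRN = -1.0),
    noise_sd = 0.3) {
  cl <- lc_classes()
  b <- matrix(0, 8, 8)
  background <- 0.002
  for (p in list(c("GRL", "DRA"), c("DRA", "GRL"), c("GRL", "WOL"),
                 c("WOL", "GRL"), c("UNL", "GRL"), c("DRA", "PAF"),
                 c("PAF", "DRA"), c("GRL", "COL")))
    b[cl[p[1L]], cl[p[2L]]] <- background
  for (src in c("GRL", "DRA", "UNL")) b[cl[src], cl["NAW"]] <- 0.008
  for (dst in c("DRA", "PAF")) b[cl["NAW"], cl[dst]] <- 0.015
  b[cl["NAW"], cl["REP"]] <- 0.002
  transition_spec(b, gain_effects = gain_effects,
                  loss_effects = loss_effects, noise_sd = noise_sd)
}

#' Random initial landscape
#'
#' Draws an initial class map with the given class mixture, spatially
#' decorrelated (each cell independent). Useful as the starting epoch of a
#' synthetic series.
#'
#' @param shape `c(nrow, ncol)`.
#' @param proportions Named numeric mixture over class names; defaults to a
#'   plausible plain-landscape mixture dominated by dryland, woodland and
#'   grassland with a minor wetland share.
#' @param cell_area Cell area in km^2.
#' @param seed Optional integer seed.
#' @return An [lc_raster].
#' @export
make_initial_landscape <- function(shape,
                                   proportions = c(DRA = 0.24, PAF = 0.03,
                                                   WOL = 0.40, GRL = 0.20,
                                                   UNL = 0.05, COL = 0.02,
                                                   NAW = 0.055, REP = 0.005),
                                   cell_area = 1, seed = NULL) {
  cl <- lc_classes()
  if (!all(names(proportions) %in% names(cl)))
    stop("unknown class name in `proportions`", call. = FALSE)
  with_seed(seed, {
    codes <- sample(cl[names(proportions)], prod(shape), replace = TRUE,
                    prob = proportions)
    lc_raster(matrix(as.integer(codes), shape[1L], shape[2L]),
              cell_area = cell_area)
  })
}

#' Simulate a multi-epoch land-cover series
#'
#' Advances the initial landscape through annual Markov substeps between
#' consecutive epochs. For each cell of class i, off-diagonal transition
#' probabilities come from `spec$baseline`; transitions into/out of the NAW
#' class are shifted on the log-odds scale by the configured driver effects
#' evaluated at that cell (drivers standardized over the valid mask), plus
#' Gaussian log-odds noise. If the off-diagonal probabilities of a cell sum to
#' more than one they are renormalized; the remainder is the stay probability.
#'
#' @param init [lc_raster] at the first epoch.
#' @param drivers Named list of `driver_field` objects covering every name in
#'   the effect vectors.
#' @param spec A [transition_spec].
#' @param epochs Numeric year labels; `epochs[1]` labels `init`.
#' @param seed Optional integer seed; identical inputs and seed give an
#'   identical series.
#' @return A [landscape_series] with one raster per epoch.
#' @export
simulate_lucc_series <- function(init, drivers, spec, epochs, seed = NULL) {
  if (!inherits(init, "lc_raster")) stop("`init` must be an lc_raster")
  if (!inherits(spec, "transition_spec")) stop("`spec` must be a transition_spec")
  if (length(epochs) < 2L || any(diff(epochs) <= 0))
    stop("`epochs` must be at least two strictly increasing years", call. = FALSE)
  cl <- spec$classes
  bad <- setdiff(unique(as.vector(init$values)), c(init$nodata, unname(cl)))
  if (length(bad))
    stop("`init` uses class code(s) unknown to the spec: ",
         paste(bad, collapse = ", "), call. = FALSE)
  eff_names <- union(names(spec$gain_effects), names(spec$loss_effects))
  missing_drv <- setdiff(eff_names, names(drivers))
  if (length(missing_drv))
    stop("driver field(s) required by the spec are missing: ",
         paste(missing_drv, collapse = ", "), call. = FALSE)
  shape <- dim(init$values)
  mask <- init$values != init$nodata
  zdrv <- lapply(drivers[eff_names], function(d) {
    if (!identical(dim(d$values), shape))
      stop("driver field ", d$name, " not co-registered with `init`",
           call. = FALSE)
    standardize_field(d$values, mask)
  })
  # per-cell log-odds shift for gain (into NAW) and loss (out of NAW)
  lin_shift <- function(effects) {
    s <- matrix(0, shape[1L], shape[2L])
    for (nm in names(effects)) s <- s + effects[[nm]] * zdrv[[nm]]
    s
  }
  gain_shift <- lin_shift(spec$gain_effects)
  loss_shift <- lin_shift(spec$loss_effects)
  naw <- cl[["NAW"]]

  with_seed(seed, {
    state <- init$values
    rasters <- vector("list", length(epochs))
    rasters[[1L]] <- init
    for (e in 2:length(epochs)) {
      nyr <- epochs[e] - epochs[e - 1L]
      for (step in seq_len(nyr)) {
        state <- lucc_step(state, mask, spec, gain_shift, loss_shift, naw, cl)
      }
      rasters[[e]] <- lc_raster(state, cell_area = init$cell_area,
                                nodata = init$nodata, classes = cl)
    }
    landscape_series(rasters, epochs)
  })
}

# One annual Markov substep. Classes are visited in fixed code order so the
# random stream (noise draws per adjusted target, then one uniform per cell)
# is reproducible.
lucc_step <- function(state, mask, spec, gain_shift, loss_shift, naw, cl) {
  out <- state
  for (i in sort(unname(cl))) {
    idx <- which(mask & state == i)
    if (!length(idx)) next
    base <- spec$baseline[i, ]
    targets <- which(base > 0)
    targets <- targets[targets != i]
    if (!length(targets)) next
    n <- length(idx)
    P <- matrix(0, n, length(targets))
    for (t in seq_along(targets)) {
      j <- targets[t]
      p0 <- base[j]
      adjust <- (j == naw && i != naw) || (i == naw)
      if (adjust && p0 > 0 && p0 < 1) {
        lp <- stats::qlogis(p0) +
          (if (j == naw) gain_shift[idx] else loss_shift[idx])
        if (spec$noise_sd > 0)
          lp <- lp + stats::rnorm(n, 0, spec$noise_sd)
        P[, t] <- stats::plogis(lp)
      } else {
        P[, t] <- p0
      }
    }
    rs <- rowSums(P)
    over <- rs > 1
    if (any(over)) P[over, ] <- P[over, , drop = FALSE] / rs[over]
    stay <- pmax(0, 1 - rowSums(P))
    u <- stats::runif(n)
    cum <- stay
    new_class <- rep.int(i, n)
    undecided <- u >= cum
    for (t in seq_along(targets)) {
      if (!any(undecided)) break
      cum <- cum + P[, t]
      take <- undecided & (u < cum)
      new_class[take] <- targets[t]
      undecided <- undecided & !take
    }
    out[idx] <- new_class
  }
  out
}

#' Synthetic tabular driver/response data
#'
#' Draws independent standard-normal driver columns and a linear response
#' `y = x %*% effects + rnorm(n, 0, noise_sd)`. With unit-variance independent
#' drivers the true coefficient of determination is
#' `sum(effects^2) / (sum(effects^2) + noise_sd^2)`. Handy for benchmarking
#' the regression harness at a known signal-to-noise ratio.
#'
#' @param n Number of rows.
#' @param effects Named numeric vector of linear coefficients; names must be a
#'   subset of [driver_names()].
#' @param noise_sd Residual standard deviation.
#' @param seed Optional integer seed.
#' @return A data.frame with the eleven driver columns and `y`.
#' @export
simulate_driver_table <- function(n, effects, noise_sd = 0.5, seed = NULL) {
  nm <- driver_names()
  if (length(effects) && !all(names(effects) %in% nm))
    stop("effect names must be driver names", call. = FALSE)
  with_seed(seed, {
    x <- matrix(stats::rnorm(n * length(nm)), n, length(nm),
                dimnames = list(NULL, nm))
    signal <- if (length(effects))
      as.vector(x[, names(effects), drop = FALSE] %*% unname(effects))
    else rep(0, n)
    y <- signal + stats::rnorm(n, 0, noise_sd)
    data.frame(x, y = y)
  })
}
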