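#' Tune depth and tree count with the sparrow search algorithm
#'
#' Searches the `(max_depth, n_trees)` box with [ssa_optimize], using the
#' validation RMSE of a model trained on the training set as the fitness.
#' Both dimensions are continuous-relaxed and rounded at evaluation;
#' evaluations are cached on the rounded pair so the swarm never refits an
#' already-scored configuration.
#'
#' @param train,validation Disjoint data.frames (or lists `list(x =, y =)`)
#'   holding the driver columns and `y`.
#' @param ssa An [ssa_config] whose bounds default to depth in \[2, 15\] and
#'   trees in \[10, 300\] when omitted.
#' @param base A [boost_config] supplying the non-searched parameters.
#' @return Object of class `tune_result`: `best_config` (a [boost_config]
#'   with tuned depth/trees), `best_rmse`, `history` (best RMSE per
#'   iteration), `n_unique_fits`.
#' @export
tune_boost <- function(train, validation, ssa = NULL,
                       base = boost_config()) {
  tv <- split_xy(train); vv <- split_xy(validation)
  if (is.null(ssa))
    ssa <- ssa_config(bounds = rbind(depth = c(2, 15), trees = c(10, 300)),
                      integer_dims = 1:2)
  if (!length(ssa$integer_dims)) ssa$integer_dims <- 1:2
  cache <- new.env(parent = emptyenv())
  fitness <- function(p) {
    key <- paste(round(p[1L]), round(p[2L]))
    if (!is.null(cache[[key]])) return(cache[[key]])
    cfg <- base
    cfg$max_depth <- as.integer(round(p[1L]))
    cfg$n_trees <- as.integer(round(p[2L]))
    fit <- fit_boost(tv$x, tv$y, cfg, eval = vv)
    cache[[key]] <- fit$metrics$rmse_eval
    cache[[key]]
  }
  fit <- ssa_optimize(fitness, ssa)
  best <- base
  best$max_depth <- as.integer(round(fit$best_x[1L]))
  best$n_trees <- as.integer(round(fit$best_x[2L]))
  structure(list(best_config = best, best_rmse = fit$best_f,
                 history = fit$history,
                 n_unique_fits = length(ls(cache))),
            class = "tune_result")
}

split_xy <- function(d) {
  if (is.list(d) && !is.data.frame(d) && all(c("x", "y") %in% names(d)))
    return(d)
  if (!is.data.frame(d) || is.null(d$y))
    stop("expected a data.frame with driver columns and `y`", call. = FALSE)
  list(x = d[, intersect(driver_names(), names(d)), drop = FALSE], y = d$y)
}

#' @export
print.tune_result <- function(x, ...) {
  cat(sprintf("<tune_result> depth = %d, trees = %d, validation RMSE = %.4g (%d unique fits)\n",
              x$best_config$max_depth, x$best_config$n_trees, x$best_rmse,
              x$n_unique_fits))
  invisible(x)
}

#' @export
plot.tune_result <- function(x, ...) {
  graphics::plot(seq_along(x$history) - 1L, x$history, type = "s",
                 xlab = "SSA iteration", ylab = "best validation RMSE",
                 main = "Hyperparameter search", ...)
  invisible(x)
}

#' Fit the wetland driving-force attribution model for one period
#'
#' The top-level fitting function: for one analysis period it builds the
#' block-level feature/response grid, computes wetland-change-density
#' sampling weights, draws a spatially balanced sample, splits it 8:2,
#' tunes the boosted regression's depth and tree count with the sparrow
#' search algorithm (validation RMSE as fitness), refits at the optimum,
#' cross-validates, and converts feature importances into per-driver
#' percentage contributions summing to 100.
#'
#' @param series A [landscape_series].
#' @param drivers Named list of driver fields (continuous drivers required;
#'   land-class drivers are derived from the rasters).
#' @param period `c(start_year, end_year)`.
#' @param period_tag Label for the period; conventionally `"DEG"`
#'   (degradation), `"RES"` (restoration) or `"COM"` (complete cycle).
#' @param block_size Analysis-grid block side in metres (default 10000).
#' @param n Sample size (default 500; must not exceed the eligible blocks).
#' @param tau_percentile,min_separation Sampling knobs, see
#'   [balance_weights] and [draw_samples].
#' @param train_fraction Train share of the split (default 0.8).
#' @param ssa Optional [ssa_config] for the tuner (its seed is derived from
#'   `seed` when unset).
#' @param base A [boost_config] for the non-searched parameters.
#' @param cv_k Folds for cross-validation (default 10).
#' @param importance_type Contribution notion, default `"gain"`.
#' @param seed Integer seed governing sampling, split, search and engine.
#' @return Object of class `wetland_attribution` with components `report`
#'   (a [contribution_report]), `cv`, `tuning`, `model`, `samples`, `split`,
#'   `period`, `period_tag`, `seed`.
#' @seealso [run_all()] to run all three periods from one configuration.
#' @export
wetland_attribution <- function(series, drivers, period, period_tag = "COM",
                                block_size = 10000, n = 500,
                                tau_percentile = 5, min_separation = 1,
                                train_fraction = 0.8, ssa = NULL,
                                base = boost_config(), cv_k = 10,
                                importance_type = "gain", seed = 1) {
  grid <- build_feature_grid(series, drivers, period, block_size)
  dens <- change_density(epoch_raster(series, period[1L]),
                         epoch_raster(series, period[2L]),
                         block_size, focus_class = "NAW")
  w <- balance_weights(grid, dens, tau_percentile)
  samples <- draw_samples(grid, w, n = n, seed = seed,
                          min_separation = min_separation,
                          period_tag = period_tag)
  sp <- split_samples(samples, train_fraction, seed = seed + 1L)
  if (is.null(ssa))
    ssa <- ssa_config(bounds = rbind(depth = c(2, 15), trees = c(10, 300)),
                      integer_dims = 1:2, seed = seed + 2L)
  if (is.null(ssa$seed)) ssa$seed <- seed + 2L
  base$seed <- as.integer(seed)
  tuning <- tune_boost(sp$train, sp$validation, ssa = ssa, base = base)
  tv <- split_xy(sp$train); vv <- split_xy(sp$validation)
  model <- fit_boost(tv$x, tv$y, tuning$best_config, eval = vv)
  av <- split_xy(samples)
  cv <- cross_validate(av$x, av$y, tuning$best_config, k = cv_k,
                       seed = seed + 3L)
  report <- contribution_report(model, importance_type, period_tag)
  structure(list(report = report, cv = cv, tuning = tuning, model = model,
                 samples = samples, split = sp, period = period,
                 period_tag = period_tag, seed = seed),
            class = "wetland_attribution")
}

#' @export
print.wetland_attribution <- function(x, ...) {
  cat(sprintf("Wetland driving-force attribution - period %s (%d-%d)\n",
              x$period_tag, x$period[1L], x$period[2L]))
  cat(sprintf("  samples: %d blocks | tuned depth %d, trees %d | validation RMSE %.4g\n",
              nrow(x$samples), x$model$config$max_depth,
              x$model$config$n_trees, x$tuning$best_rmse))
  cat(sprintf("  validation R2 %.3f | %d-fold CV mean R2 %.3f\n",
              x$model$metrics$r2_eval, x$cv$k, x$cv$mean_r2))
  print(x$report)
  invisible(x)
}

#' @export
summary.wetland_attribution <- function(object, ...) {
  structure(list(period_tag = object$period_tag, period = object$period,
                 n = nrow(object$samples),
                 config = object$model$config,
                 metrics = object$model$metrics,
                 cv = object$cv,
                 contributions = object$report),
            class = "summary.wetland_attribution")
}

#' @export
print.summary.wetland_attribution <- function(x, ...) {
  cat(sprintf("Period %s (%d-%d), n = %d blocks\n", x$period_tag,
              x$period[1L], x$period[2L], x$n))
  cat(sprintf("Tuned: depth %d, trees %d, eta %.2f | eval RMSE %.4g, R2 %.3f\n",
              x$config$max_depth, x$config$n_trees, x$config$learning_rate,
              x$metrics$rmse_eval, x$metrics$r2_eval))
  print(x$cv)
  print(x$contributions)
  invisible(x)
}

#' @export
coef.wetland_attribution <- function(object, ...) {
  stats::setNames(object$report$contribution, object$report$driver)
}

#' @export
predict.wetland_attribution <- function(object, newdata, ...) {
  predict(object$model, newdata, ...)
}

#' @export
plot.wetland_attribution <- function(x, which = c("contributions", "tuning"),
                                     ...) {
  which <- match.arg(which)
  if (which == "contributions") {
    o <- order(-x$report$contribution)
    graphics::barplot(x$report$contribution[o],
                      names.arg = x$report$driver[o], las = 2,
                      ylab = "contribution (%)",
                      main = sprintf("Driver contributions - %s", x$period_tag),
                      ...)
  } else {
    plot(x$tuning, ...)
  }
  invisible(x)
}
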