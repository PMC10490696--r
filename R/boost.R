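#' Boosted-regression configuration
#'
#' Hyperparameters of the regularized gradient-boosted regression: learning
#' rate (shrinkage) `learning_rate` in (0, 1) with the conventional default
#' 0.3, tree depth `max_depth`, number of boosting rounds `n_trees`, and the
#' regularization coefficients `reg_gamma` (complexity cost per leaf) and
#' `reg_lambda` (L2 on leaf weights) of the objective
#' `sum l(y, yhat) + gamma * N_leaves + lambda/2 * sum w^2` with squared-error
#' loss.
#'
#' @param learning_rate Shrinkage in (0, 1), default 0.3.
#' @param max_depth Tree depth `H >= 1`, default 6.
#' @param n_trees Boosting rounds `M >= 1`, default 60.
#' @param reg_gamma,reg_lambda Regularization coefficients (>= 0), defaults
#'   0 and 1.
#' @param seed Integer seed passed to the boosting engine, default 0.
#' @return An object of class `boost_config`.
#' @export
boost_config <- function(learning_rate = 0.3, max_depth = 6, n_trees = 60,
                         reg_gamma = 0, reg_lambda = 1, seed = 0) {
  if (learning_rate <= 0 || learning_rate >= 1)
    stop("`learning_rate` must be in (0, 1)", call. = FALSE)
  if (max_depth < 1 || n_trees < 1)
    stop("`max_depth` and `n_trees` must be >= 1", call. = FALSE)
  if (reg_gamma < 0 || reg_lambda < 0)
    stop("regularization coefficients must be >= 0", call. = FALSE)
  structure(list(learning_rate = learning_rate,
                 max_depth = as.integer(max_depth),
                 n_trees = as.integer(n_trees),
                 reg_gamma = reg_gamma, reg_lambda = reg_lambda,
                 seed = as.integer(seed)),
            class = "boost_config")
}

rmse <- function(obs, pred) sqrt(mean((obs - pred)^2))

# R^2 = 1 - SS_res / SS_tot on the evaluation set; NA when y is constant.
r_squared <- function(obs, pred) {
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum((obs - pred)^2) / ss_tot
}

as_feature_matrix <- function(x, feature_names = NULL) {
  if (is.data.frame(x)) {
    if (is.null(feature_names))
      feature_names <- intersect(driver_names(), names(x))
    missing_f <- setdiff(feature_names, names(x))
    if (length(missing_f))
      stop("missing feature column(s): ", paste(missing_f, collapse = ", "),
           call. = FALSE)
    x <- x[, feature_names, drop = FALSE]
    if (!all(vapply(x, is.numeric, logical(1))))
      stop("non-numeric feature column(s)", call. = FALSE)
    x <- as.matrix(x)
  }
  if (!is.numeric(x)) stop("features must be numeric", call. = FALSE)
  x
}

#' Fit the gradient-boosted regression
#'
#' Thin, seeded wrapper around the XGBoost engine with squared-error loss and
#' the configured regularization, single-threaded for exact reproducibility.
#'
#' @param x Feature matrix or data.frame (driver columns are picked out of a
#'   data.frame automatically); at least 20 rows.
#' @param y Numeric response.
#' @param config A [boost_config].
#' @param eval Optional list `list(x =, y =)`; evaluation RMSE and R^2 are
#'   stored in the result's `metrics`.
#' @return Object of class `wetboost`: the fitted booster, config, feature
#'   names and train/eval metrics.
#' @export
fit_boost <- function(x, y, config = boost_config(), eval = NULL) {
  xm <- as_feature_matrix(x)
  if (nrow(xm) < 20L)
    stop("need at least 20 training rows", call. = FALSE)
  if (length(y) != nrow(xm)) stop("length(y) != nrow(x)", call. = FALSE)
  params <- list(objective = "reg:squarederror",
                 eta = config$learning_rate,
                 max_depth = config$max_depth,
                 gamma = config$reg_gamma,
                 lambda = config$reg_lambda,
                 nthread = 1L,
                 seed = config$seed)
  dtrain <- xgboost::xgb.DMatrix(xm, label = y, nthread = 1L)
  booster <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = config$n_trees, verbose = 0)
  pred_train <- predict(booster, dtrain)
  metrics <- list(rmse_train = rmse(y, pred_train),
                  r2_train = r_squared(y, pred_train))
  if (!is.null(eval)) {
    em <- as_feature_matrix(eval$x, colnames(xm))
    pe <- predict(booster, xgboost::xgb.DMatrix(em, nthread = 1L))
    metrics$rmse_eval <- rmse(eval$y, pe)
    metrics$r2_eval <- r_squared(eval$y, pe)
  }
  structure(list(booster = booster, config = config,
                 feature_names = colnames(xm), metrics = metrics),
            class = "wetboost")
}

#' @export
predict.wetboost <- function(object, newdata, ...) {
  xm <- as_feature_matrix(newdata, object$feature_names)
  predict(object$booster, xgboost::xgb.DMatrix(xm, nthread = 1L))
}

#' @export
print.wetboost <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<wetboost> depth %d, %d trees, eta %.2f | train RMSE %.4g",
              x$config$max_depth, x$config$n_trees, x$config$learning_rate,
              m$rmse_train))
  if (!is.null(m$rmse_eval))
    cat(sprintf(" | eval RMSE %.4g, R2 %.3f", m$rmse_eval, m$r2_eval))
  cat("\n")
  invisible(x)
}

#' K-fold cross-validation of the boosted regression
#'
#' Seeded partition into `k` folds whose sizes differ by at most one; each
#' fold serves once as the validation set for a model trained on the rest,
#' and the per-fold coefficient of determination is reported.
#'
#' @param x,y Features and response as in [fit_boost].
#' @param config A [boost_config].
#' @param k Number of folds (2 <= k <= n; `k = n` is leave-one-out).
#' @param seed Optional integer seed for the fold assignment.
#' @return Object of class `cv_result`: `k`, `fold_r2`, `fold_sizes`,
#'   `mean_r2`, `median_r2`.
#' @export
cross_validate <- function(x, y, config = boost_config(), k = 10,
                           seed = NULL) {
  xm <- as_feature_matrix(x)
  n <- nrow(xm)
  if (k > n) stop("k = ", k, " exceeds the ", n, " available rows",
                  call. = FALSE)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  with_seed(seed, {
    fold <- sample(rep_len(seq_len(k), n))
    fold_r2 <- numeric(k)
    for (i in seq_len(k)) {
      tr <- fold != i
      fit <- fit_boost(xm[tr, , drop = FALSE], y[tr], config)
      pred <- predict(fit, xm[!tr, , drop = FALSE])
      fold_r2[i] <- if (sum(!tr) == 1L) NA_real_ else
        r_squared(y[!tr], pred)
    }
    structure(list(k = k, fold_r2 = fold_r2,
                   fold_sizes = as.integer(table(fold)),
                   mean_r2 = mean(fold_r2, na.rm = TRUE),
                   median_r2 = stats::median(fold_r2, na.rm = TRUE),
                   seed = seed),
              class = "cv_result")
  })
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> k = %d | mean R2 = %.3f, median R2 = %.3f\n",
              x$k, x$mean_r2, x$median_r2))
  invisible(x)
}

#' Per-driver percentage contributions
#'
#' Normalizes the fitted model's feature importances to percentages summing
#' to 100. The default importance notion is `gain` (total objective
#' improvement contributed by a feature's splits); `weight` (split frequency)
#' and `cover` are available as alternatives. Features never used by any tree
#' contribute 0.
#'
#' @param model A fitted [fit_boost] model (`wetboost`).
#' @param importance_type One of `"gain"`, `"cover"`, `"weight"`.
#' @param period_tag Optional period label stored on the report.
#' @return Data.frame `driver`, `contribution` (percent, sums to 100), class
#'   `contribution_report` with attributes `importance_type`, `period_tag`
#'   and the model `metrics`.
#' @export
contribution_report <- function(model, importance_type = c("gain", "cover",
                                                           "weight"),
                                period_tag = NULL) {
  stopifnot(inherits(model, "wetboost"))
  importance_type <- match.arg(importance_type)
  imp <- xgboost::xgb.importance(model = model$booster)
  col <- c(gain = "Gain", cover = "Cover", weight = "Frequency")[importance_type]
  raw <- stats::setNames(rep(0, length(model$feature_names)),
                         model$feature_names)
  if (!is.null(imp) && nrow(imp))
    raw[imp$Feature] <- imp[[col]]
  if (sum(raw) == 0)
    stop("all feature importances are zero (constant response?); ",
         "contributions undefined", call. = FALSE)
  out <- data.frame(driver = names(raw),
                    contribution = 100 * unname(raw) / sum(raw))
  structure(out, class = c("contribution_report", "data.frame"),
            importance_type = importance_type, period_tag = period_tag,
            metrics = model$metrics)
}

#' @export
print.contribution_report <- function(x, ...) {
  tag <- attr(x, "period_tag")
  cat(sprintf("<contribution_report>%s importance = %s (percent, sums to %.2f)\n",
              if (!is.null(tag)) paste0(" ", tag, ";") else "",
              attr(x, "importance_type"), sum(x$contribution)))
  o <- order(-x$contribution)
  print(data.frame(driver = x$driver[o],
                   contribution = round(x$contribution[o], 2)),
        row.names = FALSE)
  invisible(x)
}
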