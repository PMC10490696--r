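test_that("a constant response fits to zero error and undefined contributions", {
  d <- simulate_driver_table(50, c(), noise_sd = 0, seed = 1)
  d$y <- 3.5
  fit <- fit_boost(d[, driver_names()], d$y, boost_config(n_trees = 10))
  expect_lt(fit$metrics$rmse_train, 1e-6)
  expect_error(contribution_report(fit), "zero")
})

test_that("a noiseless linear signal is recovered to R^2 > 0.99", {
  d <- simulate_driver_table(400, c(PRE = 3), noise_sd = 0, seed = 2)
  sp <- split_samples(d, 0.8, seed = 3)
  fit <- fit_boost(sp$train[, driver_names()], sp$train$y,
                   boost_config(max_depth = 4, n_trees = 300),
                   eval = list(x = sp$validation[, driver_names()],
                               y = sp$validation$y))
  expect_gt(fit$metrics$r2_eval, 0.99)
})

test_that("fitting is deterministic under a fixed seed and config", {
  d <- simulate_driver_table(100, c(TEM = 1), noise_sd = 0.5, seed = 4)
  cfg <- boost_config(max_depth = 3, n_trees = 40, seed = 11)
  f1 <- fit_boost(d[, driver_names()], d$y, cfg)
  f2 <- fit_boost(d[, driver_names()], d$y, cfg)
  expect_identical(predict(f1, d), predict(f2, d))
})

test_that("degenerate inputs are rejected with informative errors", {
  d <- simulate_driver_table(30, c(PRE = 1), seed = 5)
  expect_error(fit_boost(d[1:10, driver_names()], d$y[1:10],
                         boost_config()), "at least 20")
  d$PRE <- as.character(d$PRE)
  expect_error(fit_boost(d[, driver_names()], d$y, boost_config()),
               "non-numeric")
  expect_error(boost_config(learning_rate = 1.5), "learning_rate")
  expect_error(boost_config(n_trees = 0), ">= 1")
})

test_that("contributions are percentages over exactly the eleven drivers", {
  d <- simulate_driver_table(200, c(PRE = 1, ELE = 0.5), noise_sd = 0.3,
                             seed = 6)
  fit <- fit_boost(d[, driver_names()], d$y,
                   boost_config(max_depth = 3, n_trees = 50))
  for (type in c("gain", "cover", "weight")) {
    rep <- contribution_report(fit, type, period_tag = "DEG")
    expect_identical(rep$driver, driver_names())
    expect_true(all(rep$contribution >= 0))
    expect_equal(sum(rep$contribution), 100, tolerance = 1e-9)
  }
})

test_that("a single informative feature ranks first in almost every replicate", {
  hits <- vapply(1:20, function(s) {
    d <- simulate_driver_table(200, c(DRN = 1.5), noise_sd = 0.4, seed = s)
    fit <- fit_boost(d[, driver_names()], d$y,
                     boost_config(max_depth = 3, n_trees = 50, seed = s))
    rep <- contribution_report(fit)
    rep$driver[which.max(rep$contribution)] == "DRN"
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("symmetric-role features receive comparable mean contributions", {
  m <- vapply(1:10, function(s) {
    d <- simulate_driver_table(300, c(PRE = 1, TEM = 1), noise_sd = 0.3,
                               seed = s)
    rep <- contribution_report(
      fit_boost(d[, driver_names()], d$y,
                boost_config(max_depth = 3, n_trees = 60, seed = s)))
    c(rep$contribution[rep$driver == "PRE"],
      rep$contribution[rep$driver == "TEM"])
  }, numeric(2))
  ratio <- mean(m[1L, ]) / mean(m[2L, ])
  expect_gt(ratio, 0.7)
  expect_lt(ratio, 1 / 0.7)
})

test_that("cross-validation folds partition the data with near-equal sizes", {
  d <- simulate_driver_table(500, c(PRE = 1), noise_sd = 0.5, seed = 7)
  cv <- cross_validate(d[, driver_names()], d$y,
                       boost_config(max_depth = 3, n_trees = 30), k = 3,
                       seed = 8)
  expect_setequal(cv$fold_sizes, c(167L, 167L, 166L))
  expect_equal(sum(cv$fold_sizes), 500L)
  # leave-one-out: n folds of size one
  d2 <- simulate_driver_table(30, c(PRE = 1), noise_sd = 0.2, seed = 9)
  loo <- cross_validate(d2[, driver_names()], d2$y,
                        boost_config(max_depth = 2, n_trees = 15), k = 30,
                        seed = 10)
  expect_equal(loo$k, 30L)
  expect_true(all(loo$fold_sizes == 1L))
  expect_error(cross_validate(d2[, driver_names()], d2$y, k = 31), "exceeds")
})

test_that("mean CV R^2 degrades monotonically with the noise level", {
  mean_r2_at <- function(noise_sd) {
    mean(vapply(1:5, function(s) {
      d <- simulate_driver_table(200, c(PRE = 0.8, TEM = 0.6),
                                 noise_sd = noise_sd, seed = s)
      cross_validate(d[, driver_names()], d$y,
                     boost_config(max_depth = 3, n_trees = 50), k = 5,
                     seed = s)$mean_r2
    }, numeric(1)))
  }
  r2 <- vapply(c(0.3, 0.8, 1.6), mean_r2_at, numeric(1))
  expect_true(all(diff(r2) < 0))
})

test_that("collapsed tuning bounds return the pinned configuration", {
  d <- simulate_driver_table(120, c(PRE = 1), noise_sd = 0.4, seed = 11)
  sp <- split_samples(d, 0.8, seed = 12)
  ssa <- ssa_config(rbind(depth = c(3, 3.4), trees = c(40, 40.4)),
                    Gmax = 3, P = 4, PD_frac = 0.5, SD = 1,
                    integer_dims = 1:2, seed = 13)
  tn <- tune_boost(sp$train, sp$validation, ssa = ssa)
  expect_equal(tn$best_config$max_depth, 3L)
  expect_equal(tn$best_config$n_trees, 40L)
  expect_equal(tn$n_unique_fits, 1L)
  expect_true(all(diff(tn$history) <= 0))
})
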