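# 4x4-cell landscape, 2000 m blocks -> 2x2 analysis grid of 4 cells each;
# everything hand-computable.
hand_fixture <- function() {
  cl <- lc_classes()
  m1 <- matrix(c(7L, 7L, 4L, 4L,
                 7L, 1L, 4L, 4L,
                 3L, 3L, 7L, 7L,
                 3L, 1L, 7L, 7L), 4, 4, byrow = TRUE)
  m2 <- m1
  m2[1L, 1L] <- 4L  # one NAW cell lost in block (1,1)
  m2[3L, 3L] <- 4L  # one NAW cell lost in block (2,2)
  m2[3L, 4L] <- 4L  # and another
  ser <- toy_series(m1, m2, c(1990, 2005))
  drv <- constant_drivers(c(4, 4), 0)
  drv$PRE <- manual_driver("PRE", matrix(as.numeric(1:16), 4, 4))
  list(ser = ser, drv = drv, m1 = m1, m2 = m2)
}

test_that("feature grid aggregation matches hand-computed blocks", {
  fx <- hand_fixture()
  g <- build_feature_grid(fx$ser, fx$drv, c(1990, 2005), block_size = 2000)
  expect_equal(nrow(g), 4L)
  expect_identical(names(g), c("cell_id", "block_row", "block_col",
                               driver_names(), "y"))
  b11 <- g[g$block_row == 1 & g$block_col == 1, ]
  # PRE stores column-major 1..16: block (1,1) holds cells (1,1),(2,1),(1,2),(2,2)
  expect_equal(b11$PRE, mean(c(1, 2, 5, 6)))
  # start classes in block (1,1): 7,7,7,1 -> NAW 3/4, DRA 1/4
  expect_equal(b11$DRA, 1 / 4)
  expect_equal(b11$WOL, 0)
  # one of three NAW cells lost: y = 100 * (2 - 3) / 4
  expect_equal(b11$y, -25)
  b22 <- g[g$block_row == 2 & g$block_col == 2, ]
  expect_equal(b22$y, 100 * (2 - 4) / 4)
  # constant drivers aggregate to the same value everywhere
  expect_true(all(g$TEM == 0))
})

test_that("a block losing all its wetland reaches the y = -100 bound", {
  cl <- lc_classes()
  m1 <- matrix(cl[["NAW"]], 2, 2)
  m2 <- matrix(cl[["DRA"]], 2, 2)
  g <- build_feature_grid(toy_series(m1, m2), constant_drivers(c(2, 2)),
                          c(1990, 2005), block_size = 2000)
  expect_equal(g$y, -100)
})

test_that("balance weights are density-proportional, thresholded, normalized", {
  fx <- hand_fixture()
  g <- build_feature_grid(fx$ser, fx$drv, c(1990, 2005), block_size = 2000)
  dens <- change_density(fx$ser$rasters[[1L]], fx$ser$rasters[[2L]],
                         2000, "NAW")
  w <- balance_weights(g, dens, tau_percentile = 5)
  expect_equal(sum(w), 1)
  expect_true(all(w >= 0))
  # blocks (2,1) and (1,2) saw no wetland change -> zero weight
  expect_equal(w[g$block_row == 2 & g$block_col == 1], 0)
  expect_equal(w[g$block_row == 1 & g$block_col == 2], 0)
  # density ratio 1:2 between blocks (1,1) and (2,2) carries into the weights
  expect_equal(w[g$block_row == 2 & g$block_col == 2] /
                 w[g$block_row == 1 & g$block_col == 1], 2)
  # uniform density -> uniform weights
  dens$density <- rep(0.3, nrow(dens))
  expect_equal(balance_weights(g, dens), rep(0.25, 4))
  dens$density <- 0
  expect_error(balance_weights(g, dens), "zero")
})

test_that("zero-weight blocks are never drawn and draws follow the weights", {
  g <- data.frame(cell_id = sprintf("B%03d_%03d", 1:4, 1L),
                  block_row = 1:4, block_col = 1L)
  w <- c(0.5, 0.3, 0.2, 0)
  # n = 1 draws are exactly multinomial in the weights
  counts <- integer(4)
  for (s in 1:10000) {
    d <- draw_samples(g, w, n = 1, seed = s, min_separation = 0)
    counts[d$block_row] <- counts[d$block_row] + 1L
  }
  expect_equal(counts[4L], 0L)
  for (i in 1:3) {
    sd_i <- sqrt(10000 * w[i] * (1 - w[i]))
    expect_lt(abs(counts[i] - 10000 * w[i]), 3 * sd_i)
  }
})

test_that("sampling is seeded, exhaustive at n = eligible, and bounded", {
  fx <- hand_fixture()
  g <- build_feature_grid(fx$ser, fx$drv, c(1990, 2005), block_size = 2000)
  w <- rep(0.25, 4)
  all4 <- draw_samples(g, w, n = 4, seed = 1, min_separation = 0)
  expect_setequal(all4$cell_id, g$cell_id)
  s1 <- draw_samples(g, w, n = 2, seed = 7)
  s2 <- draw_samples(g, w, n = 2, seed = 7)
  expect_identical(s1$cell_id, s2$cell_id)
  expect_error(draw_samples(g, w, n = 5, seed = 1), "only 4")
})

test_that("minimum separation rejects clustered candidates", {
  n <- 100L
  g <- data.frame(cell_id = sprintf("B%03d_%03d",
                                    rep(1:10, each = 10), rep(1:10, 10)),
                  block_row = rep(1:10, each = 10), block_col = rep(1:10, 10))
  w <- rep(1 / n, n)
  s <- draw_samples(g, w, n = 20, seed = 3, min_separation = 2)
  d <- as.matrix(stats::dist(s[, c("block_row", "block_col")]))
  diag(d) <- Inf
  expect_true(all(d >= 2))
})

test_that("the 8:2 split partitions 500 rows into 400/100 without leakage", {
  d <- data.frame(cell_id = sprintf("c%03d", 1:500), y = rnorm(500))
  sp <- split_samples(d, 0.8, seed = 5)
  expect_equal(nrow(sp$train), 400L)
  expect_equal(nrow(sp$validation), 100L)
  expect_length(intersect(sp$train$cell_id, sp$validation$cell_id), 0L)
  expect_setequal(c(sp$train$cell_id, sp$validation$cell_id), d$cell_id)
  sp2 <- split_samples(d, 0.8, seed = 5)
  expect_identical(sp$train$cell_id, sp2$train$cell_id)
  expect_error(split_samples(d[1:4, ], 0.8), "at least 5")
})
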