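test_that("area table matches direct cell counting", {
  # single class
  r <- lc_raster(matrix(7L, 10, 10))
  at <- area_table(landscape_series(list(r), 2000))
  expect_equal(at$NAW, 100)
  expect_equal(sum(at[, setdiff(names(at), "year")]), 100)
  # checkerboard
  cb <- matrix(rep(c(1L, 7L), length.out = 100), 10, 10)
  at2 <- area_table(landscape_series(list(lc_raster(cb)), 2000))
  expect_equal(at2$DRA, 50)
  expect_equal(at2$NAW, 50)
  # random raster vs brute-force count
  set.seed(21)
  m <- matrix(sample(0:8, 900, replace = TRUE), 30, 30)
  at3 <- area_table(landscape_series(list(lc_raster(m, cell_area = 0.25)),
                                     2000))
  for (nm in names(lc_classes()))
    expect_equal(at3[[nm]], sum(m == lc_classes()[[nm]]) * 0.25)
})

test_that("dynamic index reproduces the published worked examples", {
  a <- reference_area_series()
  naw <- dynamic_index(a$NAW[a$year == 2005], a$NAW[a$year == 2010], 5)
  expect_equal(round(naw$K_abs, 2), 9.47)
  expect_lt(naw$K_signed, 0) # formula-literal sign: negative for an increase
  unl <- dynamic_index(a$UNL[a$year == 2005], a$UNL[a$year == 2010], 5)
  expect_equal(round(unl$K_abs, 2), 10.37)
  expect_equal(dynamic_index(50, 50, 5)$K_signed, 0)
  expect_error(dynamic_index(0, 10, 5), "undefined")
  expect_error(dynamic_index(10, 5, 0), "> 0")
})

test_that("published five-year indices of the stable classes stay below 5 %/yr", {
  di <- dynamic_index_table(reference_area_series())
  expect_true(all(is.finite(di$K_abs)))
  stable <- di[di$class %in% c("DRA", "WOL", "GRL") & di$T == 5, ]
  expect_true(all(stable$K_abs < 5))
})

test_that("transfer matrix is exact on identity and an enumerated toy pair", {
  m <- matrix(sample(1:8, 9, replace = TRUE), 3, 3)
  r <- lc_raster(m)
  S_id <- transfer_matrix(r, r)
  expect_equal(sum(S_id) - sum(diag(S_id)), 0)
  expect_equal(unname(diag(S_id)),
               unname(tabulate(m, 8)[lc_classes()]) * 1)

  m1 <- matrix(c(1L, 1L, 7L, 7L, 4L, 4L, 7L, 3L, 0L), 3, 3)
  m2 <- matrix(c(1L, 7L, 7L, 2L, 4L, 7L, 7L, 3L, 0L), 3, 3)
  S <- transfer_matrix(lc_raster(m1, cell_area = 2),
                       lc_raster(m2, cell_area = 2))
  # exhaustive pair enumeration oracle
  oracle <- matrix(0, 8, 8)
  for (i in seq_along(m1))
    if (m1[i] != 0L && m2[i] != 0L)
      oracle[m1[i], m2[i]] <- oracle[m1[i], m2[i]] + 2
  expect_equal(matrix(S, 8, 8), oracle)
  expect_equal(sum(S), sum(m1 != 0L & m2 != 0L) * 2)
})

test_that("transfer matrix margins reproduce the epoch area tables exactly", {
  set.seed(31)
  m1 <- matrix(sample(1:8, 400, replace = TRUE), 20, 20)
  m2 <- matrix(sample(1:8, 400, replace = TRUE), 20, 20)
  ser <- toy_series(m1, m2)
  S <- transfer_matrix(ser$rasters[[1L]], ser$rasters[[2L]])
  at <- area_table(ser)
  expect_equal(unname(rowSums(S)),
               unname(unlist(at[1L, names(lc_classes())])))
  expect_equal(unname(colSums(S)),
               unname(unlist(at[2L, names(lc_classes())])))
})

test_that("half-masked cells are excluded with a warning", {
  m1 <- matrix(1L, 4, 4); m2 <- matrix(7L, 4, 4)
  m2[1L, 1L] <- 0L
  expect_warning(S <- transfer_matrix(lc_raster(m1), lc_raster(m2)),
                 "one epoch only")
  expect_equal(sum(S), 15)
})

test_that("transformation intensity follows its defining formula per block", {
  # no change anywhere -> R = 0
  m <- matrix(4L, 20, 20)
  ig0 <- transfer_intensity(lc_raster(m), lc_raster(m), 5, 10000)
  expect_true(all(ig0$R == 0))
  # direct substitution: one 10x10 block (100 km^2) with 25 changed cells
  m2 <- m
  m2[1:5, 1:5] <- 7L
  ig <- transfer_intensity(lc_raster(m), lc_raster(m2), 5, 10000)
  blk <- ig[ig$block_row == 1 & ig$block_col == 1, ]
  expect_equal(blk$Sgrid, 100)
  expect_equal(blk$dS, 25)
  expect_equal(blk$R, 25 / (100 * 5) * 100) # = 5 %/yr
  # homogeneity: doubling T halves every R
  ig2 <- transfer_intensity(lc_raster(m), lc_raster(m2), 10, 10000)
  expect_equal(ig2$R, ig$R / 2)
})

test_that("edge blocks use their actual covered area and are flagged", {
  m1 <- matrix(4L, 15, 15); m2 <- m1; m2[11:15, 11:15] <- 7L
  ig <- transfer_intensity(lc_raster(m1), lc_raster(m2), 5, 10000)
  edge <- ig[ig$block_row == 2 & ig$block_col == 2, ]
  expect_true(edge$edge)
  expect_equal(edge$Sgrid, 25)
  expect_equal(edge$R, 25 / (25 * 5) * 100)
  expect_false(ig$edge[ig$block_row == 1 & ig$block_col == 1])
  expect_error(transfer_intensity(lc_raster(m1), lc_raster(m2), 5, 500),
               "smaller than one cell")
})

test_that("blockwise changed area totals the transfer-matrix off-diagonal", {
  set.seed(32)
  m1 <- matrix(sample(1:8, 2500, replace = TRUE), 50, 50)
  m2 <- matrix(sample(1:8, 2500, replace = TRUE), 50, 50)
  S <- transfer_matrix(lc_raster(m1), lc_raster(m2))
  ig <- transfer_intensity(lc_raster(m1), lc_raster(m2), 5, 10000)
  expect_equal(sum(ig$dS), sum(S) - sum(diag(S)))
})

test_that("change density is the per-block changed fraction", {
  cl <- lc_classes()
  m1 <- matrix(cl[["NAW"]], 10, 10)
  m2 <- matrix(cl[["DRA"]], 10, 10)
  d_all <- change_density(lc_raster(m1), lc_raster(m2), 10000, "NAW")
  expect_equal(d_all$density, 1)
  m3 <- m1; m3[, 1:5] <- cl[["DRA"]]
  d_half <- change_density(lc_raster(m1), lc_raster(m3), 10000, "NAW")
  expect_equal(d_half$density, 0.5)
  # random pair vs brute-force focus-restricted counting
  set.seed(33)
  a <- matrix(sample(c(4L, 7L), 400, replace = TRUE), 20, 20)
  b <- matrix(sample(c(4L, 7L), 400, replace = TRUE), 20, 20)
  d <- change_density(lc_raster(a), lc_raster(b), 10000, "NAW")
  oracle <- sum(a != b & (a == 7L | b == 7L)) / 400
  expect_equal(sum(d$dS) / sum(d$Sgrid), oracle)
})
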