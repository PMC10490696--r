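# Shared fixtures and independent oracles, all built in code at test time.

# A driver field with known values (bypasses the random-field generator so
# hand oracles stay hand-computable).
manual_driver <- function(name, values) {
  structure(list(name = name, values = values,
                 static = name %in% c("ELE", "SLO")),
            class = "driver_field")
}

# Constant-value driver set covering the seven continuous drivers.
constant_drivers <- function(shape, value = 0) {
  nms <- c("ELE", "SLO", "TEM", "PRE", "DRN", "PDD", "GDP")
  stats::setNames(lapply(nms, function(nm) {
    manual_driver(nm, matrix(value, shape[1L], shape[2L]))
  }), nms)
}

# Small two-epoch series built directly from class-code matrices.
toy_series <- function(m1, m2, years = c(1990, 2005), cell_area = 1) {
  landscape_series(list(lc_raster(m1, cell_area = cell_area),
                        lc_raster(m2, cell_area = cell_area)),
                   years)
}

# Straight-line transcription of the SSA update equations, written
# independently of the package internals: one literal loop consuming the RNG
# in the same documented order (per-iteration alarm draw; producers in rank
# order; followers in rank order; scout index draw then per-scout draws).
ssa_transcription <- function(fn, bounds, Gmax, P, PD_frac, SD, ST,
                              integer_dims = integer(0), seed = 1) {
  d <- nrow(bounds); lo <- bounds[, 1L]; hi <- bounds[, 2L]
  clamp <- function(x) pmin(pmax(x, lo), hi)
  ev <- function(x) {
    if (length(integer_dims)) x[integer_dims] <- round(x[integer_dims])
    fn(x)
  }
  set.seed(as.integer(seed))
  X <- matrix(runif(P * d), P, d)
  X <- sweep(sweep(X, 2L, hi - lo, "*"), 2L, lo, "+")
  f <- vapply(seq_len(P), function(i) ev(X[i, ]), numeric(1))
  ib <- which.min(f); iw <- which.max(f)
  Xb <- X[ib, ]; fb <- f[ib]; Xw <- X[iw, ]; fw <- f[iw]
  hist <- fb
  npd <- ceiling(PD_frac * P)
  for (t in seq_len(Gmax)) {
    ord <- order(f)
    R2 <- runif(1)
    for (k in seq_len(npd)) {                       # producers, Eq. (4)
      i <- ord[k]
      if (R2 < ST) {
        a <- runif(1)
        X[i, ] <- X[i, ] * exp(-k / (a * max(Gmax, 1)))
      } else {
        X[i, ] <- X[i, ] + rnorm(1)
      }
      X[i, ] <- clamp(X[i, ])
    }
    Xb_it <- X[ord[1L], ]; Xw_it <- X[ord[P], ]
    for (k in seq.int(npd + 1L, P)) {               # followers, Eq. (5)
      if (k > P) break
      i <- ord[k]
      if (k > P / 2) {
        X[i, ] <- rnorm(1) * exp((Xw_it - X[i, ]) / k^2)
      } else {
        A <- sample(c(-1, 1), d, replace = TRUE)
        X[i, ] <- Xb_it + sum(abs(X[i, ] - Xb_it) * A) / d
      }
      X[i, ] <- clamp(X[i, ])
    }
    for (j in sample.int(P, SD)) {                  # scouts, Eq. (6)
      if (f[j] > fb) {
        X[j, ] <- Xb + rnorm(1) * abs(X[j, ] - Xb)
      } else {
        kap <- runif(1, -1, 1)
        X[j, ] <- X[j, ] + kap * (X[j, ] - Xw) / ((f[j] - fw) + 1e-50)
      }
      X[j, ] <- clamp(X[j, ])
    }
    f <- vapply(seq_len(P), function(i) ev(X[i, ]), numeric(1))
    ib <- which.min(f)
    if (f[ib] < fb) { fb <- f[ib]; Xb <- X[ib, ] }
    iw <- which.max(f); fw <- f[iw]; Xw <- X[iw, ]
    hist <- c(hist, fb)
  }
  bx <- Xb
  if (length(integer_dims)) bx[integer_dims] <- round(bx[integer_dims])
  list(best_x = bx, best_f = fb, history = hist)
}

sphere <- function(x) sum(x^2)
rastrigin <- function(x) 10 * length(x) + sum(x^2 - 10 * cos(2 * pi * x))

# Uniform random search baseline at a fixed evaluation budget.
with_rand_search <- function(fn, d, budget, seed, lo = -5, hi = 5) {
  set.seed(as.integer(seed))
  best <- Inf
  for (i in seq_len(budget)) best <- min(best, fn(runif(d, lo, hi)))
  best
}
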