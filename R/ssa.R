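#' Sparrow search algorithm configuration
#'
#' Configures the bounded SSA minimizer. The swarm is split each iteration
#' into producers (the best `PD_frac` fraction, wide exploration), followers
#' (the rest, exploitation around the best producer) and `SD` randomly chosen
#' scouts (anti-predation perturbation). `ST` is the warning threshold in
#' \[0.5, 1\] against which a per-iteration alarm value `R2 ~ U(0, 1)` is
#' compared; the defaults (`Gmax = 80`, `P = 50`, `PD_frac = 0.2`, `SD = 5`,
#' `ST = 0.8`) follow common SSA practice for hyperparameter search.
#'
#' @param bounds Numeric matrix with one row per dimension and columns
#'   `lo`, `hi` (`lo < hi`).
#' @param Gmax Maximum iterations (>= 0).
#' @param P Population size.
#' @param PD_frac Producer fraction in (0, 1).
#' @param SD Number of scouts (<= P).
#' @param ST Warning threshold in \[0.5, 1\].
#' @param integer_dims Indices of dimensions rounded before every fitness
#'   evaluation (continuous relaxation for integer hyperparameters).
#' @param seed Optional integer seed.
#' @return An object of class `ssa_config`.
#' @export
ssa_config <- function(bounds, Gmax = 80, P = 50, PD_frac = 0.2, SD = 5,
                       ST = 0.8, integer_dims = integer(0), seed = NULL) {
  bounds <- as.matrix(bounds)
  if (ncol(bounds) != 2L || any(bounds[, 1L] >= bounds[, 2L]))
    stop("`bounds` must be a d x 2 matrix with lo < hi", call. = FALSE)
  if (PD_frac <= 0 || PD_frac >= 1) stop("`PD_frac` must be in (0, 1)")
  if (SD > P) stop("`SD` must be <= P")
  if (ST < 0.5 || ST > 1) stop("`ST` must be in [0.5, 1]")
  if (Gmax < 0 || P < 2) stop("need Gmax >= 0 and P >= 2")
  if (length(integer_dims) && any(!integer_dims %in% seq_len(nrow(bounds))))
    stop("`integer_dims` out of range")
  structure(list(bounds = bounds, Gmax = as.integer(Gmax), P = as.integer(P),
                 PD_frac = PD_frac, SD = as.integer(SD), ST = ST,
                 integer_dims = as.integer(integer_dims), seed = seed),
            class = "ssa_config")
}

ssa_clamp <- function(x, bounds) pmin(pmax(x, bounds[, 1L]), bounds[, 2L])

ssa_eval <- function(fn, x, config) {
  if (length(config$integer_dims))
    x[config$integer_dims] <- round(x[config$integer_dims])
  v <- fn(x)
  if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
    stop("non-finite fitness at point (", paste(signif(x, 6), collapse = ", "),
         ")", call. = FALSE)
  v
}

#' SSA producer update
#'
#' Updates the producer sparrows (ranks `1..ceiling(PD_frac * P)` by current
#' fitness). With alarm below the warning threshold (`R2 < ST`) a producer at
#' rank i contracts multiplicatively, `X <- X * exp(-i / (alpha * Gmax))` with
#' `alpha ~ U(0, 1)`; otherwise it takes a Gaussian step `X <- X + Q` in every
#' dimension with `Q ~ N(0, 1)`. Positions are clamped to the bounds.
#'
#' Low-level building block of [ssa_optimize]; the `state` list carries
#' `X` (P x d positions), `f` (fitness), `ord` (fitness ranking) and `R2`
#' (this iteration's alarm draw).
#'
#' @param state Swarm state list.
#' @param config An [ssa_config].
#' @return The updated state.
#' @export
update_producers <- function(state, config) {
  npd <- ceiling(config$PD_frac * config$P)
  for (k in seq_len(npd)) {
    idx <- state$ord[k]
    if (state$R2 < config$ST) {
      alpha <- stats::runif(1)
      state$X[idx, ] <- state$X[idx, ] * exp(-k / (alpha * max(config$Gmax, 1L)))
    } else {
      Q <- stats::rnorm(1)
      state$X[idx, ] <- state$X[idx, ] + Q
    }
    state$X[idx, ] <- ssa_clamp(state$X[idx, ], config$bounds)
  }
  state
}

#' SSA follower update
#'
#' Updates the non-producer sparrows in rank order. The worse half
#' (rank i > P/2) jump towards the neighbourhood of the current worst
#' position, `X <- Q * exp((Xw - X) / i^2)`; the better half move next to the
#' best producer, `X <- Xb + (|X - Xb| . A+) L`, where `A` is a random +/-1
#' row vector and `A+ = A^T / d` its Moore-Penrose pseudo-inverse, so the
#' update adds the same signed average deviation to every dimension. `Xb` is
#' the rank-1 sparrow's position after the producer phase; `Xw` the rank-P
#' position at phase start.
#'
#' @inheritParams update_producers
#' @return The updated state.
#' @export
update_followers <- function(state, config) {
  npd <- ceiling(config$PD_frac * config$P)
  d <- ncol(state$X)
  Xb <- state$X[state$ord[1L], ]
  Xw <- state$X[state$ord[config$P], ]
  for (k in seq.int(npd + 1L, config$P)) {
    if (k > config$P) break
    idx <- state$ord[k]
    if (k > config$P / 2) {
      Q <- stats::rnorm(1)
      state$X[idx, ] <- Q * exp((Xw - state$X[idx, ]) / k^2)
    } else {
      A <- sample(c(-1, 1), d, replace = TRUE)
      step <- sum(abs(state$X[idx, ] - Xb) * A) / d
      state$X[idx, ] <- Xb + step
    }
    state$X[idx, ] <- ssa_clamp(state$X[idx, ], config$bounds)
  }
  state
}

#' SSA scout update
#'
#' Perturbs `SD` randomly chosen sparrows. A scout whose fitness is worse than
#' the global best (`fi > fg`) relocates around the global best position,
#' `X <- Xb + beta * |X - Xb|` with `beta ~ N(0, 1)`; a scout already at the
#' global best moves relative to the worst, `X <- X + kappa * (X - Xw) /
#' ((fi - fw) + eps)` with `kappa ~ U(-1, 1)` and `eps = 1e-50` guarding the
#' zero division when best and worst fitness coincide.
#'
#' @inheritParams update_producers
#' @return The updated state.
#' @export
update_scouts <- function(state, config) {
  eps <- 1e-50
  idx <- sample.int(config$P, config$SD)
  for (j in idx) {
    if (state$f[j] > state$fb) {
      beta <- stats::rnorm(1)
      state$X[j, ] <- state$Xb + beta * abs(state$X[j, ] - state$Xb)
    } else {
      kappa <- stats::runif(1, -1, 1)
      state$X[j, ] <- state$X[j, ] +
        kappa * (state$X[j, ] - state$Xw) / ((state$f[j] - state$fw) + eps)
    }
    state$X[j, ] <- ssa_clamp(state$X[j, ], config$bounds)
  }
  state
}

#' Minimize a function with the sparrow search algorithm
#'
#' Runs `Gmax` iterations of producer/follower/scout updates over a uniformly
#' initialized population, evaluating every sparrow each iteration (integer
#' dimensions are rounded before evaluation) and tracking the best point ever
#' evaluated, so the reported history is monotone non-increasing.
#'
#' @param fn Scalar fitness function of a numeric vector; must be finite on
#'   the box.
#' @param config An [ssa_config].
#' @return List of class `ssa_fit`: `best_x` (integer dims rounded),
#'   `best_f`, `history` (best-so-far per iteration, length `Gmax + 1`
#'   including the initial population), and `n_evals`.
#' @export
#' @examples
#' cfg <- ssa_config(cbind(rep(-5, 3), rep(5, 3)), Gmax = 30, P = 10, seed = 1)
#' fit <- ssa_optimize(function(x) sum(x^2), cfg)
#' fit$best_f
ssa_optimize <- function(fn, config) {
  stopifnot(inherits(config, "ssa_config"))
  d <- nrow(config$bounds)
  lo <- config$bounds[, 1L]; hi <- config$bounds[, 2L]
  with_seed(config$seed, {
    X <- matrix(stats::runif(config$P * d), config$P, d)
    X <- sweep(sweep(X, 2L, hi - lo, "*"), 2L, lo, "+")
    f <- vapply(seq_len(config$P), function(i) ssa_eval(fn, X[i, ], config),
                numeric(1))
    n_evals <- config$P
    ib <- which.min(f); iw <- which.max(f)
    state <- list(X = X, f = f, Xb = X[ib, ], fb = f[ib],
                  Xw = X[iw, ], fw = f[iw])
    history <- state$fb
    for (t in seq_len(config$Gmax)) {
      state$ord <- order(state$f)
      state$R2 <- stats::runif(1)
      state <- update_producers(state, config)
      state <- update_followers(state, config)
      state <- update_scouts(state, config)
      state$f <- vapply(seq_len(config$P),
                        function(i) ssa_eval(fn, state$X[i, ], config),
                        numeric(1))
      n_evals <- n_evals + config$P
      ib <- which.min(state$f)
      if (state$f[ib] < state$fb) {
        state$fb <- state$f[ib]
        state$Xb <- state$X[ib, ]
      }
      iw <- which.max(state$f)
      state$fw <- state$f[iw]
      state$Xw <- state$X[iw, ]
      history <- c(history, state$fb)
    }
    best_x <- state$Xb
    if (length(config$integer_dims))
      best_x[config$integer_dims] <- round(best_x[config$integer_dims])
    structure(list(best_x = best_x, best_f = state$fb, history = history,
                   n_evals = n_evals, config = config),
              class = "ssa_fit")
  })
}

#' @export
print.ssa_fit <- function(x, ...) {
  cat(sprintf("<ssa_fit> best f = %.6g at (%s) after %d evaluations\n",
              x$best_f, paste(signif(x$best_x, 6), collapse = ", "),
              x$n_evals))
  invisible(x)
}

#' @export
plot.ssa_fit <- function(x, ...) {
  graphics::plot(seq_along(x$history) - 1L, x$history, type = "s",
                 xlab = "iteration", ylab = "best fitness",
                 main = "SSA convergence", ...)
  invisible(x)
}
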