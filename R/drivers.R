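#' Synthetic driver fields as Gaussian random fields
#'
#' Generates smoothly varying continuous covariate surfaces by circular
#' convolution of white noise with a Gaussian kernel of the requested
#' correlation length (FFT-based, so the field wraps at the edges, which is
#' immaterial for synthetic benchmarks). Fields are standardized to zero mean
#' and unit variance by default.
#'
#' @param shape Integer vector `c(nrow, ncol)`, both positive.
#' @param names Character vector of driver names (default all eleven from
#'   [driver_names()]).
#' @param corr_len Correlation length in cells (>= 1), recycled over drivers.
#' @param seed Optional integer seed; identical seeds give bit-identical
#'   fields.
#' @param standardize Standardize each field to mean 0, sd 1 (default TRUE).
#' @return A named list of `driver_field` objects, each holding `name`,
#'   a numeric `values` matrix and a `static` flag (TRUE for the topographic
#'   drivers ELE and SLO, which do not change between epochs).
#' @export
#' @examples
#' flds <- make_driver_fields(c(40, 40), corr_len = 8, seed = 1)
#' names(flds)
make_driver_fields <- function(shape, names = driver_names(), corr_len = 20,
                               seed = NULL, standardize = TRUE) {
  if (length(shape) != 2L || any(shape < 1) || any(shape != round(shape)))
    stop("`shape` must be two positive integers", call. = FALSE)
  if (any(corr_len < 1))
    stop("`corr_len` must be >= 1 cell", call. = FALSE)
  corr_len <- rep_len(corr_len, length(names))
  with_seed(seed, {
    fields <- vector("list", length(names))
    for (i in seq_along(names)) {
      v <- gaussian_random_field(shape[1L], shape[2L], corr_len[i])
      if (standardize) v <- standardize_field(v)
      fields[[i]] <- structure(
        list(name = names[i], values = v,
             static = names[i] %in% c("ELE", "SLO")),
        class = "driver_field")
    }
    stats::setNames(fields, names)
  })
}

#' @export
print.driver_field <- function(x, ...) {
  cat(sprintf("<driver_field> %s (%s), %d x %d, mean %.3g, sd %.3g\n",
              x$name, if (x$static) "static" else "per-epoch",
              nrow(x$values), ncol(x$values),
              mean(x$values), stats::sd(x$values)))
  invisible(x)
}

# Smooth wrapped Gaussian random field: white noise * Gaussian kernel via FFT.
gaussian_random_field <- function(nr, nc, corr_len) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  dy <- pmin(0:(nr - 1L), nr - 0:(nr - 1L))
  dx <- pmin(0:(nc - 1L), nc - 0:(nc - 1L))
  k <- exp(-outer(dy^2, dx^2, "+") / (2 * corr_len^2))
  f <- Re(stats::fft(stats::fft(z) * stats::fft(k), inverse = TRUE)) / (nr * nc)
  f
}

#' Standardize a field to zero mean and unit variance
#'
#' @param values Numeric matrix.
#' @param mask Optional logical matrix; statistics are computed over `TRUE`
#'   cells only (all cells are still transformed).
#' @return Matrix with `|mean| < 1e-9` and `|sd - 1| < 1e-9` over the mask.
#' @export
standardize_field <- function(values, mask = NULL) {
  v <- if (is.null(mask)) as.vector(values) else values[mask]
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0)
    stop("field is constant; cannot standardize", call. = FALSE)
  (values - mean(v)) / s
}
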