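#' @useDynLib mtsimage, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats quantile approx rnorm runif
#' @importFrom utils read.csv write.csv read.table write.table capture.output
NULL

.check_series <- function(x, min_len = 2L) {
  if (!is.numeric(x)) stop("series must be numeric", call. = FALSE)
  if (length(x) < min_len)
    stop(sprintf("series must have length >= %d", min_len), call. = FALSE)
  if (any(!is.finite(x)))
    stop("series contains non-finite values (NaN/Inf/NA)", call. = FALSE)
  invisible(x)
}

#' Rescale a univariate series to the unit interval
#'
#' Applies the min-max map `(x - min(x)) / (max(x) - min(x))`, the first step
#' of every field encoding. A constant series has no range; by convention it
#' maps to the mid-range value 0.5 everywhere so that flat sensor channels do
#' not abort a batch (the MTF encoder still rejects such a channel because it
#' cannot be binned).
#'
#' @param x Numeric vector, length >= 2, finite values.
#' @return Numeric vector in `[0, 1]`; for non-constant input the minimum is
#'   exactly 0 and the maximum exactly 1.
#' @examples
#' rescale_01(c(0, 5, 10))
#' rescale_01(c(7, 7, 7))
#' @export
rescale_01 <- function(x) {
  .check_series(x)
  rng <- range(x)
  if (rng[1] == rng[2]) return(rep(0.5, length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Piecewise aggregate approximation
#'
#' Reduces a length-`T` series to length `N` by replacing contiguous segments
#' with their means. Segment boundaries are `floor(l * T / N)` (1-based), so
#' segment sizes differ by at most one and the segmentation is exact whenever
#' `N` divides `T`. `paa(x, length(x))` returns `x` unchanged and
#' `paa(x, 1)` returns the global mean.
#'
#' @param x Numeric vector (finite values).
#' @param N Target length, integer in `[1, length(x)]`.
#' @return Numeric vector of length `N` of segment means.
#' @examples
#' paa(c(1, 2, 3, 4), 2)       # 1.5 3.5
#' paa(c(1, 2, 3, 4, 5), 2)    # 1.5 4.0
#' @export
paa <- function(x, N) {
  .check_series(x, min_len = 1L)
  Tn <- length(x)
  if (length(N) != 1L || !is.finite(N) || N != as.integer(N) || N < 1 || N > Tn)
    stop("N must be a single integer in [1, length(x)]", call. = FALSE)
  N <- as.integer(N)
  if (N == Tn) return(x)
  ends <- floor(seq_len(N) * Tn / N)
  starts <- c(1L, ends[-N] + 1L)
  vapply(seq_len(N), function(l) mean(x[starts[l]:ends[l]]), numeric(1))
}

#' Resample a series to a fixed length
#'
#' Length normalization used to give every channel the common image size `n`:
#' series at least as long as `n` are reduced with [paa()]; shorter series are
#' linearly interpolated onto `n` equally spaced points over their time span,
#' which preserves shape without inventing structure.
#'
#' @param x Numeric vector, length >= 2.
#' @param n Target length, positive integer.
#' @return Numeric vector of length exactly `n`.
#' @export
resample_to <- function(x, n) {
  .check_series(x)
  if (length(n) != 1L || !is.finite(n) || n != as.integer(n) || n < 1)
    stop("n must be a single positive integer", call. = FALSE)
  n <- as.integer(n)
  if (length(x) >= n) return(paa(x, n))
  approx(x = seq_along(x), y = x, n = n)$y
}

.check_rescaled <- function(x, tol = 1e-12) {
  .check_series(x)
  if (any(x < -tol) || any(x > 1 + tol))
    stop("values must lie in [0, 1]; rescale the series first", call. = FALSE)
  pmin(pmax(x, 0), 1)   # absorb rounding within tol before arccos/sqrt
}

.field_matrix <- function(M, method, range) {
  structure(M, class = c("field_matrix", class(M)),
            method = method, theoretical_range = range)
}

#' @export
print.field_matrix <- function(x, ...) {
  cat(sprintf("<field_matrix> %s, %d x %d, theoretical range [%g, %g]\n",
              attr(x, "method"), nrow(x), ncol(x),
              attr(x, "theoretical_range")[1], attr(x, "theoretical_range")[2]))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x))), drop = FALSE], ...)
  invisible(x)
}

#' Gramian Angular Summation Field
#'
#' Encodes a `[0,1]`-rescaled series as the n-by-n matrix with entries
#' `cos(phi_i + phi_j)` where `phi = arccos(x)`; equivalently the Gram-like
#' outer-product form `x x' - sqrt(1 - x^2) sqrt(1 - x^2)'`. The result is
#' symmetric, its entries lie in `[-1, 1]`, and the diagonal `2 x_i^2 - 1`
#' lets the rescaled series be recovered as `sqrt((diag + 1) / 2)`.
#'
#' @param x Numeric vector with values in `[0, 1]` (see [rescale_01()]).
#' @return A `field_matrix` with method `"GASF"` and theoretical range
#'   `[-1, 1]`.
#' @examples
#' gasf(c(0, 1))
#' @export
gasf <- function(x) {
  x <- .check_rescaled(x)
  s <- sqrt(1 - x^2)
  M <- outer(x, x) - outer(s, s)
  .field_matrix(M, "GASF", c(-1, 1))
}

#' Gramian Angular Difference Field
#'
#' Encodes a `[0,1]`-rescaled series as the n-by-n matrix with entries
#' `sin(phi_i - phi_j) = sqrt(1 - x_i^2) x_j - x_i sqrt(1 - x_j^2)`.
#' The result is antisymmetric with a zero diagonal and entries in `[-1, 1]`.
#'
#' @inheritParams gasf
#' @return A `field_matrix` with method `"GADF"` and theoretical range
#'   `[-1, 1]`.
#' @examples
#' gadf(c(0, 1))
#' @export
gadf <- function(x) {
  x <- .check_rescaled(x)
  s <- sqrt(1 - x^2)
  M <- outer(s, x) - outer(x, s)
  .field_matrix(M, "GADF", c(-1, 1))
}

#' Fit a first-order Markov model on quantile bins
#'
#' Assigns each value of a rescaled series to one of `b` quantile bins
#' (right-closed bins, the lowest closed on both ends; edges are the empirical
#' `i/b` quantiles) and estimates the bin-to-bin transition matrix `W` from
#' consecutive pairs: `W[i, j]` is the fraction of transitions leaving bin `i`
#' that arrive in bin `j`. Rows with no observed outgoing transition are left
#' all-zero rather than imputed.
#'
#' @param x Numeric vector in `[0, 1]`, length >= 2.
#' @param b Number of quantile bins, integer >= 2; must not exceed the number
#'   of distinct values in `x`.
#' @return A list of class `markov_model` with elements `bin_edges`
#'   (`b - 1` quantiles), `W` (`b` x `b` row-stochastic-or-zero matrix),
#'   `b`, and `bins` (the per-timestep bin index).
#' @examples
#' fit_markov(c(0, 0, 1, 1), 2)$W
#' @export
fit_markov <- function(x, b) {
  x <- .check_rescaled(x)
  if (length(b) != 1L || !is.finite(b) || b != as.integer(b) || b < 2)
    stop("b must be a single integer >= 2", call. = FALSE)
  b <- as.integer(b)
  n_distinct <- length(unique(x))
  if (b > n_distinct)
    stop(sprintf(
      "degenerate binning: b = %d exceeds the %d distinct value(s) in the series",
      b, n_distinct), call. = FALSE)
  edges <- unname(quantile(x, probs = seq_len(b - 1L) / b, names = FALSE))
  # right-closed bins: bin(v) = 1 + #(edges < v); lowest bin closed at both ends
  bins <- rowSums(outer(x, edges, ">")) + 1L
  counts <- matrix(0, b, b)
  from <- bins[-length(bins)]
  to <- bins[-1L]
  for (k in seq_along(from)) counts[from[k], to[k]] <- counts[from[k], to[k]] + 1
  out <- rowSums(counts)
  W <- counts
  nz <- out > 0
  W[nz, ] <- counts[nz, , drop = FALSE] / out[nz]
  structure(list(bin_edges = edges, W = W, b = b, bins = as.integer(bins)),
            class = "markov_model")
}

#' Markov Transition Field
#'
#' Encodes a rescaled series as the n-by-n matrix whose `(i, j)` entry is the
#' first-order transition probability from the quantile bin of `x[i]` to the
#' quantile bin of `x[j]` under the model fitted by [fit_markov()]. Entries
#' are probabilities in `[0, 1]`; unlike the Gramian fields the matrix is
#' generally not symmetric and cannot be inverted back to the series.
#'
#' @inheritParams fit_markov
#' @return A `field_matrix` with method `"MTF"` and theoretical range
#'   `[0, 1]`.
#' @examples
#' mtf(c(0, 0, 1, 1), 2)
#' @export
mtf <- function(x, b = 8L) {
  model <- fit_markov(x, b)
  M <- model$W[model$bins, model$bins, drop = FALSE]
  dimnames(M) <- NULL
  .field_matrix(M, "MTF", c(0, 1))
}

#' Encode one channel end to end
#'
#' Convenience composition used throughout the pipeline: rescale to `[0,1]`,
#' length-normalize to `n` (PAA down, linear interpolation up), then apply the
#' chosen encoder. Segment means and interpolants are convex combinations of
#' the rescaled values, so the resampled series stays inside `[0, 1]`.
#'
#' @param x Numeric vector (raw sensor values), length >= 2.
#' @param method One of `"GASF"`, `"GADF"`, `"MTF"` (case-insensitive).
#' @param n Image size (output is `n` x `n`).
#' @param b Quantile bin count for MTF; ignored by the Gramian encoders.
#' @return A `field_matrix` of size `n` x `n`.
#' @export
encode_series <- function(x, method = c("GASF", "GADF", "MTF"), n = 128L, b = 8L) {
  method <- toupper(method)
  method <- match.arg(method, c("GASF", "GADF", "MTF"))
  z <- resample_to(rescale_01(x), n)
  switch(method, GASF = gasf(z), GADF = gadf(z), MTF = mtf(z, b))
}
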