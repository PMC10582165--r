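## Small separable filtering kernel shared by the fusion and preprocessing
## code. All filters use symmetric (mirror) border extension so flat regions
## stay flat up to the image edge.

## pad a matrix by mirror reflection (without repeating the edge sample when
## reflect_edge = FALSE is not needed here; simple symmetric half-sample)
pad_sym <- function(X, r) {
  if (r == 0) return(X)
  n <- nrow(X); m <- ncol(X)
  ri <- c(pmin(r:1, n), 1:n, n - pmin(1:r, n) + 1)
  ci <- c(pmin(r:1, m), 1:m, m - pmin(1:r, m) + 1)
  X[ri, ci, drop = FALSE]
}

## 1-D convolution of every column with an odd-length kernel, symmetric border
conv_cols <- function(X, kernel) {
  k <- length(kernel)
  r <- (k - 1L) %/% 2L
  n <- nrow(X)
  Xp <- pad_sym(X, r)[, seq_len(ncol(X)) + r, drop = FALSE]
  out <- matrix(0, n, ncol(X))
  for (i in seq_len(k)) {
    out <- out + kernel[i] * Xp[(i - 1L) + seq_len(n), , drop = FALSE]
  }
  out
}

## separable 2-D convolution (same kernel along rows and columns)
conv_sep <- function(X, kernel) {
  t(conv_cols(t(conv_cols(X, kernel)), kernel))
}

## box mean over a (2r+1)^2 window, symmetric border
box_filter <- function(X, r) {
  if (r == 0) return(X)
  k <- rep(1 / (2 * r + 1), 2 * r + 1)
  conv_sep(X, k)
}

## Gaussian blur with a truncated, renormalized kernel
gaussian_kernel <- function(sigma, radius = max(1L, ceiling(3 * sigma))) {
  x <- -radius:radius
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

gaussian_blur <- function(X, sigma) {
  if (sigma <= 0) return(X)
  conv_sep(X, gaussian_kernel(sigma))
}

## gradient magnitude by central differences, replicated border
gradient_magnitude <- function(X) {
  n <- nrow(X); m <- ncol(X)
  gx <- X[, c(2:m, m), drop = FALSE] - X[, c(1, 1:(m - 1)), drop = FALSE]
  gy <- X[c(2:n, n), , drop = FALSE] - X[c(1, 1:(n - 1)), , drop = FALSE]
  sqrt(gx^2 + gy^2)
}

#' Gaussian smoothing of a slice
#'
#' Classical separable Gaussian filter, provided as the dependency-free
#' alternative to the learned denoiser.
#'
#' @param image A [slice_image()].
#' @param sigma Kernel standard deviation in pixels (default 1).
#' @return Smoothed `slice_image`, same dimensions and bit depth.
#' @export
smooth_gaussian <- function(image, sigma = 1) {
  reslice(image, gaussian_blur(px(image), sigma))
}
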