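## Orthonormal DCT-II, implemented as a cached transform matrix per size.
## At the slice sizes this package works with (<= 512), the matrix product
## is both trivial in cost and exactly invertible (D is orthogonal), which
## the coefficient-domain fusion relies on.

.dct_cache <- new.env(parent = emptyenv())

dct_matrix <- function(N) {
  key <- as.character(N)
  if (!is.null(.dct_cache[[key]])) return(.dct_cache[[key]])
  n <- 0:(N - 1)
  D <- sqrt(2 / N) * cos(pi * outer(n, n + 0.5) / N)
  D[1, ] <- D[1, ] / sqrt(2)
  .dct_cache[[key]] <- D
  D
}

## 2-D orthonormal DCT-II and its inverse
dct2 <- function(X) {
  Dr <- dct_matrix(nrow(X)); Dc <- dct_matrix(ncol(X))
  Dr %*% X %*% t(Dc)
}

idct2 <- function(C) {
  Dr <- dct_matrix(nrow(C)); Dc <- dct_matrix(ncol(C))
  t(Dr) %*% C %*% Dc
}
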