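## Fused-image quality metrics: Shannon entropy of the gray-level
## histogram, population standard deviation, PSNR against a source, and the
## global-moment structural similarity index. Conventions:
##   * entropy uses exactly L integer bins on [0, L-1] (no adaptive binning);
##   * STD uses the population divisor M*N;
##   * PSNR's peak L is the maximum representable intensity (L - 1 levels,
##     i.e. 255 for 8-bit) unless `peak = "image_max"`;
##   * SSIM is computed from whole-image moments (one global window) with
##     the standard stabilizers K1 = 0.01, K2 = 0.03; a uniform sliding
##     window with border-clipped normalization is available via
##     `window_radius`, and reduces to the global value when the window
##     covers the image.

#' Shannon entropy of a slice (bits)
#'
#' `-sum(p_i log2 p_i)` over the non-empty bins of the L-bin gray-level
#' histogram; ranges from 0 (constant image) to `log2(L)` (all levels
#' equiprobable). Non-integer intensities are quantized onto the slice's
#' gray-level grid first.
#'
#' @param image A [slice_image()].
#' @return Entropy in bits.
#' @export
img_entropy <- function(image) {
  if (length(image) == 0L) stop("img_entropy: empty image")
  L <- attr(image, "bit_depth") %||% 256L
  v <- as.vector(px(quantize_slice(image)))
  counts <- tabulate(v + 1L, nbins = L)
  p <- counts[counts > 0] / length(v)
  -sum(p * log2(p))
}

#' Population standard deviation of a slice
#'
#' @param image A [slice_image()] or matrix.
#' @return SD in intensity units, divisor M*N.
#' @export
img_std <- function(image) {
  v <- as.vector(px(image))
  sqrt(mean((v - mean(v))^2))
}

#' Peak signal-to-noise ratio between a source and the fused slice (dB)
#'
#' `10 log10(L^2 / RMSE^2)`; identical images return `Inf` (excluded, with
#' a count, from cohort averages by [quality_table()]).
#'
#' @param source,fused [slice_image()]s of equal dimensions.
#' @param peak `"bit_depth"` (default; `L = bit_depth - 1` of the fused
#'   slice) or `"image_max"` (the fused slice's own maximum).
#' @return PSNR in dB.
#' @export
img_psnr <- function(source, fused, peak = c("bit_depth", "image_max")) {
  peak <- match.arg(peak)
  check_same_dim(source, fused, "img_psnr")
  A <- px(source); F_ <- px(fused)
  rmse <- sqrt(mean((A - F_)^2))
  if (rmse == 0) return(Inf)
  L <- if (peak == "bit_depth") (attr(fused, "bit_depth") %||% 256L) - 1 else max(F_)
  10 * log10(L^2 / rmse^2)
}

## global-moment SSIM between two matrices (population moments)
ssim_global <- function(A, F_, C1, C2) {
  muA <- mean(A); muF <- mean(F_)
  vA <- mean((A - muA)^2); vF <- mean((F_ - muF)^2)
  cAF <- mean((A - muA) * (F_ - muF))
  ((2 * muA * muF + C1) * (2 * cAF + C2)) /
    ((muA^2 + muF^2 + C1) * (vA + vF + C2))
}

## border-clipped uniform-window local means: every pixel's window is the
## intersection of the (2r+1)^2 square with the image, normalized by the
## pixels actually covered -- so r >= image size reproduces global moments
local_mean_clipped <- function(X, r) {
  n <- nrow(X); m <- ncol(X)
  S <- t(apply(apply(X, 2, cumsum), 1, cumsum)) # S[i, j] = sum X[1:i, 1:j]
  ## integral-image window sums via padded cumulative matrix
  Sp <- matrix(0, n + 1, m + 1); Sp[2:(n + 1), 2:(m + 1)] <- S
  i1 <- pmax(row(X) - r, 1); i2 <- pmin(row(X) + r, n)
  j1 <- pmax(col(X) - r, 1); j2 <- pmin(col(X) + r, m)
  sums <- Sp[cbind(as.vector(i2 + 1), as.vector(j2 + 1))] -
    Sp[cbind(as.vector(i1), as.vector(j2 + 1))] -
    Sp[cbind(as.vector(i2 + 1), as.vector(j1))] +
    Sp[cbind(as.vector(i1), as.vector(j1))]
  counts <- (i2 - i1 + 1) * (j2 - j1 + 1)
  matrix(sums / as.vector(counts), n, m)
}

ssim_windowed <- function(A, F_, C1, C2, r) {
  muA <- local_mean_clipped(A, r); muF <- local_mean_clipped(F_, r)
  vA <- local_mean_clipped(A * A, r) - muA^2
  vF <- local_mean_clipped(F_ * F_, r) - muF^2
  cAF <- local_mean_clipped(A * F_, r) - muA * muF
  map <- ((2 * muA * muF + C1) * (2 * cAF + C2)) /
    ((muA^2 + muF^2 + C1) * (vA + vF + C2))
  mean(map)
}

#' Structural similarity of a fused image to its two sources
#'
#' `SSIM(A, B, F) = (SSIM(A, F) + SSIM(B, F)) / 2`, each term the
#' luminance-contrast-structure product computed from image moments with
#' stabilizers `C1 = (K1 L)^2`, `C2 = (K2 L)^2`. Equals 1 when the fused
#' image is identical to both sources.
#'
#' @param a,b Source [slice_image()]s.
#' @param fused Fused slice of the same dimensions.
#' @param K1,K2 Stabilizer constants (defaults 0.01, 0.03).
#' @param window_radius `NULL` (default) for one global window; an integer
#'   radius for a uniform sliding window with border-clipped normalization.
#' @return Combined SSIM (unitless).
#' @export
ssim_pair <- function(a, b, fused, K1 = 0.01, K2 = 0.03, window_radius = NULL) {
  check_same_dim(a, fused, "ssim_pair")
  check_same_dim(b, fused, "ssim_pair")
  L <- (attr(fused, "bit_depth") %||% 256L) - 1
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  A <- px(a); B <- px(b); F_ <- px(fused)
  if (is.null(window_radius)) {
    (ssim_global(A, F_, C1, C2) + ssim_global(B, F_, C1, C2)) / 2
  } else {
    (ssim_windowed(A, F_, C1, C2, window_radius) +
       ssim_windowed(B, F_, C1, C2, window_radius)) / 2
  }
}

#' Per-subject quality metrics of one fusion result
#'
#' @param a,b The source slices the fused image came from.
#' @param result A `fusion_result`.
#' @return One-row data frame: method, entropy, std, psnr (mean of the two
#'   per-source PSNRs), psnr_a, psnr_b, ssim.
#' @export
fused_quality <- function(a, b, result) {
  f <- result$fused
  pa <- img_psnr(a, f); pb <- img_psnr(b, f)
  data.frame(method = result$method,
             entropy = img_entropy(f),
             std = img_std(f),
             psnr = mean(c(pa, pb)),
             psnr_a = pa, psnr_b = pb,
             ssim = ssim_pair(a, b, f))
}

#' Cohort quality table
#'
#' Aggregates per-(subject, method) metric rows into per-method cohort
#' means. Infinite PSNR sentinels (identical images) are excluded from the
#' PSNR average and counted in `psnr_inf_n`. The best method per metric
#' column is flagged.
#'
#' @param per_subject Data frame with columns `method`, `entropy`, `std`,
#'   `psnr`, `ssim` (one row per subject and method).
#' @return An object of class `quality_report` with elements `per_subject`,
#'   `summary`, and `best`.
#' @export
quality_table <- function(per_subject) {
  stopifnot(all(c("method", "entropy", "std", "psnr", "ssim") %in%
                  names(per_subject)))
  methods <- unique(per_subject$method)
  rows <- lapply(methods, function(m) {
    d <- per_subject[per_subject$method == m, ]
    fin <- is.finite(d$psnr)
    data.frame(method = m,
               entropy = mean(d$entropy),
               std = mean(d$std),
               psnr = if (any(fin)) mean(d$psnr[fin]) else NA_real_,
               psnr_inf_n = sum(!fin),
               ssim = mean(d$ssim),
               n = nrow(d))
  })
  summary <- do.call(rbind, rows)
  best <- vapply(c("entropy", "std", "psnr", "ssim"), function(col)
    summary$method[which.max(summary[[col]])], "")
  structure(list(per_subject = per_subject, summary = summary, best = best),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat("Cohort-average fused-image quality (higher is better):\n")
  print(x$summary, row.names = FALSE, digits = 4)
  cat("Best per metric:",
      paste(sprintf("%s=%s", names(x$best), x$best), collapse = ", "), "\n")
  invisible(x)
}
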