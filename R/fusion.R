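## Classical fusion methods. All methods operate on float intensities and
## quantize once, on output; the float fused image is kept alongside the
## quantized slice because the contrast statistic downstream is computed on
## the working scale.

## shared result container
fusion_result <- function(fused_float, template, method, params,
                          provenance = NULL) {
  L <- attr(template, "bit_depth") %||% 256L
  over <- mean(fused_float < 0 | fused_float > L - 1)
  fused <- quantize_slice(slice_image(pmin(pmax(fused_float, 0), L - 1),
                                      bit_depth = L,
                                      spacing = attr(template, "spacing") %||% c(1, 1),
                                      modality = "FUSED"))
  structure(list(fused = fused, fused_float = fused_float, method = method,
                 params = params, provenance = provenance,
                 overflow_fraction = over),
            class = "fusion_result")
}

#' @export
print.fusion_result <- function(x, ...) {
  cat(sprintf("<fusion_result> %s, %dx%d px, %.2f%% out-of-range before clipping\n",
              x$method, nrow(x$fused), ncol(x$fused), 100 * x$overflow_fraction))
  invisible(x)
}

check_same_dim <- function(a, b, what) {
  if (!all(dim(a) == dim(b)))
    stop(what, ": source images must share dimensions")
}

#' PCA image fusion
#'
#' The two flattened pixel vectors are treated as variables; the eigenvector
#' of the largest eigenvalue of their 2x2 covariance gives the fusion
#' weights `w_i = v_i / (v1 + v2)`, and the fused image is the corresponding
#' weighted sum. If both inputs are constant (zero covariance) the weights
#' fall back to 0.5/0.5 with a warning.
#'
#' @param a,b Source [slice_image()]s (or matrices) of equal dimensions.
#' @param provenance Optional subject identifier carried into the result.
#' @return A `fusion_result`.
#' @export
fuse_pca <- function(a, b, provenance = NULL) {
  check_same_dim(a, b, "fuse_pca")
  A <- px(a); B <- px(b)
  C <- stats::cov(cbind(as.vector(A), as.vector(B)))
  if (all(abs(C) < .Machine$double.eps)) {
    warning("fuse_pca: zero covariance (both inputs constant); equal weights")
    w <- c(0.5, 0.5)
  } else {
    v <- eigen(C, symmetric = TRUE)$vectors[, 1]
    if (v[1] < 0) v <- -v                      # deterministic sign
    if (abs(sum(v)) < .Machine$double.eps) {
      warning("fuse_pca: degenerate eigenvector; equal weights")
      w <- c(0.5, 0.5)
    } else {
      w <- v / sum(v)
    }
  }
  fused <- w[1] * A + w[2] * B
  fusion_result(fused, a, "PCA", list(weights = w), provenance)
}

## symmetric padding of both images to dimensions divisible by 2^levels;
## returns padded matrices plus the crop window
pad_to_multiple <- function(X, mult) {
  n <- nrow(X); m <- ncol(X)
  pr <- (mult - n %% mult) %% mult
  pc <- (mult - m %% mult) %% mult
  if (pr == 0 && pc == 0) return(list(X = X, rows = seq_len(n), cols = seq_len(m)))
  r <- max(pr, pc)
  Xp <- pad_sym(X, r)
  list(X = Xp[(r + 1):(r + n + pr), (r + 1):(r + m + pc), drop = FALSE],
       rows = seq_len(n), cols = seq_len(m))
}

## dyadic sub-band index masks on an n x m DCT coefficient plane
dchwt_band_masks <- function(n, m, levels) {
  stopifnot(n %% 2^levels == 0, m %% 2^levels == 0)
  masks <- vector("list", levels + 1L)
  ridx <- row(matrix(0, n, m)); cidx <- col(matrix(0, n, m))
  for (l in seq_len(levels)) {
    hi_r <- n / 2^(l - 1); hi_c <- m / 2^(l - 1)
    lo_r <- n / 2^l; lo_c <- m / 2^l
    masks[[l]] <- (ridx <= hi_r & cidx <= hi_c) & (ridx > lo_r | cidx > lo_c)
  }
  masks[[levels + 1L]] <- ridx <= n / 2^levels & cidx <= m / 2^levels
  names(masks) <- c(sprintf("detail%d", seq_len(levels)), "approx")
  masks
}

#' DCT-domain harmonic-wavelet decomposition
#'
#' The orthonormal 2-D DCT of the image is partitioned into dyadic
#' frequency sub-bands: a low-frequency approximation block and, per level,
#' an L-shaped detail band. Because the partition is a relabelling of an
#' orthogonal transform's coefficients, forward-then-inverse reconstruction
#' is exact to rounding.
#'
#' @param image A [slice_image()] or matrix, dimensions divisible by
#'   `2^levels`.
#' @param levels Decomposition depth (default 3).
#' @return List with the coefficient matrix, the band masks, and `levels`.
#' @export
dchwt_decompose <- function(image, levels = 3L) {
  X <- px(image)
  if (nrow(X) %% 2^levels != 0 || ncol(X) %% 2^levels != 0)
    stop("dchwt_decompose: dimensions must be divisible by 2^levels")
  list(coefficients = dct2(X),
       masks = dchwt_band_masks(nrow(X), ncol(X), levels),
       levels = levels)
}

#' @rdname dchwt_decompose
#' @param decomposition Result of `dchwt_decompose`.
#' @export
dchwt_reconstruct <- function(decomposition) {
  idct2(decomposition$coefficients)
}

#' DCHWT image fusion
#'
#' Both sources are decomposed with [dchwt_decompose()]; detail coefficients
#' are fused by absolute-maximum selection (ties to `a`), approximation
#' coefficients by averaging, and the fused slice is the inverse transform.
#' Dimensions not divisible by `2^levels` are mirror-padded and cropped on
#' output, with a warning.
#'
#' @param a,b Source [slice_image()]s of equal dimensions.
#' @param levels Decomposition depth (default 3).
#' @param provenance Optional subject identifier.
#' @return A `fusion_result`.
#' @export
fuse_dchwt <- function(a, b, levels = 3L, provenance = NULL) {
  check_same_dim(a, b, "fuse_dchwt")
  A <- px(a); B <- px(b)
  mult <- 2^levels
  padded <- nrow(A) %% mult != 0 || ncol(A) %% mult != 0
  if (padded)
    warning("fuse_dchwt: dimensions not divisible by 2^levels; padding symmetrically")
  pa <- pad_to_multiple(A, mult); pb <- pad_to_multiple(B, mult)
  Ca <- dct2(pa$X); Cb <- dct2(pb$X)
  masks <- dchwt_band_masks(nrow(pa$X), ncol(pa$X), levels)
  Cf <- ifelse(abs(Ca) >= abs(Cb), Ca, Cb)     # abs-max details, ties -> a
  Cf[masks$approx] <- (Ca[masks$approx] + Cb[masks$approx]) / 2
  fused <- idct2(Cf)[pa$rows, pa$cols, drop = FALSE]
  fusion_result(fused, a, "DCHWT", list(levels = levels), provenance)
}

## guided filter (He et al. style), self-guided when guide == input
guided_filter <- function(I, p, r, eps) {
  mI <- box_filter(I, r); mp <- box_filter(p, r)
  corrI <- box_filter(I * I, r); corrIp <- box_filter(I * p, r)
  varI <- corrI - mI^2
  covIp <- corrIp - mI * mp
  a <- covIp / (varI + eps)
  b <- mp - a * mI
  box_filter(a, r) * I + box_filter(b, r)
}

#' Structure-aware two-scale image fusion
#'
#' Each source is split into a base layer (edge-preserving guided
#' self-filtering) and a detail layer. Per-pixel weight maps come from local
#' structure saliency -- Gaussian-smoothed gradient magnitude -- normalized
#' so the two sources' weights sum to 1 at every pixel; the base weights are
#' additionally smoothed (and renormalized) so large-scale brightness blends
#' softly while structure transfers sharply. The fused image is the weighted
#' base plus the weighted detail.
#'
#' @param a,b Source [slice_image()]s of equal dimensions.
#' @param params Optional overrides: `base_radius` (guided filter radius,
#'   default 8), `eps_scale` (guided filter regularizer as a fraction of the
#'   squared intensity range, default 0.01), `saliency_sigma` (default 4),
#'   `base_sigma` (extra smoothing of the base weights, default 8).
#' @param provenance Optional subject identifier.
#' @return A `fusion_result`; the detail weight map of source `a` is kept in
#'   `params$weight_a`.
#' @export
fuse_structure_aware <- function(a, b, params = list(), provenance = NULL) {
  check_same_dim(a, b, "fuse_structure_aware")
  p <- utils::modifyList(list(base_radius = 8L, eps_scale = 0.01,
                              saliency_sigma = 4, base_sigma = 8), params)
  A <- px(a); B <- px(b)
  L <- attr(a, "bit_depth") %||% 256L
  eps <- p$eps_scale * (L - 1)^2
  baseA <- guided_filter(A, A, p$base_radius, eps)
  baseB <- guided_filter(B, B, p$base_radius, eps)
  detA <- A - baseA; detB <- B - baseB
  sA <- gaussian_blur(gradient_magnitude(A), p$saliency_sigma)
  sB <- gaussian_blur(gradient_magnitude(B), p$saliency_sigma)
  tiny <- 1e-12
  wA <- (sA + tiny) / (sA + sB + 2 * tiny)
  wAb <- gaussian_blur(wA, p$base_sigma)
  wBb <- gaussian_blur(1 - wA, p$base_sigma)
  wAbase <- wAb / (wAb + wBb)
  fused <- wAbase * baseA + (1 - wAbase) * baseB + wA * detA + (1 - wA) * detB
  fusion_result(fused, a, "STRUCTURE_AWARE",
                c(p, list(weight_a = wA, weight_a_base = wAbase)), provenance)
}
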