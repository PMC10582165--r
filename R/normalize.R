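#' Control-region intensity normalization
#'
#' Linear standardization against a control region of normal-appearing white
#' matter: the slice is rescaled as `a * x + b` so that the control-region
#' mean maps to 100 and its standard deviation to 10 on the working scale.
#' The map is strictly increasing (`a > 0`), so pixel rankings -- and any
#' ratio statistic computed after re-normalization, such as the relative
#' signal contrast -- are invariant to global affine intensity changes of
#' the input. This is a deliberately simple, single-subject surrogate for
#' regression-based scan-effect removal methods that require a multi-subject
#' voxel matrix in a common template space.
#'
#' @param image A [slice_image()].
#' @param control_mask Logical matrix marking the control region (non-empty).
#' @param target_mean,target_sd Working-scale targets (defaults 100 and 10).
#' @return Normalized `slice_image` (float scale, not re-quantized).
#' @export
normalize_control_region <- function(image, control_mask,
                                     target_mean = 100, target_sd = 10) {
  X <- px(image)
  if (!is.logical(control_mask) || !any(control_mask))
    stop("normalize_control_region: control mask must be a non-empty logical mask")
  if (!all(dim(control_mask) == dim(X)))
    stop("normalize_control_region: mask dimensions differ from the image")
  v <- X[control_mask]
  mu <- mean(v)
  ## population SD to match the contract "control STD -> 10" exactly
  sdv <- sqrt(mean((v - mu)^2))
  if (sdv == 0) {
    warning("normalize_control_region: zero-variance control region; mean-only shift")
    a <- 1
  } else {
    a <- target_sd / sdv
  }
  b <- target_mean - a * mu
  reslice(image, a * X + b)
}
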