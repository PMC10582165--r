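#' A single 2-D grayscale MRI slice
#'
#' Light container for one slice: a numeric pixel matrix plus the metadata
#' the downstream metrics need (quantization depth, pixel spacing, modality
#' tag). Pixels are stored as doubles; [quantize_slice()] rounds and clips
#' onto the `[0, bit_depth - 1]` integer grid.
#'
#' @param pixels Numeric matrix (rows x cols) of non-negative intensities.
#' @param bit_depth Number of gray levels L (default 256, i.e. 8-bit).
#' @param spacing Pixel spacing in mm, length-2 (row, col).
#' @param modality One of `"ADC"`, `"SWI"`, `"FUSED"`.
#' @return An object of class `slice_image`.
#' @examples
#' img <- slice_image(matrix(0:255, 16, 16), modality = "ADC")
#' dim(img)
#' @export
slice_image <- function(pixels, bit_depth = 256L, spacing = c(1, 1),
                        modality = c("ADC", "SWI", "FUSED")) {
  modality <- match.arg(modality)
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("slice_image: empty pixel grid")
  if (any(!is.finite(pixels)))
    stop("slice_image: non-finite intensities")
  if (bit_depth < 2L)
    stop("slice_image: bit_depth must be at least 2 levels")
  structure(pixels,
            bit_depth = as.integer(bit_depth),
            spacing = as.numeric(spacing),
            modality = modality,
            class = c("slice_image", "matrix", "array"))
}

#' @export
print.slice_image <- function(x, ...) {
  cat(sprintf("<slice_image> %s %dx%d, %d levels, spacing %s mm\n",
              attr(x, "modality"), nrow(x), ncol(x), attr(x, "bit_depth"),
              paste(signif(attr(x, "spacing"), 3), collapse = "x")))
  cat(sprintf("  intensity range [%.3f, %.3f]\n", min(x), max(x)))
  invisible(x)
}

#' @export
as.matrix.slice_image <- function(x, ...) {
  attributes(x) <- list(dim = dim(x))
  x
}

#' Round and clip a slice onto its integer gray-level grid
#'
#' @param image A `slice_image` (or plain matrix, with `bit_depth` given).
#' @param bit_depth Gray levels; defaults to the slice's own.
#' @return A `slice_image` with integer-valued pixels in `[0, L - 1]`.
#' @export
quantize_slice <- function(image, bit_depth = NULL) {
  L <- bit_depth %||% attr(image, "bit_depth") %||% 256L
  px <- pmin(pmax(round(as.matrix(image)), 0), L - 1)
  slice_image(px, bit_depth = L,
              spacing = attr(image, "spacing") %||% c(1, 1),
              modality = attr(image, "modality") %||% "FUSED")
}

## keep a slice's metadata while replacing its pixels
reslice <- function(template, pixels, modality = NULL) {
  slice_image(pixels,
              bit_depth = attr(template, "bit_depth") %||% 256L,
              spacing = attr(template, "spacing") %||% c(1, 1),
              modality = modality %||% attr(template, "modality") %||% "FUSED")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## pixel matrix as plain double matrix
px <- function(image) {
  m <- as.matrix(image)
  storage.mode(m) <- "double"
  m
}

## evaluate code under a temporary RNG state; restores .Random.seed after
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## deterministic per-subject seed derived from a cohort seed; stays < 2^31
derive_seed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647)
  for (k in c(index, 2654435761)) {
    s <- (s * 48271 + as.double(k) * 10007 + 12345) %% 2147483647
  }
  as.integer(s) + 1L
}
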