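## Landmark-based non-rigid registration: a cubic B-spline free-form
## deformation fitted to corresponding point pairs by linear least squares,
## plus the cubic image interpolation used for resampling.
##
## Coordinate convention (package-wide): 0-based (row, col), pixel centres at
## integer coordinates, transforms map fixed -> moving (pull-back sampling).

## Keys cubic-convolution kernel, a = -0.5 (interpolating: exact at integers)
keys_cubic <- function(t) {
  t <- abs(t)
  w <- numeric(length(t))
  i1 <- t <= 1
  i2 <- t > 1 & t < 2
  w[i1] <- ((1.5 * t[i1] - 2.5) * t[i1]) * t[i1] + 1
  w[i2] <- ((-0.5 * t[i2] + 2.5) * t[i2] - 4) * t[i2] + 2
  w
}

## vectorized bicubic sampling of X at 0-based float coords (rr, cc);
## points outside [0, n-1] x [0, m-1] return `fill`
interp_bicubic <- function(X, rr, cc, fill = 0) {
  n <- nrow(X); m <- ncol(X)
  inside <- rr >= 0 & rr <= n - 1 & cc >= 0 & cc <= m - 1
  out <- rep(fill, length(rr))
  if (!any(inside)) return(out)
  r <- rr[inside]; c <- cc[inside]
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  acc <- numeric(length(r))
  for (k in -1:2) {
    ri <- pmin(pmax(r0 + k, 0), n - 1) + 1
    wr <- keys_cubic(fr - k)
    for (l in -1:2) {
      ci <- pmin(pmax(c0 + l, 0), m - 1) + 1
      wc <- keys_cubic(fc - l)
      acc <- acc + wr * wc * X[cbind(ri, ci)]
    }
  }
  out[inside] <- acc
  out
}

## rigid pull-back warp used by the phantom's misalignment jitter:
## output(x) = X(R_theta (x - center) + center + shift)
warp_rigid <- function(X, theta, shift, center) {
  n <- nrow(X); m <- ncol(X)
  rr <- rep(seq_len(n) - 1, times = m) - center[1]
  cc <- rep(seq_len(m) - 1, each = n) - center[2]
  sr <- cos(theta) * rr - sin(theta) * cc + center[1] + shift[1]
  sc <- sin(theta) * rr + cos(theta) * cc + center[2] + shift[2]
  matrix(interp_bicubic(X, sr, sc), n, m)
}

## landmark pairs implied by a known rigid jitter: the anatomy at fixed
## location p sits at T^{-1}(p) in the jittered image
rigid_landmarks <- function(s, theta, shift, center, n_points = 12L) {
  ang <- seq(0, 2 * pi, length.out = n_points + 1L)[-(n_points + 1L)]
  ctr <- (s - 1) / 2
  p <- rbind(cbind(ctr + 0.38 * s * cos(ang), ctr + 0.38 * s * sin(ang)),
             c(ctr, ctr))
  q <- sweep(p, 2, center[1:2] + shift)
  inv <- cbind(cos(theta) * q[, 1] + sin(theta) * q[, 2],
               -sin(theta) * q[, 1] + cos(theta) * q[, 2])
  inv <- sweep(inv, 2, center[1:2], `+`)
  landmark_set(fixed = p, moving = inv,
               label = c(sprintf("rim%02d", seq_len(n_points)), "center"))
}

#' Corresponding anatomical landmark pairs
#'
#' @param fixed,moving Two-column matrices of 0-based (row, col) pixel
#'   coordinates; row i of `moving` is the position in the moving image of
#'   the anatomy at row i of `fixed`.
#' @param label Optional character labels per pair.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(fixed, moving, label = NULL) {
  fixed <- matrix(as.numeric(fixed), ncol = 2)
  moving <- matrix(as.numeric(moving), ncol = 2)
  if (nrow(fixed) != nrow(moving))
    stop("landmark_set: fixed and moving pair counts differ")
  if (anyDuplicated(fixed))
    stop("landmark_set: duplicate fixed points")
  if (is.null(label)) label <- sprintf("L%02d", seq_len(nrow(fixed)))
  structure(list(fixed = fixed, moving = moving, label = as.character(label)),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> %d corresponding pairs\n", nrow(x$fixed)))
  invisible(x)
}

#' Write / read landmark pairs as JSON
#'
#' Serialized as a list of `{label, fixed: [r, c], moving: [r, c]}` records.
#'
#' @param landmarks A [landmark_set()].
#' @param path File path.
#' @return The reader returns a `landmark_set`; the writer returns `path`
#'   invisibly.
#' @export
write_landmarks_json <- function(landmarks, path) {
  recs <- lapply(seq_len(nrow(landmarks$fixed)), function(i)
    list(label = landmarks$label[i],
         fixed = landmarks$fixed[i, ],
         moving = landmarks$moving[i, ]))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_landmarks_json
#' @export
read_landmarks_json <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  landmark_set(fixed = do.call(rbind, lapply(recs, function(r) unlist(r$fixed))),
               moving = do.call(rbind, lapply(recs, function(r) unlist(r$moving))),
               label = vapply(recs, function(r) r$label, ""))
}

## cubic B-spline kernel (support [-2, 2], partition of unity on integers)
bspline3 <- function(t) {
  t <- abs(t)
  w <- numeric(length(t))
  i1 <- t < 1
  i2 <- t >= 1 & t < 2
  w[i1] <- (4 - 6 * t[i1]^2 + 3 * t[i1]^3) / 6
  w[i2] <- (2 - t[i2])^3 / 6
  w
}

## 1-D basis matrix: rows = sample positions x, cols = control indices
bspline_basis_1d <- function(x, ctrl_idx, spacing) {
  B <- outer(x / spacing, ctrl_idx, function(u, i) bspline3(u - i))
  B
}

ctrl_index_range <- function(extent, spacing) {
  (-1L):(ceiling(extent / spacing) + 2L)
}

#' Cubic B-spline free-form deformation
#'
#' A displacement field parameterized by control-point displacements on a
#' regular grid of the given spacing, interpolated with the cubic B-spline
#' kernel. With all displacements zero the transform is the identity.
#' Transforms map fixed-image coordinates to moving-image coordinates.
#'
#' @param grid_spacing Control-point spacing in pixels.
#' @param domain Integer `c(rows, cols)` of the fixed image.
#' @param disp_r,disp_c Matrices of control-point displacements (rows x cols
#'   of the control grid); default all zero (identity).
#' @return An object of class `bspline_transform`.
#' @export
bspline_transform <- function(grid_spacing, domain, disp_r = NULL, disp_c = NULL,
                              affine = NULL) {
  ir <- ctrl_index_range(domain[1] - 1, grid_spacing)
  ic <- ctrl_index_range(domain[2] - 1, grid_spacing)
  z <- matrix(0, length(ir), length(ic))
  disp_r <- disp_r %||% z
  disp_c <- disp_c %||% z
  ## optional global affine component: x_moving = [x_fixed, 1] %*% affine
  ## (3 x 2), composed with the B-spline residual field; identity default
  affine <- affine %||% rbind(diag(2), c(0, 0))
  stopifnot(all(dim(disp_r) == dim(z)), all(dim(disp_c) == dim(z)),
            all(dim(affine) == c(3L, 2L)))
  structure(list(grid_spacing = grid_spacing, domain = as.integer(domain),
                 ctrl_rows = ir, ctrl_cols = ic,
                 disp_r = disp_r, disp_c = disp_c, affine = affine,
                 residual_rms = NA_real_),
            class = "bspline_transform")
}

#' @export
print.bspline_transform <- function(x, ...) {
  cat(sprintf("<bspline_transform> %d px grid, %dx%d control points, residual RMS %s px\n",
              x$grid_spacing, length(x$ctrl_rows), length(x$ctrl_cols),
              ifelse(is.na(x$residual_rms), "NA", sprintf("%.4f", x$residual_rms))))
  invisible(x)
}

#' Evaluate a B-spline displacement field at points
#'
#' @param transform A [bspline_transform()].
#' @param points Two-column matrix of 0-based (row, col) coordinates.
#' @return Two-column matrix of (row, col) displacements.
#' @export
displacement_at <- function(transform, points) {
  points <- matrix(as.numeric(points), ncol = 2)
  Br <- bspline_basis_1d(points[, 1], transform$ctrl_rows, transform$grid_spacing)
  Bc <- bspline_basis_1d(points[, 2], transform$ctrl_cols, transform$grid_spacing)
  ## tensor-product B-spline residual on top of the affine component
  dr <- rowSums((Br %*% transform$disp_r) * Bc)
  dc <- rowSums((Br %*% transform$disp_c) * Bc)
  aff <- cbind(points, 1) %*% transform$affine - points
  aff + cbind(dr, dc)
}

## dense tensor design matrix for a set of points (landmark fitting only)
bspline_design <- function(points, transform) {
  Br <- bspline_basis_1d(points[, 1], transform$ctrl_rows, transform$grid_spacing)
  Bc <- bspline_basis_1d(points[, 2], transform$ctrl_cols, transform$grid_spacing)
  ## row i = outer(Br[i,], Bc[i,]) flattened column-major (matches disp matrices)
  A <- matrix(0, nrow(points), length(transform$ctrl_rows) * length(transform$ctrl_cols))
  for (i in seq_len(nrow(points)))
    A[i, ] <- as.vector(outer(Br[i, ], Bc[i, ]))
  A
}

#' Fit a B-spline transform to landmark pairs
#'
#' Two-stage closed-form least squares, the convention of landmark
#' registration toolkits: a global affine map is fitted to the pairs first,
#' then the control-point displacements of the B-spline field are fitted to
#' the remaining residuals (with a tiny ridge term for the control points
#' far from any landmark, which the data leave under-determined). Both
#' stages minimize sums of squared landmark residuals in closed form; the
#' final residual RMS in pixels is stored on the returned transform.
#'
#' @param landmarks A [landmark_set()] with at least 4 non-collinear pairs.
#' @param domain Fixed-image extent `c(rows, cols)`.
#' @param grid_spacing Control grid spacing in pixels (default 32).
#' @param ridge Ridge regularization weight (default `1e-8`).
#' @return A [bspline_transform()] mapping fixed to moving coordinates.
#' @export
fit_landmark_bspline <- function(landmarks, domain, grid_spacing = 32, ridge = 1e-8) {
  P <- nrow(landmarks$fixed)
  if (P < 4) stop("fit_landmark_bspline: need at least 4 landmark pairs")
  ## collinearity diagnostic: rank of the affine design must be 3
  M <- cbind(1, landmarks$fixed)
  if (qr(M)$rank < 3)
    stop("fit_landmark_bspline: degenerate (collinear) landmark configuration")
  ## stage 1: global affine
  Xd <- cbind(landmarks$fixed, 1)
  affine <- solve(crossprod(Xd), crossprod(Xd, landmarks$moving))
  tr <- bspline_transform(grid_spacing, domain, affine = affine)
  ## stage 2: B-spline field on the affine residuals
  A <- bspline_design(landmarks$fixed, tr)
  R <- landmarks$moving - Xd %*% affine
  AtA <- crossprod(A) + diag(ridge, ncol(A))
  D <- solve(AtA, crossprod(A, R))
  nr <- length(tr$ctrl_rows)
  tr$disp_r <- matrix(D[, 1], nr)
  tr$disp_c <- matrix(D[, 2], nr)
  fit <- A %*% D
  tr$residual_rms <- sqrt(mean(rowSums((fit - R)^2)))
  tr
}

#' Resample a slice through a B-spline transform
#'
#' Pull-back resampling: the output value at fixed-image pixel `x` is the
#' moving image interpolated at `x + d(x)` with the cubic (Keys) kernel.
#' Samples falling outside the moving image are set to 0 (background of a
#' brain-extracted slice). Output dimensions equal the transform's fixed
#' domain.
#'
#' @param image Moving [slice_image()].
#' @param transform A [bspline_transform()].
#' @return Resampled `slice_image`.
#' @export
resample_slice <- function(image, transform) {
  n <- transform$domain[1]; m <- transform$domain[2]
  X <- px(image)
  Br <- bspline_basis_1d(seq_len(n) - 1, transform$ctrl_rows, transform$grid_spacing)
  Bc <- bspline_basis_1d(seq_len(m) - 1, transform$ctrl_cols, transform$grid_spacing)
  dr <- Br %*% transform$disp_r %*% t(Bc)
  dc <- Br %*% transform$disp_c %*% t(Bc)
  r0 <- matrix(seq_len(n) - 1, n, m)
  c0 <- matrix(rep(seq_len(m) - 1, each = n), n, m)
  af <- transform$affine
  rr <- af[1, 1] * r0 + af[2, 1] * c0 + af[3, 1] + dr
  cc <- af[1, 2] * r0 + af[2, 2] * c0 + af[3, 2] + dc
  out <- matrix(interp_bicubic(X, as.vector(rr), as.vector(cc)), n, m)
  reslice(image, out)
}

#' Register a jittered modality onto its reference
#'
#' Convenience wrapper for the phantom workflow: fits the B-spline transform
#' from a subject's landmark pairs and resamples the moving slice onto the
#' fixed grid.
#'
#' @param moving Moving [slice_image()] (e.g. the jittered SWI).
#' @param landmarks [landmark_set()] tying the fixed frame to the moving one.
#' @param grid_spacing Control grid spacing in pixels.
#' @return List with `image` (resampled slice) and `transform`.
#' @export
register_landmarks <- function(moving, landmarks, grid_spacing = 32) {
  tr <- fit_landmark_bspline(landmarks, domain = dim(moving),
                             grid_spacing = grid_spacing)
  list(image = resample_slice(moving, tr), transform = tr)
}
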