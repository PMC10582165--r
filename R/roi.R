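#' Circular regions of interest over a slice
#'
#' The grading statistics follow the radiologist convention of three small
#' circular ROIs per region (tumour and normal-appearing white matter), whose
#' per-ROI means are averaged in a second stage. Coordinates are 0-based
#' (row, col) pixel centres; a pixel belongs to a circle when its centre lies
#' within `radius` of the ROI centre.
#'
#' @param tumor Data frame with columns `row`, `col`, `radius` (>= 3 rows
#'   recommended; at least 1 required).
#' @param wm Same shape, for white-matter reference ROIs.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(tumor, wm) {
  chk <- function(d, what) {
    d <- as.data.frame(d)
    if (!all(c("row", "col", "radius") %in% names(d)))
      stop("roi_set: ", what, " needs columns row, col, radius")
    if (nrow(d) < 1L) stop("roi_set: ", what, " is empty")
    if (any(d$radius <= 0)) stop("roi_set: non-positive ROI radius")
    d[, c("row", "col", "radius")]
  }
  structure(list(tumor = chk(tumor, "tumor"), wm = chk(wm, "wm")),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d tumor + %d white-matter circular ROIs\n",
              nrow(x$tumor), nrow(x$wm)))
  invisible(x)
}

## logical mask of one circle on an n x m grid (0-based centre coords)
circle_mask <- function(n, m, row, col, radius) {
  dr <- (seq_len(n) - 1) - row
  dc <- (seq_len(m) - 1) - col
  outer(dr^2, dc^2, `+`) <= radius^2
}

## indices of the pixels of one circle; errors if it leaves the image.
## restricted to the circle's bounding box for speed.
circle_pixels <- function(image, row, col, radius) {
  n <- nrow(image); m <- ncol(image)
  if (row - radius < 0 || col - radius < 0 ||
      row + radius > n - 1 || col + radius > m - 1)
    stop("ROI extends outside the image bounds")
  ri <- (floor(row - radius):ceiling(row + radius)) + 1
  ci <- (floor(col - radius):ceiling(col + radius)) + 1
  dr2 <- ((ri - 1) - row)^2
  dc2 <- ((ci - 1) - col)^2
  inb <- outer(dr2, dc2, `+`) <= radius^2
  idx <- which(inb)
  rr <- ri[(idx - 1) %% length(ri) + 1]
  cc <- ci[(idx - 1) %/% length(ri) + 1]
  (cc - 1) * n + rr
}

rois_disjoint <- function(rois) {
  ## conservative circle-circle check between the two roles
  d2 <- outer(rois$tumor$row, rois$wm$row, `-`)^2 +
    outer(rois$tumor$col, rois$wm$col, `-`)^2
  rsum <- outer(rois$tumor$radius, rois$wm$radius, `+`)
  all(d2 >= rsum^2)
}

#' Write / read an ROI set as JSON
#'
#' Serialized as a list of `{role, center: [row, col], radius_px}` records
#' with 0-based row-major pixel coordinates.
#'
#' @param rois A [roi_set()].
#' @param path Output (input) file path.
#' @return `read_rois_json` returns a `roi_set`; the writer returns `path`
#'   invisibly.
#' @export
write_rois_json <- function(rois, path) {
  recs <- lapply(c("tumor", "wm"), function(role) {
    d <- rois[[role]]
    lapply(seq_len(nrow(d)), function(i)
      list(role = role, center = c(d$row[i], d$col[i]), radius_px = d$radius[i]))
  })
  jsonlite::write_json(do.call(c, recs), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rois_json
#' @export
read_rois_json <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  grab <- function(role) {
    sel <- Filter(function(r) identical(r$role, role), recs)
    do.call(rbind, lapply(sel, function(r)
      data.frame(row = r$center[[1]], col = r$center[[2]], radius = r$radius_px)))
  }
  roi_set(grab("tumor"), grab("wm"))
}
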