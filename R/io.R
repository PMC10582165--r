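## File I/O glue: slices as single-slice NIfTI volumes or PNG, tabular
## outputs as plain UTF-8 CSV with "." decimal separator.

#' Write / read a slice as a one-slice NIfTI volume
#'
#' @param image A [slice_image()].
#' @param path File path (`.nii` or `.nii.gz`).
#' @param modality Modality tag to attach on read.
#' @return The reader returns a `slice_image`; the writer returns `path`
#'   invisibly.
#' @export
write_slice_nifti <- function(image, path) {
  sp <- attr(image, "spacing") %||% c(1, 1)
  vol <- array(px(image), dim = c(nrow(image), ncol(image), 1L))
  img <- RNifti::asNifti(vol, pixdim = c(sp, 1))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_slice_nifti
#' @param bit_depth Gray levels to attach on read (default 256).
#' @export
read_slice_nifti <- function(path, modality = "FUSED", bit_depth = 256L) {
  vol <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(vol)
  m <- if (length(dim(vol)) == 3L) vol[, , 1] else vol[, ]
  slice_image(m, bit_depth = bit_depth,
              spacing = pd[1:2], modality = modality)
}

## CRC32 (PNG chunk checksums), table-driven
.crc_env <- new.env(parent = emptyenv())

crc32_table <- function() {
  if (!is.null(.crc_env$tab)) return(.crc_env$tab)
  tab <- integer(256)
  for (n in 0:255) {
    c <- n
    for (k in 1:8) {
      ## bitwShiftR performs a logical (unsigned) shift in R
      c <- if (bitwAnd(c, 1L) != 0L)
        bitwXor(-306674912L, bitwShiftR(c, 1))  # 0xEDB88320
      else bitwShiftR(c, 1)
    }
    tab[n + 1] <- c
  }
  .crc_env$tab <- tab
  tab
}

crc32 <- function(bytes) {
  tab <- crc32_table()
  c <- -1L  # 0xFFFFFFFF
  b <- as.integer(bytes)
  for (i in seq_along(b)) {
    idx <- bitwAnd(bitwXor(c, b[i]), 255L)
    c <- bitwXor(tab[idx + 1], bitwShiftR(c, 8))
  }
  bitwXor(c, -1L)
}

u32be <- function(x) {
  x <- as.numeric(x) %% 4294967296
  as.raw(c(x %/% 16777216, (x %/% 65536) %% 256, (x %/% 256) %% 256, x %% 256))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(u32be(length(data)), body, u32be(crc32(body)))
}

## memCompress(type = "gzip") emits an RFC 1950 zlib stream (0x78 header +
## adler32 trailer), which is exactly what a PNG IDAT chunk carries
zlib_compress <- function(bytes) {
  memCompress(bytes, type = "gzip")
}

#' Write a slice as a 16-bit grayscale PNG
#'
#' Intensities are mapped from `[0, bit_depth - 1]` onto the 16-bit range.
#' The file is written directly (IHDR/IDAT/IEND with deflate via
#' [memCompress()]), since the available PNG bindings only write 8-bit
#' grayscale.
#'
#' @param image A [slice_image()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_slice_png <- function(image, path) {
  L <- attr(image, "bit_depth") %||% 256L
  v <- round(pmin(pmax(px(image) / (L - 1), 0), 1) * 65535)
  n <- nrow(v); m <- ncol(v)
  ## scanlines: filter byte 0 + big-endian 16-bit samples, row-major
  scan <- matrix(as.raw(0), 2 * m + 1, n)
  vt <- t(v)
  scan[seq(2, 2 * m, 2), ] <- as.raw(vt %/% 256)
  scan[seq(3, 2 * m + 1, 2), ] <- as.raw(vt %% 256)
  ihdr <- c(u32be(m), u32be(n), as.raw(c(16, 0, 0, 0, 0)))
  out <- c(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", zlib_compress(as.vector(scan))),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}

## deterministic CSV writer (UTF-8, header, "." decimal)
write_csv_plain <- function(d, path) {
  utils::write.csv(d, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
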