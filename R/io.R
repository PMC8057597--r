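# Image and kernel file I/O. Images are held internally as floating-point
# matrices; PNG/TIFF round-trips record the intensity scaling used.

#' Read a grayscale image
#'
#' Reads 8/16-bit grayscale PNG or TIFF (colour channels are averaged), or a
#' whitespace-separated plain-text matrix for `.txt`/`.dat` files. PNG/TIFF
#' values arrive in `[0, 1]`.
#'
#' @param path file path; format chosen by extension.
#' @return Numeric matrix.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = , tiff = tiff::readTIFF(path),
                txt = , dat = as.matrix(utils::read.table(path)),
                stop(sprintf("unsupported image format '.%s'", ext),
                     call. = FALSE))
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  img <- unname(as.matrix(img))
  storage.mode(img) <- "double"
  img
}

#' Write a grayscale image
#'
#' Rescales by `1/max(img)` (when the maximum exceeds 1) so values fit the
#' file's `[0, 1]` range, clamps small negatives at zero, and writes the
#' file. The scale factor applied is returned invisibly and reported via
#' `message()` so it can be logged.
#'
#' @param img numeric matrix.
#' @param path output path (`.png`, `.tif`/`.tiff`).
#' @param bit_depth 8 or 16; honoured for TIFF, while PNG output is always
#'   8-bit (16-bit PNGs can still be read).
#' @return Invisibly, the divisor applied before writing.
#' @export
write_image <- function(img, path, bit_depth = 16L) {
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16", call. = FALSE)
  scale <- max(max(img), 1)
  out <- pmin(pmax(img / scale, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(out, path, dpi = NULL),
         tif = , tiff = tiff::writeTIFF(out, path,
                                        bits.per.sample = bit_depth),
         stop(sprintf("unsupported image format '.%s'", ext), call. = FALSE))
  message(sprintf("wrote %s (intensities divided by %g for %d-bit storage)",
                  path, scale, bit_depth))
  invisible(scale)
}

#' Read a blur kernel from a plain-text matrix file
#'
#' Whitespace-separated rows of nonnegative weights; normalised on load,
#' with a warning if the raw sum deviates from 1 by more than 1e-6.
#'
#' @param path text file path.
#' @return A [blur_kernel()].
#' @export
read_kernel <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  w <- as.matrix(utils::read.table(path))
  blur_kernel(unname(w))
}
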