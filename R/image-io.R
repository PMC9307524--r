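#' Read a grayscale image as a numeric matrix
#'
#' Thin wrapper over the \pkg{tiff} and \pkg{png} readers that returns images
#' in the row/column convention used throughout this package: rows are the
#' axial (z) direction with row 1 at the probe side, columns are lateral (x).
#' Multi-channel images are averaged to one gray channel. Pixel values are
#' rescaled from the readers' [0, 1] convention to `bit_depth` gray levels.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @param bit_depth Gray-level range of the returned matrix; the default 8
#'   yields values in [0, 255].
#' @return A numeric matrix of gray levels.
#' @seealso [write_gray_image()]
#' @export
read_gray_image <- function(path, bit_depth = 8) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    "tif" = ,
    "tiff" = tiff::readTIFF(path),
    "png" = png::readPNG(path),
    rlang::abort(sprintf("Unsupported image extension '%s' (use TIFF or PNG).", ext))
  )
  if (length(dim(img)) == 3L) img <- apply(img, c(1L, 2L), mean)
  img * (2^bit_depth - 1)
}

#' Write a grayscale matrix to TIFF or PNG
#'
#' @param img Numeric matrix of gray levels in `[0, 2^bit_depth - 1]`.
#' @param path Output path; format chosen from the extension.
#' @param bit_depth Gray-level range of `img` (default 8).
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(img, path, bit_depth = 8) {
  check_image(img)
  x <- pmin(pmax(img / (2^bit_depth - 1), 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    "tif" = ,
    "tiff" = tiff::writeTIFF(x, path, bits.per.sample = 16L),
    "png" = png::writePNG(x, path),
    rlang::abort(sprintf("Unsupported image extension '%s' (use TIFF or PNG).", ext))
  )
  invisible(path)
}
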