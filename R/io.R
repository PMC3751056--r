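#' Read a grayscale image
#'
#' Reads an 8- or 16-bit PNG or TIFF frame as a numeric matrix in
#' `[0, 1]`; RGB(A) input is converted by the Rec. 601 luminance
#' `0.299 R + 0.587 G + 0.114 B`.
#'
#' @param path Image file (`.png`, `.tif`, `.tiff`).
#' @return Numeric matrix.
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
              png = png::readPNG(path),
              tif = ,
              tiff = tiff::readTIFF(path),
              stop("unsupported image format: ", ext))
  if (length(dim(a)) == 3) {
    if (dim(a)[3] >= 3)
      a <- 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
    else a <- a[, , 1]
  }
  a
}

#' Read a binary mask image
#'
#' Reads a PNG/TIFF mask; pixels above 0.5 (on the unit scale) are
#' foreground.
#'
#' @param path Image file.
#' @return Logical matrix.
#' @export
read_mask <- function(path) read_gray_image(path) > 0.5

#' Write a binary mask as a 0/255 PNG
#'
#' @param mask Logical matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(.as_mask(mask) * 1, path)
  invisible(path)
}

#' Write a contour as a two-column CSV
#'
#' @param contour Data frame from [extract_contour()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contour_csv <- function(contour, path) {
  utils::write.csv(contour[, c("x", "y")], path, row.names = FALSE)
  invisible(path)
}
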