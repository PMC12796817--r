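#' Read a microscopy image from TIFF or PNG
#'
#' Returns intensities as a numeric matrix (grayscale) or H x W x 3 array
#' (RGB), rescaled to the 0..255 convention used throughout the package
#' regardless of the file's bit depth.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @return Numeric matrix or 3-d array of intensities in 0..255.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    tif = ,
    tiff = tiff::readTIFF(path) * 255,
    png = png::readPNG(path) * 255,
    stop("unsupported image format: .", ext)
  )
  x <- drop_alpha(x)
  storage_numeric(x)
}

drop_alpha <- function(x) {
  d <- dim(x)
  if (length(d) == 3L && d[3] == 4L) x <- x[, , 1:3, drop = FALSE]
  if (length(d) == 3L && dim(x)[3] == 1L) x <- x[, , 1]
  x
}

storage_numeric <- function(x) {
  storage.mode(x) <- "double"
  x
}

#' Write a grayscale or RGB image to TIFF or PNG
#'
#' @param image Numeric matrix or H x W x 3 array.
#' @param path Output path; format chosen by extension.
#' @param max_value Intensity corresponding to full scale (default 255).
#' @return The path, invisibly.
#' @export
write_image <- function(image, path, max_value = 255) {
  check_image(image)
  scaled <- pmin(pmax(image / max_value, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = ,
    tiff = tiff::writeTIFF(scaled, path, bits.per.sample = 16L),
    png = png::writePNG(scaled, path),
    stop("unsupported image format: .", ext)
  )
  invisible(path)
}

#' Read an instance or semantic label mask from TIFF or PNG
#'
#' Labels are returned as an integer-valued matrix with 0 = background.
#' TIFF masks are read with `as.is = TRUE` so stored integer labels come
#' back unscaled; PNG masks are rescaled from 0..1 to 16-bit integers.
#'
#' @param path Path to the mask file.
#' @return Integer label matrix.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    tif = ,
    tiff = tiff::readTIFF(path, as.is = TRUE),
    png = round(png::readPNG(path) * 65535),
    stop("unsupported mask format: .", ext)
  )
  if (length(dim(x)) == 3L) x <- x[, , 1]
  x <- round(x)
  storage.mode(x) <- "double"
  check_mask(x)
  x
}

#' Write an instance label mask as a 16-bit integer TIFF
#'
#' Labels up to 65535 are stored losslessly; larger labels are refused.
#'
#' @param mask Integer label matrix, 0 = background.
#' @param path Output `.tif` path.
#' @return The path, invisibly.
#' @export
write_mask <- function(mask, path) {
  check_mask(mask)
  if (max(mask) > 65535) {
    stop("mask labels exceed 65535; 16-bit TIFF cannot store them losslessly")
  }
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  invisible(path)
}
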