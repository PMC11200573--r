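# Internal image convention: numeric array dim c(H, W, 3), values in [0, 1],
# channel order RGB.  8-bit (or 16-bit TIFF) only at the file boundary.

#' Validate and normalise an in-memory image
#'
#' Coerces a matrix (grayscale) or H x W x C array to the package's internal
#' convention: an H x W x 3 numeric array with values in \[0, 1\].
#' Grayscale input is promoted to three identical channels; an alpha channel
#' is dropped.
#'
#' @param img numeric matrix or 3-d array.
#' @param clip if `TRUE` (default) values are clipped into \[0, 1\];
#'   otherwise out-of-range values raise an error.
#' @return an H x W x 3 numeric array in \[0, 1\].
#' @export
as_image <- function(img, clip = TRUE) {
  if (is.matrix(img)) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (!is.array(img) || length(dim(img)) != 3L)
    stop("image must be a matrix or an H x W x C array", call. = FALSE)
  if (dim(img)[3L] == 1L) {
    img <- array(rep(img, 3L), dim = c(dim(img)[1:2], 3L))
  } else if (dim(img)[3L] == 4L) {
    img <- img[, , 1:3, drop = FALSE]
  } else if (dim(img)[3L] != 3L) {
    stop("image must have 1, 3 or 4 channels, got ", dim(img)[3L],
         call. = FALSE)
  }
  storage.mode(img) <- "double"
  if (anyNA(img)) stop("image contains NA values", call. = FALSE)
  if (clip) {
    img[img < 0] <- 0
    img[img > 1] <- 1
  } else if (min(img) < 0 || max(img) > 1) {
    stop("image values outside [0, 1]", call. = FALSE)
  }
  img
}

#' Read an image file as an H x W x 3 array in \[0, 1\]
#'
#' Supported formats: PNG, JPEG, TIFF (by file extension).  Grayscale files
#' are promoted to three identical channels; 16-bit TIFF is scaled by its bit
#' depth so that full scale maps to 1.
#'
#' @param path file path.
#' @return H x W x 3 numeric array in \[0, 1\].
#' @export
load_image <- function(path) {
  if (!file.exists(path))
    stop("cannot read image file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png  = png::readPNG(path),
    jpg  = ,
    jpeg = jpeg::readJPEG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '", ext, "' for ", path, call. = FALSE))
  as_image(img)
}

#' Write an image to disk
#'
#' PNG and TIFF are written as 8-bit; JPEG quality may be set.  Values are
#' clipped into \[0, 1\] before quantisation.
#'
#' @param img image array (see [as_image()]).
#' @param path output path; format chosen by extension (png/jpg/jpeg/tif/tiff).
#' @param quality JPEG quality in (0, 1], ignored for other formats.
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path, quality = 0.95) {
  img <- as_image(img)
  ext <- tolower(tools::file_ext(path))
  ok <- switch(ext,
    png  = png::writePNG(img, path),
    jpg  = ,
    jpeg = jpeg::writeJPEG(img, path, quality = quality),
    tif  = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = 8L),
    stop("unsupported image format '", ext, "' for ", path, call. = FALSE))
  invisible(path)
}

#' Write a binary mask as an 8-bit single-channel PNG (0/255)
#' @param mask logical or 0/1 matrix.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
save_mask <- function(mask, path) {
  m <- (as.matrix(mask) != 0) * 1
  png::writePNG(m, path)
  invisible(path)
}

#' Read a binary mask PNG written by [save_mask()]
#' @param path PNG path.
#' @return logical matrix.
#' @export
load_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  m > 0.5
}

# luminance (Rec. 601) of an H x W x 3 array
luminance <- function(img) {
  0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Peak signal-to-noise ratio between two images
#'
#' Reference-based fidelity in decibels over a \[0, 1\] signal range.  Used
#' internally for phantom-oracle experiments; it is not part of the headline
#' unpaired evaluation battery, which is reference-free by design.
#'
#' @param img,ref images of identical dimensions.
#' @return PSNR in dB (`Inf` for identical images).
#' @export
psnr <- function(img, ref) {
  img <- as_image(img); ref <- as_image(ref)
  if (!identical(dim(img), dim(ref)))
    stop("psnr: image dimensions differ", call. = FALSE)
  mse <- mean((img - ref)^2)
  if (mse == 0) return(Inf)
  -10 * log10(mse)
}

# Deterministic seed fan-out: derive a child seed from a parent seed and a
# label.  Simple 32-bit mixing keeps results identical across platforms.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) *
             seq_along(utf8ToInt(as.character(label))))
  ((as.double(seed) * 48271 + h * 16807) %% 2147483563) + 1
}
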