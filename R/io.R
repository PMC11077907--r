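#' Read a PNG or TIFF image as an HxWx3 array in [0, 1]
#'
#' Values are scaled by 2^bits - 1 by the underlying readers. An alpha channel
#' is dropped; single-channel (grayscale) images are replicated to 3 channels
#' with a warning. Images are assumed sRGB-encoded.
#'
#' @param path file path ending in .png, .tif or .tiff (case-insensitive).
#' @return HxWx3 array with attributes `source_id` (file name) and
#'   `bit_depth`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path, info = TRUE),
                tif = ,
                tiff = tiff::readTIFF(path, info = TRUE),
                stop("unsupported image format: ", ext))
  info <- attr(img, "info")                      # png attaches a list ...
  bits <- if (!is.null(info$bit.depth)) info$bit.depth
          else if (!is.null(attr(img, "bits.per.sample")))
            attr(img, "bits.per.sample")         # ... tiff attaches flat attrs
          else 8L
  d <- dim(img)
  attributes(img) <- NULL
  dim(img) <- d
  if (is.matrix(img)) {
    warning("grayscale image replicated to 3 channels: ", basename(path))
    img <- array(rep(img, 3), c(dim(img), 3))
  }
  if (dim(img)[3] == 2) {  # gray + alpha
    warning("grayscale image replicated to 3 channels: ", basename(path))
    img <- array(rep(img[, , 1], 3), c(dim(img)[1:2], 3))
  }
  if (dim(img)[3] == 4) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[1] < 3 || dim(img)[2] < 3) stop("image smaller than 3x3: ", path)
  structure(img, source_id = basename(path), bit_depth = as.integer(bits[1]))
}

#' Write an image array to PNG (8-bit) or TIFF (16-bit)
#'
#' @param img HxWx3 (or HxW for masks) array in [0, 1].
#' @param path output path; `.png` writes 8-bit PNG, `.tif`/`.tiff` writes
#'   16-bit TIFF.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  check_unit_range(img, "image")
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(img, target = path),
         tif = ,
         tiff = tiff::writeTIFF(img, path, bits.per.sample = 16L),
         stop("unsupported image format: ", ext))
  invisible(path)
}

#' Quantize an image to an integer bit depth
#'
#' Rounds to the nearest representable level at `bits` per channel, as a
#' file write/read round trip would. Used to make generated fixtures
#' bit-stable.
#'
#' @param img array in [0, 1].
#' @param bits bits per channel.
#' @return array of the same shape on the quantized grid.
#' @export
quantize_image <- function(img, bits = 16L) {
  levels <- 2^bits - 1
  out <- round(img * levels) / levels
  attributes(out) <- attributes(img)
  out
}

list_corpus_images <- function(dir) {
  files <- list.files(dir, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE,
                      full.names = TRUE)
  sort(files)
}
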