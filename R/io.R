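#' Read and write images and masks as PNG
#'
#' Images are 8-bit RGB PNGs; label masks are single-channel PNGs storing
#' the raw codes 0/1/2 (they look black in a viewer; see
#' [plot_mask()] for a display rendering).
#'
#' @param image rows x cols x 3 array, 0..255.
#' @param path Output file path.
#' @return `path`, invisibly (writers); an image array or integer matrix
#'   (readers).
#' @export
write_image_png <- function(image, path) {
  stopifnot(length(dim(image)) == 3)
  png::writePNG(clip255(image) / 255, path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_image_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 2) x <- array(rep(x, 3), dim = c(dim(x), 3))
  if (dim(x)[3] == 4) x <- x[, , 1:3, drop = FALSE]
  x * 255
}

#' @rdname write_image_png
#' @param mask Integer matrix of codes 0/1/2.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_mask_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  matrix(as.integer(round(x * 255)), nrow(x), ncol(x))
}

#' Serialize reference color statistics to JSON
#'
#' @param ref A reference-statistics list (see [he_reference_stats()]).
#' @param path JSON file path.
#' @return `path` (writer) / reference list (reader), invisibly.
#' @export
write_reference_json <- function(ref, path) {
  out <- list(mean = as.list(ref$mean), sd = as.list(ref$sd),
              version = ref$version)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_reference_json
#' @export
read_reference_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$mean <- unlist(x$mean); x$sd <- unlist(x$sd)
  x
}
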