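#' Read an 8-bit raster image
#'
#' Reads a PNG, TIFF or JPEG file into an [rgb_image()]. Single-channel
#' (grayscale) rasters are replicated to three channels; anything other than a
#' 1- or 3-channel 8-bit raster is rejected. JPEG is accepted on input only —
#' all masks and images the package writes are lossless PNG.
#'
#' @param path Path to a `.png`, `.tif`/`.tiff`, `.jpg`/`.jpeg` file.
#' @return An [rgb_image()] whose `id` is the filename stem.
#' @export
read_image <- function(path) {
  raw <- read_raster(path)
  px <- raw$values
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), c(dim(px), 3L))
  nch <- dim(px)[3]
  abort_if(!nch %in% c(1L, 3L),
           sprintf("'%s' has %d channels; expected 1 or 3", path, nch))
  if (nch == 1L) px <- array(rep(px[, , 1], 3L), c(dim(px)[1:2], 3L))
  rgb_image(round_half_up(px * 255),
            id = sub("\\.[^.]+$", "", basename(path)))
}

#' Read a binary ground-truth or prediction mask
#'
#' Reads a single-channel raster holding exactly two pixel values (0 plus one
#' nonzero value, conventionally 255; an all-0 or all-nonzero raster is also
#' accepted). Nonzero maps to foreground.
#'
#' @param path Path to a single-channel raster file.
#' @param provenance Provenance tag for the resulting mask; defaults to
#'   `"ground_truth"`.
#' @return A [binary_mask()].
#' @export
read_mask <- function(path, provenance = "ground_truth") {
  raw <- read_raster(path)
  px <- raw$values
  if (length(dim(px)) == 3L) {
    abort_if(dim(px)[3] != 1L,
             sprintf("'%s' is not single-channel (found %d channels)",
                     path, dim(px)[3]))
    px <- px[, , 1]
  }
  lev <- sort(unique(as.vector(px)))
  abort_if(length(lev) > 2L || (length(lev) == 2L && lev[1] != 0),
           sprintf("mask '%s' is not two-valued with background 0: values {%s}",
                   path, paste(signif(lev * 255, 4), collapse = ", ")))
  binary_mask(matrix(px > 0, nrow(px), ncol(px)), provenance = provenance)
}

#' Write an image or mask as PNG
#'
#' `write_image()` writes an [rgb_image()] as 8-bit RGB PNG; `write_mask()`
#' writes a [binary_mask()] as single-channel PNG with foreground 255 and
#' background 0 (visually inspectable, losslessly round-trippable with
#' [read_mask()]).
#'
#' @param image An [rgb_image()].
#' @param mask A [binary_mask()].
#' @param path Output path (PNG).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "rgb_image"))
  png::writePNG(image$pixels / 255, target = path)
  invisible(path)
}

#' @rdname write_image
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  png::writePNG(mask$values * 1.0, target = path)
  invisible(path)
}

# internal: decode any supported raster to values in [0,1]; enforce 8-bit.
read_raster <- function(path) {
  abort_if(!file.exists(path), sprintf("file not found: '%s'", path))
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "png") {
    px <- png::readPNG(path, info = TRUE)
    depth <- attr(px, "info")$bit.depth
    abort_if(!is.null(depth) && depth != 8,
             sprintf("'%s' is %d-bit; only 8-bit rasters are supported",
                     path, depth))
  } else if (ext %in% c("tif", "tiff")) {
    px <- tiff::readTIFF(path, info = TRUE)
    depth <- attr(px, "bits.per.sample")
    abort_if(!is.null(depth) && depth != 8,
             sprintf("'%s' is %d-bit; only 8-bit rasters are supported",
                     path, depth))
  } else if (ext %in% c("jpg", "jpeg")) {
    px <- jpeg::readJPEG(path)
  } else {
    stop(sprintf("unsupported raster format '.%s' (use PNG/TIFF/JPEG)", ext),
         call. = FALSE)
  }
  # drop a fully-opaque alpha channel rather than failing
  if (length(dim(px)) == 3L && dim(px)[3] %in% c(2L, 4L)) {
    alpha <- px[, , dim(px)[3]]
    abort_if(any(alpha != 1), sprintf("'%s' has a non-trivial alpha channel",
                                      path))
    px <- px[, , -dim(px)[3], drop = FALSE]
    if (dim(px)[3] == 1L) px <- px[, , 1]
  }
  list(values = px)
}
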