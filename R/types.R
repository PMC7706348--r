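#' RGB image container
#'
#' An 8-bit RGB raster stored as an `height x width x 3` integer array with
#' values in `[0, 255]`, row-major with origin at the top-left, 1-based
#' `(row, col)` pixel coordinates (the R raster convention). This is the raw
#' observation every stage of the segmentation pipeline operates on.
#'
#' @param pixels A numeric array. Either `H x W x 3`, or an `H x W` matrix
#'   (treated as grayscale and replicated across the three channels). Values
#'   must be integers in `[0, 255]`.
#' @param id Character identifier, typically the source filename stem.
#'
#' @return An object of class `rgb_image` with fields `pixels`, `height`,
#'   `width` and `id`.
#' @seealso [read_image()], [binarize_image()], [generate_scene()]
#' @export
#' @examples
#' img <- rgb_image(array(128L, c(8, 8, 3)), id = "flat")
#' img$height
rgb_image <- function(pixels, id = "image") {
  abort_if(!is.numeric(pixels) && !is.logical(pixels),
           "`pixels` must be a numeric array")
  if (is.matrix(pixels)) {
    pixels <- array(rep(pixels, 3L), c(dim(pixels), 3L))
  }
  d <- dim(pixels)
  abort_if(length(d) != 3L || d[3] != 3L,
           "`pixels` must be an H x W x 3 array (or an H x W matrix)")
  abort_if(anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255,
           "pixel intensities must lie in [0, 255]")
  abort_if(any(pixels != floor(pixels)), "pixel intensities must be integers")
  storage.mode(pixels) <- "integer"
  attributes(pixels) <- list(dim = d)   # drop decoder metadata etc.
  structure(
    list(pixels = pixels, height = d[1], width = d[2], id = as.character(id)),
    class = "rgb_image"
  )
}

#' @export
print.rgb_image <- function(x, ...) {
  cat(sprintf("<rgb_image '%s'> %d x %d x 3, 8-bit\n", x$id, x$height, x$width))
  invisible(x)
}

#' Binary segmentation mask
#'
#' A boolean `height x width` raster aligned to an [rgb_image()], tagged with
#' the stage that produced it. Masks from the thresholding stage carry the
#' precise target contours; masks from the patch classifier carry contextual
#' (but boundary-inflated) detections; the combined mask is their pixel-wise
#' intersection.
#'
#' @param values A logical matrix (or 0/1 numeric matrix).
#' @param provenance One of `"ground_truth"`, `"binarization"`, `"cnn"`,
#'   `"combined"`.
#'
#' @return An object of class `binary_mask` with fields `values`, `height`,
#'   `width` and `provenance`.
#' @export
binary_mask <- function(values,
                        provenance = c("ground_truth", "binarization",
                                       "cnn", "combined")) {
  provenance <- match.arg(provenance)
  abort_if(!is.matrix(values), "`values` must be a matrix")
  if (is.numeric(values)) {
    abort_if(!all(values %in% c(0, 1)), "numeric mask values must be 0/1")
    values <- values > 0
  }
  abort_if(!is.logical(values) || anyNA(values),
           "`values` must be logical with no NA")
  structure(
    list(values = values, height = nrow(values), width = ncol(values),
         provenance = provenance),
    class = "binary_mask"
  )
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask [%s]> %d x %d, %d foreground px (%.1f%%)\n",
              x$provenance, x$height, x$width, sum(x$values),
              100 * mean(x$values)))
  invisible(x)
}

# internal: shape agreement between rasters
check_same_shape <- function(a, b, what = "masks") {
  abort_if(a$height != b$height || a$width != b$width,
           sprintf("%s have different shapes: %dx%d vs %dx%d",
                   what, a$height, a$width, b$height, b$width))
  invisible(TRUE)
}
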