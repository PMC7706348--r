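#' Dense whole-image prediction with a sliding window
#'
#' Classifies the (reflect-padded) patch centered on every pixel of a stride
#' grid and assigns the patch label to its center pixel. With `stride > 1`
#' each pixel takes the label of its nearest grid center, so the returned
#' mask is always dense; stride 1 is exact per-pixel labeling, larger strides
#' trade boundary fidelity for speed. Patches are classified in batches,
#' which never changes the result.
#'
#' @param network A `flower_cnn`/`flower_cnn_fit`, or a plain function
#'   `f(blocks)` taking a `p x p x 3 x B` 8-bit array and returning a logical
#'   vector of length `B` (useful for mock classifiers in tests).
#' @param image An [rgb_image()] at least `patch_size` pixels in each
#'   dimension.
#' @param stride Grid spacing in pixels, `1 <= stride <= min(H, W)`.
#' @param patch_size Patch edge length; taken from the network configuration
#'   when `network` is a CNN, required (odd) when it is a function.
#' @param batch_size Patches classified per forward pass.
#' @return A [binary_mask()] with provenance `"cnn"`.
#' @export
sliding_window_predict <- function(network, image, stride = 1L,
                                   patch_size = NULL, batch_size = 256L) {
  stopifnot(inherits(image, "rgb_image"))
  if (is.function(network)) {
    abort_if(is.null(patch_size), "`patch_size` is required with a function classifier")
  } else {
    patch_size <- as_network(network)$cfg$input_size
  }
  abort_if(patch_size %% 2 != 1, "`patch_size` must be odd")
  h <- image$height; w <- image$width
  abort_if(stride < 1 || stride > min(h, w),
           sprintf("stride must be in [1, %d]", min(h, w)))
  abort_if(h < patch_size || w < patch_size,
           sprintf("image must be at least %d x %d", patch_size, patch_size))

  r <- (patch_size - 1L) %/% 2L
  # reflect-pad once; every patch is then a plain slice
  ri <- reflect_index((1L - r):(h + r), h)
  ci <- reflect_index((1L - r):(w + r), w)
  padded <- image$pixels[ri, ci, , drop = FALSE]

  gr <- seq(1L, h, by = stride)
  gc <- seq(1L, w, by = stride)
  grid <- expand.grid(gi = seq_along(gr), gj = seq_along(gc))
  labels <- logical(nrow(grid))
  for (start in seq(1L, nrow(grid), by = batch_size)) {
    sel <- start:min(start + batch_size - 1L, nrow(grid))
    blocks <- array(0, c(patch_size, patch_size, 3L, length(sel)))
    for (k in seq_along(sel)) {
      rr <- gr[grid$gi[sel[k]]]
      cc <- gc[grid$gj[sel[k]]]
      blocks[, , , k] <- padded[rr:(rr + 2L * r), cc:(cc + 2L * r), ]
    }
    labels[sel] <- if (is.function(network)) {
      as.logical(network(blocks))
    } else {
      predict_scores(network, blocks) > 0.5
    }
  }
  labmat <- matrix(labels[order(grid$gj, grid$gi)],
                   length(gr), length(gc))
  # nearest-center fill
  nr <- pmin(floor((seq_len(h) - 1L) / stride + 0.5) + 1L, length(gr))
  nc <- pmin(floor((seq_len(w) - 1L) / stride + 0.5) + 1L, length(gc))
  binary_mask(labmat[nr, nc, drop = FALSE], "cnn")
}

#' Intersect the binarization and classifier masks
#'
#' The combination step of the method: a pixel is foreground only where the
#' threshold mask (precise contours, bright clutter included) *and* the patch
#' classifier mask (contextually validated, boundary-inflated) agree. The
#' intersection keeps the thresholded contours while the classifier deletes
#' bright background noise; equivalently it trims the classifier's inflated
#' boundaries back to the thresholded outline.
#'
#' @param bin_mask,cnn_mask [binary_mask()] objects of equal shape.
#' @return A [binary_mask()] with provenance `"combined"`.
#' @export
combine_masks <- function(bin_mask, cnn_mask) {
  stopifnot(inherits(bin_mask, "binary_mask"), inherits(cnn_mask, "binary_mask"))
  check_same_shape(bin_mask, cnn_mask)
  binary_mask(bin_mask$values & cnn_mask$values, "combined")
}

#' Run the full segmentation pipeline on one image
#'
#' Binarizes the image ([binarize_image()]), runs the sliding-window patch
#' classifier ([sliding_window_predict()]), and intersects the two masks
#' ([combine_masks()]). Deterministic given the network and image.
#'
#' @inheritParams sliding_window_predict
#' @return An object of class `prediction_bundle`: the three masks
#'   (`bin_mask`, `cnn_mask`, `combined_mask`), `stride` and `image_id`. The
#'   constructor asserts `combined = bin AND cnn` bit-exactly.
#' @export
run_pipeline <- function(network, image, stride = 1L, patch_size = NULL,
                         batch_size = 256L) {
  bin <- binarize_image(image)
  cnn <- sliding_window_predict(network, image, stride = stride,
                                patch_size = patch_size,
                                batch_size = batch_size)
  prediction_bundle(bin, cnn, combine_masks(bin, cnn),
                    stride = stride, image_id = image$id)
}

#' @rdname run_pipeline
#' @param bin_mask,cnn_mask,combined_mask The three stage masks.
#' @param stride Stride used for the classifier mask.
#' @param image_id Source image identifier.
#' @export
prediction_bundle <- function(bin_mask, cnn_mask, combined_mask, stride,
                              image_id) {
  check_same_shape(bin_mask, cnn_mask)
  check_same_shape(bin_mask, combined_mask)
  abort_if(!identical(combined_mask$values,
                      bin_mask$values & cnn_mask$values),
           "combined mask must equal bin AND cnn pixel-wise")
  abort_if(bin_mask$provenance != "binarization" ||
             cnn_mask$provenance != "cnn" ||
             combined_mask$provenance != "combined",
           "mask provenances must be binarization / cnn / combined")
  structure(list(bin_mask = bin_mask, cnn_mask = cnn_mask,
                 combined_mask = combined_mask, stride = as.integer(stride),
                 image_id = image_id),
            class = "prediction_bundle")
}

#' @export
print.prediction_bundle <- function(x, ...) {
  cat(sprintf(
    "<prediction_bundle '%s'> stride %d | foreground px: bin %d, cnn %d, combined %d\n",
    x$image_id, x$stride, sum(x$bin_mask$values), sum(x$cnn_mask$values),
    sum(x$combined_mask$values)))
  invisible(x)
}
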