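#' Grayscale projection of an RGB image
#'
#' Rec. 601 luma, `0.299 R + 0.587 G + 0.114 B`, rounded half-up and clipped
#' to `[0, 255]`. Bright flowers are near-white, so any luminance projection
#' separates them from the darker canopy; luma is the standard choice and the
#' default scalar image the thresholding stage operates on.
#'
#' @param image An [rgb_image()].
#' @return An integer `H x W` matrix of intensities in `[0, 255]`.
#' @export
to_grayscale <- function(image) {
  stopifnot(inherits(image, "rgb_image"))
  px <- image$pixels
  g <- LUMA[1] * px[, , 1] + LUMA[2] * px[, , 2] + LUMA[3] * px[, , 3]
  g <- matrix(clip8(round_half_up(g)), image$height, image$width)
  storage.mode(g) <- "integer"
  g
}

#' Otsu's threshold from the 256-bin histogram
#'
#' Global binarization: picks the intensity threshold `t` maximizing the
#' between-class variance `w0 * w1 * (mu0 - mu1)^2` of the two pixel classes
#' it induces, computed from the 256-bin histogram. Candidates are
#' `t = 0..254` with both classes non-empty; foreground is the *high* class
#' (`intensity > t`), which is where the bright targets live. When several
#' thresholds attain the maximum the smallest is returned, the deterministic
#' choice that favors a larger foreground (thresholding is the
#' recall-preserving stage of the combined method). A single-valued image has
#' no second class: the threshold is that value, the variance 0, and the mask
#' all-background.
#'
#' @param gray An integer matrix (or vector) of intensities in `[0, 255]`,
#'   e.g. from [to_grayscale()].
#' @return An object of class `otsu_result`: a list with `threshold`,
#'   `between_class_variance`, and `mask` (a [binary_mask()] with provenance
#'   `"binarization"`).
#' @export
#' @examples
#' g <- matrix(c(rep(10L, 6), rep(200L, 4)), 2, 5)
#' otsu_threshold(g)$threshold
otsu_threshold <- function(gray) {
  abort_if(length(gray) == 0L, "empty intensity array")
  abort_if(anyNA(gray) || min(gray) < 0 || max(gray) > 255,
           "intensities must lie in [0, 255]")
  if (!is.matrix(gray)) gray <- matrix(as.integer(gray), nrow = 1L)
  h <- tabulate(as.integer(gray) + 1L, nbins = 256L)
  n <- sum(h)
  lv <- 0:255
  total <- sum(h * lv)
  cumn <- cumsum(h)[1:255]          # class sizes for t = 0..254 (low class <= t)
  cums <- cumsum(h * lv)[1:255]
  valid <- cumn > 0 & cumn < n
  if (!any(valid)) {                # single-valued image
    v <- as.integer(gray[1])
    return(structure(
      list(threshold = v, between_class_variance = 0,
           mask = binary_mask(matrix(FALSE, nrow(gray), ncol(gray)),
                              "binarization")),
      class = "otsu_result"))
  }
  w0 <- cumn / n
  mu0 <- cums / cumn
  mu1 <- (total - cums) / (n - cumn)
  bcv <- rep(-Inf, 255)
  bcv[valid] <- (w0 * (1 - w0) * (mu0 - mu1)^2)[valid]
  t <- which.max(bcv) - 1L          # first max = smallest tied threshold
  structure(
    list(threshold = t, between_class_variance = max(bcv),
         mask = binary_mask(gray > t, "binarization")),
    class = "otsu_result")
}

#' @export
print.otsu_result <- function(x, ...) {
  cat(sprintf("<otsu_result> threshold = %d, between-class variance = %.3f\n",
              x$threshold, x$between_class_variance))
  invisible(x)
}

#' Binarize an RGB image by Otsu thresholding of its luma
#'
#' The contour-extraction stage of the combined method: converts the image to
#' grayscale with [to_grayscale()] and thresholds it with [otsu_threshold()].
#' The resulting mask traces bright-target outlines precisely but also picks
#' up bright background clutter — which the patch classifier stage removes.
#' No morphological post-processing is applied.
#'
#' @param image An [rgb_image()].
#' @return A [binary_mask()] with provenance `"binarization"`; the selected
#'   threshold and its between-class variance are attached as attributes
#'   `"threshold"` and `"between_class_variance"`.
#' @export
binarize_image <- function(image) {
  res <- otsu_threshold(to_grayscale(image))
  m <- res$mask
  attr(m, "threshold") <- res$threshold
  attr(m, "between_class_variance") <- res$between_class_variance
  m
}
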