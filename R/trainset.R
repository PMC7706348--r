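#' Extract a square patch centered on a pixel
#'
#' Returns the `patch_size x patch_size` neighborhood block around `center`;
#' windows crossing the image border are completed by mirror (reflect)
#' padding, which preserves local intensity statistics better than
#' zero-padding. The same padding rule is used by sliding-window inference so
#' training and prediction see identical border behavior.
#'
#' @param image An [rgb_image()].
#' @param center Length-2 integer vector `(row, col)`, 1-based, inside the
#'   image.
#' @param patch_size Odd patch edge length (default 31; chosen to cover a
#'   whole ~900 px^2 target).
#' @return An integer `patch_size x patch_size x 3` array.
#' @export
extract_patch <- function(image, center, patch_size = 31L) {
  stopifnot(inherits(image, "rgb_image"))
  abort_if(patch_size %% 2 != 1 || patch_size < 1,
           "`patch_size` must be a positive odd integer")
  center <- as.integer(center)
  abort_if(length(center) != 2L || anyNA(center) ||
             center[1] < 1L || center[1] > image$height ||
             center[2] < 1L || center[2] > image$width,
           sprintf("center (%s) out of bounds for %d x %d image",
                   paste(center, collapse = ", "),
                   image$height, image$width))
  r <- (patch_size - 1L) %/% 2L
  ri <- reflect_index((center[1] - r):(center[1] + r), image$height)
  ci <- reflect_index((center[2] - r):(center[2] + r), image$width)
  image$pixels[ri, ci, , drop = FALSE]
}

# patch_set: tibble of samples + metadata; the CNN's training unit collection
patch_set <- function(samples, patch_size, seed = NA_integer_) {
  stopifnot(all(c("image_id", "row", "col", "label", "block") %in%
                  names(samples)))
  structure(tibble::as_tibble(samples),
            patch_size = as.integer(patch_size),
            seed = seed,
            class = c("patch_set", class(tibble::tibble())))
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %d samples (%d positive, %d negative), %d x %d patches\n",
              nrow(x), sum(x$label == "positive"), sum(x$label == "negative"),
              attr(x, "patch_size"), attr(x, "patch_size")))
  invisible(x)
}

#' Build positive / negative patch sample sets
#'
#' `build_positive_set()` cuts one patch per supplied center from images known
#' to contain targets (centers typically come from merged superpixel regions,
#' [merge_regions()], or from a generated scene's flower centers).
#' `build_negative_set()` samples `n_per_image` patch centers uniformly
#' *without replacement* from images verified target-free, reproducibly from
#' `seed`. Duplicate centers are kept as duplicate samples; deduplication is
#' the caller's responsibility.
#'
#' @param flower_images,background_images Lists of [rgb_image()].
#' @param centers_per_image List (parallel to `flower_images`) of data frames
#'   or 2-column matrices of 1-based `(row, col)` centers.
#' @param n_per_image Number of negative patches per background image.
#' @param patch_size Odd patch edge length.
#' @param seed Integer seed for negative sampling.
#' @return A `patch_set` tibble: columns `image_id`, `row`, `col`, `label`,
#'   `block` (list of `patch_size x patch_size x 3` arrays).
#' @export
build_positive_set <- function(flower_images, centers_per_image,
                               patch_size = 31L) {
  stopifnot(length(flower_images) == length(centers_per_image))
  rows <- purrr::map2(flower_images, centers_per_image, function(img, ctr) {
    ctr <- as.data.frame(ctr)
    if (nrow(ctr) == 0L) return(NULL)
    names(ctr)[1:2] <- c("row", "col")
    tibble::tibble(
      image_id = img$id,
      row = as.integer(ctr$row), col = as.integer(ctr$col),
      label = "positive",
      block = purrr::map2(ctr$row, ctr$col,
                          ~ extract_patch(img, c(.x, .y), patch_size)))
  })
  out <- dplyr::bind_rows(rows)
  abort_if(nrow(out) == 0L,
           "no positive centers supplied; cannot build a positive set")
  patch_set(out, patch_size)
}

#' @rdname build_positive_set
#' @export
build_negative_set <- function(background_images, n_per_image,
                               patch_size = 31L, seed = 1L) {
  abort_if(n_per_image < 0, "`n_per_image` must be >= 0")
  rows <- purrr::imap(background_images, function(img, i) {
    npix <- img$height * img$width
    abort_if(n_per_image > npix,
             sprintf("n_per_image = %d exceeds the %d pixels of image '%s'",
                     n_per_image, npix, img$id))
    if (n_per_image == 0L) return(NULL)
    idx <- with_stream(seed, paste0("negatives/", i, "/", img$id),
                       sample.int(npix, n_per_image))
    rr <- ((idx - 1L) %% img$height) + 1L
    cc <- ((idx - 1L) %/% img$height) + 1L
    tibble::tibble(
      image_id = img$id, row = rr, col = cc, label = "negative",
      block = purrr::map2(rr, cc, ~ extract_patch(img, c(.x, .y), patch_size)))
  })
  empty <- tibble::tibble(image_id = character(0), row = integer(0),
                          col = integer(0), label = character(0),
                          block = list())
  patch_set(dplyr::bind_rows(c(list(empty), rows)), patch_size, seed = seed)
}

#' Write or read a patch set on disk
#'
#' `write_patch_set()` stores the blocks as PNG files in `positive/` and
#' `negative/` subdirectories plus a `manifest.csv` (columns `path`, `label`,
#' `image_id`, `row`, `col`; 1-based coordinates); `read_patch_set()` loads
#' such a directory back. Block PNGs round-trip bit-exactly.
#'
#' @param patches A `patch_set`.
#' @param dir Directory to write to / read from.
#' @return `write_patch_set()` the manifest tibble (invisibly);
#'   `read_patch_set()` a `patch_set`.
#' @export
write_patch_set <- function(patches, dir) {
  stopifnot(inherits(patches, "patch_set"))
  for (d in file.path(dir, c("positive", "negative"))) {
    dir.create(d, showWarnings = FALSE, recursive = TRUE)
  }
  paths <- file.path(dir, patches$label,
                     sprintf("%s_%05d.png", patches$label,
                             seq_len(nrow(patches))))
  purrr::walk2(patches$block, paths,
               ~ png::writePNG(.x / 255, target = .y))
  manifest <- tibble::tibble(path = file.path(patches$label, basename(paths)),
                             label = patches$label,
                             image_id = patches$image_id,
                             row = patches$row, col = patches$col)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' @rdname write_patch_set
#' @export
read_patch_set <- function(dir) {
  mf <- utils::read.csv(file.path(dir, "manifest.csv"),
                        stringsAsFactors = FALSE)
  blocks <- purrr::map(file.path(dir, mf$path), function(p) {
    px <- png::readPNG(p)
    arr <- round_half_up(px * 255)
    storage.mode(arr) <- "integer"
    arr
  })
  ps <- dim(blocks[[1]])[1]
  patch_set(tibble::tibble(image_id = mf$image_id, row = mf$row, col = mf$col,
                           label = mf$label, block = blocks),
            patch_size = ps)
}
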