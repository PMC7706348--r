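#' Specification of a synthetic canopy scene
#'
#' Parameters of the seeded scene generator that emulates ground-based canopy
#' imagery with small bright flowering targets: near-white elliptical flower
#' clusters of ~900 px area on a darker, low-frequency textured, green-dominant
#' background, plus small bright distractors (specular leaves, soil highlights)
#' whose pixel *values* overlap the flowers' but whose spatial context does
#' not — they exist to be removed by the patch-classifier stage. An `intense`
#' illumination regime multiplies all channels by `intense_gain` (then clips),
#' pushing the background toward the flower intensities and stressing pure
#' thresholding.
#'
#' @param height,width Scene size in pixels.
#' @param n_flowers Number of non-overlapping flower clusters.
#' @param flower_area_mean Mean flower area in px^2 (default 900, the target
#'   size that motivates the 31x31 patch).
#' @param flower_area_cv Coefficient of variation of flower areas.
#' @param flower_luma_range,background_luma_range Intensity ranges (0-255).
#' @param background_texture_scale Spatial scale (px) of the low-frequency
#'   background texture.
#' @param n_distractors Number of small bright background specks.
#' @param distractor_area_range Distractor areas in px^2; kept below 50 px^2
#'   so a 31x31 context window suffices to reject them.
#' @param illumination `"soft"` or `"intense"`.
#' @param intense_gain Channel gain applied under intense illumination.
#' @param perspective_squash Vertical/horizontal ellipse axis ratio in (0, 1];
#'   stands in for the camera depression angle (lower angle, flatter ellipse).
#' @param seed Integer seed; the scene is fully determined by it.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(height = 160, width = 160,
                       n_flowers = 5,
                       flower_area_mean = 900,
                       flower_area_cv = 0.2,
                       flower_luma_range = c(225, 255),
                       background_luma_range = c(40, 140),
                       background_texture_scale = 16,
                       n_distractors = 25,
                       distractor_area_range = c(4, 40),
                       illumination = c("soft", "intense"),
                       intense_gain = 1.6,
                       perspective_squash = 0.7,
                       seed = 1L) {
  illumination <- match.arg(illumination)
  spec <- list(height = as.integer(height), width = as.integer(width),
               n_flowers = as.integer(n_flowers),
               flower_area_mean = flower_area_mean,
               flower_area_cv = flower_area_cv,
               flower_luma_range = flower_luma_range,
               background_luma_range = background_luma_range,
               background_texture_scale = background_texture_scale,
               n_distractors = as.integer(n_distractors),
               distractor_area_range = distractor_area_range,
               illumination = illumination,
               intense_gain = intense_gain,
               perspective_squash = perspective_squash,
               seed = as.integer(seed))
  validate_scene_spec(spec)
  structure(spec, class = "scene_spec")
}

validate_scene_spec <- function(s) {
  abort_if(s$height < 32 || s$width < 32, "scene must be at least 32 x 32")
  abort_if(s$n_flowers < 0 || s$n_distractors < 0, "counts must be >= 0")
  tot <- s$n_flowers * s$flower_area_mean
  abort_if(tot >= 0.3 * s$height * s$width,
           sprintf(paste0("infeasible spec: total flower area %.0f px^2 ",
                          "exceeds 30%% of the %d x %d scene"),
                   tot, s$height, s$width))
  abort_if(s$distractor_area_range[2] >= 50,
           "distractor areas must stay below 50 px^2")
  abort_if(s$perspective_squash <= 0 || s$perspective_squash > 1,
           "perspective_squash must be in (0, 1]")
  abort_if(diff(s$flower_luma_range) < 0 || diff(s$background_luma_range) < 0,
           "luma ranges must be [low, high]")
  invisible(s)
}

# bilinear upsampling of a coarse noise grid -> low-frequency field in [0,1]
low_freq_field <- function(h, w, scale) {
  gr <- floor((h - 1) / scale) + 2L
  gc <- floor((w - 1) / scale) + 2L
  g <- matrix(stats::runif(gr * gc), gr, gc)
  u <- (seq_len(h) - 1) / scale
  v <- (seq_len(w) - 1) / scale
  i0 <- pmin(floor(u) + 1L, gr - 1L); fu <- u - (i0 - 1L)
  j0 <- pmin(floor(v) + 1L, gc - 1L); fv <- v - (j0 - 1L)
  a <- g[i0, j0] * outer(1 - fu, 1 - fv) + g[i0 + 1L, j0] * outer(fu, 1 - fv) +
    g[i0, j0 + 1L] * outer(1 - fu, fv) + g[i0 + 1L, j0 + 1L] * outer(fu, fv)
  rng <- range(a)
  if (diff(rng) == 0) return(matrix(0.5, h, w))
  (a - rng[1]) / diff(rng)
}

#' Generate one synthetic canopy scene with ground truth
#'
#' Renders the scene described by a [scene_spec()]: a green-dominant
#' low-frequency background, anti-aliased bright flower ellipses with a
#' +-2 px soft edge (rejection-sampled so flowers never overlap), and small
#' bright distractor specks. The truth mask covers flower pixels only;
#' distractors are background. Fully deterministic given `spec$seed`, with
#' independent named randomness streams for background, placement, colors and
#' distractors.
#'
#' @param spec A [scene_spec()].
#' @return An object of class `synthetic_scene`: list with `image`
#'   ([rgb_image()]), `truth` ([binary_mask()], provenance `"ground_truth"`),
#'   `flower_centers` (tibble of 1-based `row`, `col`), and `spec`.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  h <- spec$height; w <- spec$width; seed <- spec$seed

  # background: low-frequency luma field, green-dominant hue, mild grain
  bg_luma <- with_stream(seed, "background", {
    f <- low_freq_field(h, w, spec$background_texture_scale)
    l <- spec$background_luma_range[1] + f * diff(spec$background_luma_range)
    pmin(pmax(l + stats::rnorm(h * w, sd = 3), spec$background_luma_range[1]),
         spec$background_luma_range[2])
  })
  img <- array(0, c(h, w, 3))
  hue <- c(0.88, 1.12, 0.72)            # green-dominant, ~unit luma weight
  for (ch in 1:3) img[, , ch] <- clip8(bg_luma * hue[ch])

  truth <- matrix(FALSE, h, w)
  centers <- NULL
  squash <- spec$perspective_squash

  if (spec$n_flowers > 0) {
    # areas resampled until the total honors the ground-truth budget
    areas <- with_stream(seed, "areas", {
      tgt <- spec$n_flowers * spec$flower_area_mean
      for (i in 1:200) {
        a <- stats::rnorm(spec$n_flowers, spec$flower_area_mean,
                          spec$flower_area_cv * spec$flower_area_mean)
        a <- pmax(a, 60)
        if (abs(sum(a) - tgt) <= 0.2 * tgt) break
      }
      a
    })
    ax <- sqrt(areas / (pi * squash))   # horizontal semi-axis
    bx <- ax * squash                   # vertical semi-axis
    pl <- with_stream(seed, "placement", {
      cy <- numeric(0); cx <- numeric(0)
      for (i in seq_len(spec$n_flowers)) {
        ok <- FALSE
        for (try in 1:500) {
          ry <- stats::runif(1, bx[i] + 3, h - bx[i] - 2)
          rx <- stats::runif(1, ax[i] + 3, w - ax[i] - 2)
          if (i == 1 ||
              all((ry - cy)^2 + (rx - cx)^2 >
                  (ax[i] + ax[seq_len(i - 1)] + 4)^2)) {
            ok <- TRUE; break
          }
        }
        abort_if(!ok, sprintf(
          "could not place flower %d without overlap; scene too crowded", i))
        cy <- c(cy, ry); cx <- c(cx, rx)
      }
      cbind(cy, cx)
    })
    cols <- with_stream(seed, "colors", {
      lf <- stats::runif(spec$n_flowers, spec$flower_luma_range[1],
                         spec$flower_luma_range[2])
      cbind(R = lf * stats::runif(spec$n_flowers, 0.97, 1),
            G = lf,
            B = lf * stats::runif(spec$n_flowers, 0.93, 1))
    })
    for (i in seq_len(spec$n_flowers)) {
      rr <- max(1L, floor(pl[i, 1] - bx[i] - 3)):min(h, ceiling(pl[i, 1] + bx[i] + 3))
      cc <- max(1L, floor(pl[i, 2] - ax[i] - 3)):min(w, ceiling(pl[i, 2] + ax[i] + 3))
      d <- sqrt(outer(((rr - pl[i, 1]) / bx[i])^2,
                      ((cc - pl[i, 2]) / ax[i])^2, `+`))
      alpha <- pmax(0, pmin(1, 0.5 - (d - 1) * bx[i] / 4))  # +-2 px soft edge
      for (ch in 1:3) {
        img[rr, cc, ch] <- alpha * cols[i, ch] + (1 - alpha) * img[rr, cc, ch]
      }
      truth[rr, cc] <- truth[rr, cc] | (d <= 1)
    }
    centers <- cbind(row = round_half_up(pl[, 1]), col = round_half_up(pl[, 2]))
  }

  if (spec$n_distractors > 0) {
    with_stream(seed, "distractors", {
      for (i in seq_len(spec$n_distractors)) {
        rd <- sqrt(stats::runif(1, spec$distractor_area_range[1],
                                spec$distractor_area_range[2]) / pi)
        for (try in 1:200) {
          ry <- stats::runif(1, rd + 2, h - rd - 1)
          rx <- stats::runif(1, rd + 2, w - rd - 1)
          clear <- is.null(centers) ||
            all((ry - pl[, 1])^2 + (rx - pl[, 2])^2 > (ax + rd + 4)^2)
          if (clear) break
        }
        if (!clear) next                 # crowded scene: drop the speck
        lum <- stats::runif(1, spec$flower_luma_range[1],
                            spec$flower_luma_range[2])
        col <- c(lum * stats::runif(1, 0.97, 1), lum,
                 lum * stats::runif(1, 0.93, 1))
        rr <- max(1L, floor(ry - rd - 1)):min(h, ceiling(ry + rd + 1))
        cc <- max(1L, floor(rx - rd - 1)):min(w, ceiling(rx + rd + 1))
        d <- sqrt(outer((rr - ry)^2, (cc - rx)^2, `+`))
        alpha <- pmax(0, pmin(1, rd - d + 0.5))   # 1 px soft edge
        for (ch in 1:3) {
          img[rr, cc, ch] <- alpha * col[ch] + (1 - alpha) * img[rr, cc, ch]
        }
      }
    })
  }

  if (spec$illumination == "intense") img <- clip8(img * spec$intense_gain)

  structure(
    list(image = rgb_image(clip8(round_half_up(img)),
                           id = sprintf("scene_%d", seed)),
         truth = binary_mask(truth, "ground_truth"),
         flower_centers = if (is.null(centers)) {
           tibble::tibble(row = integer(0), col = integer(0))
         } else {
           tibble::as_tibble(centers)
         },
         spec = spec),
    class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene '%s'> %d x %d, %d flowers (%d truth px), %s light\n",
              x$image$id, x$image$height, x$image$width,
              x$spec$n_flowers, sum(x$truth$values), x$spec$illumination))
  invisible(x)
}

#' Generate a seeded benchmark family of scenes
#'
#' Generates `n_scenes` scenes from one [scene_spec()] with consecutive seeds
#' `seed, seed+1, ..., seed+n_scenes-1`, optionally writing
#' `scene_XXX.png` / `truth_XXX.png` pairs and a `manifest.csv` to `dir`.
#'
#' @param spec A [scene_spec()]; its `seed` field is overridden per scene.
#' @param n_scenes Number of scenes.
#' @param seed First seed of the range.
#' @param dir Optional output directory.
#' @return List with `scenes` (list of `synthetic_scene`) and `manifest`
#'   (tibble: `scene`, `seed`, `n_flowers`, `truth_px`, and file paths when
#'   `dir` is given).
#' @export
generate_benchmark <- function(spec, n_scenes, seed, dir = NULL) {
  abort_if(!is_count(n_scenes), "`n_scenes` must be a positive count")
  scenes <- purrr::map(seq_len(n_scenes) - 1L, function(k) {
    s <- spec
    s$seed <- as.integer(seed + k)
    generate_scene(structure(s, class = "scene_spec"))
  })
  manifest <- tibble::tibble(
    scene = sprintf("scene_%03d", seq_len(n_scenes)),
    seed = as.integer(seed + seq_len(n_scenes) - 1L),
    n_flowers = purrr::map_int(scenes, ~ .x$spec$n_flowers),
    truth_px = purrr::map_int(scenes, ~ sum(.x$truth$values))
  )
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    manifest$image_path <- file.path(dir, sprintf("scene_%03d.png",
                                                  seq_len(n_scenes)))
    manifest$truth_path <- file.path(dir, sprintf("truth_%03d.png",
                                                  seq_len(n_scenes)))
    purrr::walk(seq_len(n_scenes), function(i) {
      write_image(scenes[[i]]$image, manifest$image_path[i])
      write_mask(scenes[[i]]$truth, manifest$truth_path[i])
    })
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(scenes = scenes, manifest = manifest)
}

#' Build a patch training set from synthetic scenes
#'
#' Positives are patches centered on the generated flower centers of the
#' flower scenes; negatives are randomly sampled patches from flower-free
#' background scenes (which retain their bright distractors, so the
#' classifier learns to reject them).
#'
#' @param scenes List of `synthetic_scene` with flowers.
#' @param background_scenes List of `synthetic_scene` with `n_flowers = 0`.
#' @param n_neg_per_image Negatives sampled per background scene.
#' @param seed Integer seed for the negative sampling.
#' @param patch_size Odd patch edge length (default 31).
#' @return A `patch_set` (see [build_positive_set()]).
#' @export
scene_to_trainset <- function(scenes, background_scenes, n_neg_per_image,
                              seed, patch_size = 31L) {
  abort_if(any(purrr::map_int(background_scenes, ~ .x$spec$n_flowers) != 0L),
           "`background_scenes` must have n_flowers = 0")
  pos <- build_positive_set(
    purrr::map(scenes, "image"),
    purrr::map(scenes, ~ .x$flower_centers),
    patch_size = patch_size)
  neg <- build_negative_set(
    purrr::map(background_scenes, "image"),
    n_per_image = n_neg_per_image, patch_size = patch_size, seed = seed)
  patch_set(dplyr::bind_rows(pos, neg), patch_size = patch_size, seed = seed)
}
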