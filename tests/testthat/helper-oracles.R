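# Independent oracles and fixture builders used across the suite.

# exhaustive Otsu: evaluate every split 0..254 directly from the pixel list
brute_force_otsu <- function(gray) {
  v <- as.vector(gray)
  best_t <- NA_integer_
  best_b <- -Inf
  for (t in 0:254) {
    lo <- v[v <= t]
    hi <- v[v > t]
    if (length(lo) == 0L || length(hi) == 0L) next
    w0 <- length(lo) / length(v)
    b <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (b > best_b + 1e-12) {   # strict: ties keep the smallest t
      best_b <- b
      best_t <- t
    }
  }
  list(threshold = best_t, between_class_variance = best_b)
}

# per-pixel confusion tally by explicit loop
loop_confusion <- function(pred, truth) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      if (pred[i, j] && truth[i, j]) tp <- tp + 1L
      else if (pred[i, j] && !truth[i, j]) fp <- fp + 1L
      else if (!pred[i, j] && truth[i, j]) fn <- fn + 1L
      else tn <- tn + 1L
    }
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

# linearly separable patch task: bright vs dark blocks with mild noise
separable_patch_set <- function(n_per_class = 100L, patch_size = 31L,
                                bright = 220, dark = 60, sd = 10,
                                seed = 1L) {
  withr::with_seed(seed, {
    mk <- function(level) {
      array(pmin(255, pmax(0, round(level +
        stats::rnorm(patch_size^2 * 3, 0, sd)))),
        c(patch_size, patch_size, 3L))
    }
    blocks <- c(purrr::map(seq_len(n_per_class), ~ mk(bright)),
                purrr::map(seq_len(n_per_class), ~ mk(dark)))
    flowerseg:::patch_set(tibble::tibble(
      image_id = rep(c("bright", "dark"), each = n_per_class),
      row = (patch_size + 1L) %/% 2L, col = (patch_size + 1L) %/% 2L,
      label = rep(c("positive", "negative"), each = n_per_class),
      block = blocks), patch_size = patch_size)
  })
}

# mock patch classifier: positive iff the patch's center-pixel luma > 128
center_luma_classifier <- function(blocks) {
  ctr <- (dim(blocks)[1] + 1L) %/% 2L
  l <- 0.299 * blocks[ctr, ctr, 1, ] + 0.587 * blocks[ctr, ctr, 2, ] +
    0.114 * blocks[ctr, ctr, 3, ]
  floor(l + 0.5) > 128
}

random_mask <- function(h, w, p = 0.5, provenance = "ground_truth") {
  binary_mask(matrix(stats::runif(h * w) < p, h, w), provenance)
}

small_scene <- function(seed = 9, h = 45, w = 64, n_flowers = 2,
                        n_distractors = 3, area = 150) {
  generate_scene(scene_spec(height = h, width = w, n_flowers = n_flowers,
                            n_distractors = n_distractors,
                            flower_area_mean = area, seed = seed))
}
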