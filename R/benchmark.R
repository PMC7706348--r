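#' End-to-end benchmark on synthetic canopy scenes
#'
#' Runs the whole method on a seeded family of generated scenes: builds a
#' patch training set from training scenes (flower patches) and flower-free
#' background scenes (which keep their bright distractors, so the classifier
#' learns to reject exactly the clutter that defeats pure thresholding),
#' trains the default compact network, then segments `n_scenes` fresh test
#' scenes with [run_pipeline()] and scores all three masks of each against
#' the generated ground truth.
#'
#' Defaults are sized for single-CPU runs: 12 flower + 4 background training
#' scenes (60 positive / 100 negative patches), up to 60 training epochs with
#' small minibatches, stride-3 sliding-window inference.
#'
#' @param n_scenes Number of test scenes.
#' @param seed Master seed; train scenes, background scenes, training and
#'   test scenes draw from independent named streams of it.
#' @param spec A [scene_spec()] describing the scene family (per-scene seeds
#'   are overridden).
#' @param n_train_scenes,n_background_scenes Training scene counts.
#' @param n_neg_per_image Negative patches per background scene.
#' @param stride Sliding-window stride used at test time.
#' @param train_cfg A [train_config()].
#' @return An object of class `flower_benchmark`: list with `results` (tibble
#'   of per-scene, per-mask scores), `medians` (per-mask medians), `fit` (the
#'   trained `flower_cnn_fit`), and the configuration used.
#' @export
run_flower_benchmark <- function(n_scenes = 20L, seed = 1L,
                                 spec = scene_spec(),
                                 n_train_scenes = 12L,
                                 n_background_scenes = 4L,
                                 n_neg_per_image = 25L,
                                 stride = 3L,
                                 train_cfg = train_config(
                                   batch_size = 10L, max_steps = 60L,
                                   plateau_patience = 8L, seed = seed)) {
  as_spec <- function(overrides) {
    s <- spec
    s[names(overrides)] <- overrides
    structure(s, class = "scene_spec")
  }
  train_scenes <- generate_benchmark(
    spec, n_train_scenes, seed = stream_seed(seed, "train-scenes"))$scenes
  bg_scenes <- generate_benchmark(
    as_spec(list(n_flowers = 0L)), n_background_scenes,
    seed = stream_seed(seed, "background-scenes"))$scenes
  patches <- scene_to_trainset(train_scenes, bg_scenes,
                               n_neg_per_image = n_neg_per_image,
                               seed = stream_seed(seed, "trainset"))
  fit <- train_cnn(NULL, patches, train_cfg)

  test <- generate_benchmark(spec, n_scenes,
                             seed = stream_seed(seed, "test-scenes"))
  results <- purrr::imap(test$scenes, function(sc, i) {
    bundle <- run_pipeline(fit, sc$image, stride = stride)
    dplyr::mutate(evaluate_bundle(bundle, sc$truth),
                  scene = test$manifest$scene[i], .before = 1L)
  })
  results <- dplyr::bind_rows(results)
  medians <- results |>
    dplyr::group_by(mask) |>
    dplyr::summarise(dplyr::across(c(recall, precision, f1, iou),
                                   ~ stats::median(.x, na.rm = TRUE)),
                     .groups = "drop")
  structure(list(results = results, medians = medians, fit = fit,
                 spec = spec, n_scenes = as.integer(n_scenes),
                 stride = as.integer(stride), seed = as.integer(seed)),
            class = "flower_benchmark")
}

#' @export
print.flower_benchmark <- function(x, ...) {
  cat(sprintf("<flower_benchmark> %d scenes (%s illumination), stride %d\n",
              x$n_scenes, x$spec$illumination, x$stride))
  print(x$medians)
  invisible(x)
}

#' @export
tidy.flower_benchmark <- function(x, ...) x$results

#' @export
glance.flower_benchmark <- function(x, ...) {
  tidyr::pivot_wider(x$medians, names_from = "mask",
                     values_from = c("recall", "precision", "f1", "iou"))
}
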