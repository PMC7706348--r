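#' Training recipe for the patch classifier
#'
#' Minibatch stochastic gradient descent with a momentum factor, Gaussian
#' weight initialization, and a step learning-rate schedule: when the
#' validation error rate has become stable — it has improved below its
#' starting value at least once and then stopped improving for
#' `plateau_patience` consecutive epochs — the learning rate is multiplied by
#' `lr_decay_factor` (10% of the current rate by default), and training stops
#' after `max_steps` epochs. The defaults are the recipe used throughout the package: batch
#' 100, momentum 0.9, init sd 0.01, initial rate 0.01, decay 0.1, 100 steps.
#'
#' @param batch_size Minibatch size.
#' @param momentum Momentum factor.
#' @param init_std Gaussian weight-initialization standard deviation.
#' @param lr_initial Initial learning rate.
#' @param lr_decay_factor Multiplicative decay, in (0, 1).
#' @param max_steps Maximum number of epochs.
#' @param plateau_patience Epochs without validation improvement before a
#'   learning-rate drop.
#' @param val_fraction Fraction of samples held out for validation, in (0, 1).
#' @param seed Integer seed driving initialization, the validation split and
#'   epoch shuffles.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 100L, momentum = 0.9, init_std = 0.01,
                         lr_initial = 0.01, lr_decay_factor = 0.1,
                         max_steps = 100L, plateau_patience = 5L,
                         val_fraction = 0.2, seed = 1L) {
  abort_if(lr_decay_factor <= 0 || lr_decay_factor >= 1,
           "`lr_decay_factor` must be in (0, 1)")
  abort_if(val_fraction <= 0 || val_fraction >= 1,
           "`val_fraction` must be in (0, 1)")
  abort_if(batch_size < 1, "`batch_size` must be >= 1")
  structure(list(batch_size = as.integer(batch_size), momentum = momentum,
                 init_std = init_std, lr_initial = lr_initial,
                 lr_decay_factor = lr_decay_factor,
                 max_steps = as.integer(max_steps),
                 plateau_patience = as.integer(plateau_patience),
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "train_config")
}

# stack patch blocks into a normalized (p, p, 3, N) array
patches_to_array <- function(blocks, p) {
  x <- array(as.numeric(unlist(blocks)), c(p, p, 3L, length(blocks)))
  x / 255
}

#' Train the patch classifier
#'
#' Softmax cross-entropy loss minimized by seeded minibatch SGD with
#' momentum; a seeded `val_fraction` of the samples is held out and its
#' misclassification rate drives the plateau learning-rate schedule (see
#' [train_config()]). Fully reproducible: the same network seed, data and
#' config give an identical training record.
#'
#' @param network A [build_network()] result, or `NULL` to build the default
#'   [net_config()] network from `cfg$seed` and `cfg$init_std`.
#' @param patches A `patch_set` containing both classes (see
#'   [build_positive_set()], [scene_to_trainset()]).
#' @param cfg A [train_config()].
#' @return An object of class `flower_cnn_fit`: list with the trained
#'   `network`, the per-epoch `record` tibble (`step`, `loss`, `val_error`,
#'   `lr`), and `train_config`. [generics::tidy()] returns the record;
#'   [generics::glance()] a one-row summary.
#' @export
train_cnn <- function(network = NULL, patches, cfg = train_config()) {
  stopifnot(inherits(patches, "patch_set"), inherits(cfg, "train_config"))
  if (is.null(network)) {
    network <- build_network(net_config(), seed = cfg$seed,
                             init_std = cfg$init_std)
  }
  p <- attr(patches, "patch_size")
  abort_if(p != network$cfg$input_size,
           sprintf("patch size %d does not match network input size %d",
                   p, network$cfg$input_size))
  lab <- patches$label
  abort_if(length(unique(lab)) < 2L,
           "training set must contain both classes")
  n <- nrow(patches)
  X <- patches_to_array(patches$block, p)
  y <- ifelse(lab == "positive", 2L, 1L)

  n_val <- max(1L, round(cfg$val_fraction * n))
  val_idx <- with_stream(cfg$seed, "val-split", sample.int(n, n_val))
  train_idx <- setdiff(seq_len(n), val_idx)
  abort_if(length(unique(y[train_idx])) < 2L,
           "training split lost a class; lower val_fraction or add samples")
  Xval <- X[, , , val_idx, drop = FALSE]
  yval <- y[val_idx]

  vel <- purrr::map(network$layers, function(ly) {
    if (is.null(ly$W)) NULL else list(dW = ly$W * 0, db = ly$b * 0)
  })
  lr <- cfg$lr_initial
  best_val <- Inf
  initial_val <- NA_real_
  stale <- 0L
  rec <- vector("list", cfg$max_steps)

  for (step in seq_len(cfg$max_steps)) {
    ord <- with_stream(cfg$seed, paste0("epoch-", step), sample(train_idx))
    losses <- c()
    for (start in seq(1L, length(ord), by = cfg$batch_size)) {
      bi <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
      fw <- net_forward(network, X[, , , bi, drop = FALSE], keep_cache = TRUE)
      losses <- c(losses, mean_ce_loss(fw$logits, y[bi]))
      grads <- net_backward(network, fw, y[bi])
      for (i in seq_along(network$layers)) {
        if (is.null(grads[[i]])) next
        vel[[i]]$dW <- cfg$momentum * vel[[i]]$dW - lr * grads[[i]]$dW
        vel[[i]]$db <- cfg$momentum * vel[[i]]$db - lr * grads[[i]]$db
        network$layers[[i]]$W <- network$layers[[i]]$W + vel[[i]]$dW
        network$layers[[i]]$b <- network$layers[[i]]$b + vel[[i]]$db
      }
    }
    val_pred <- max.col(t(net_forward(network, Xval)$logits),
                        ties.method = "first")
    val_err <- mean(val_pred != yval)
    rec[[step]] <- tibble::tibble(step = step, loss = mean(losses),
                                  val_error = val_err, lr = lr)
    if (is.na(initial_val)) initial_val <- val_err
    if (val_err < best_val - 1e-9) {
      best_val <- val_err
      stale <- 0L
    } else {
      stale <- stale + 1L
      # "stable" means settled after genuine progress: the rate is only
      # decayed once validation error has improved below its starting value,
      # so the schedule cannot starve the initial small-weight plateau
      if (stale >= cfg$plateau_patience && best_val < initial_val - 1e-9) {
        lr <- lr * cfg$lr_decay_factor
        stale <- 0L
      }
    }
  }
  structure(list(network = network, record = dplyr::bind_rows(rec),
                 train_config = cfg),
            class = "flower_cnn_fit")
}

#' @export
print.flower_cnn_fit <- function(x, ...) {
  last <- utils::tail(x$record, 1L)
  cat(sprintf("<flower_cnn_fit> %d epochs, final loss %.4f, val error %.3f\n",
              nrow(x$record), last$loss, last$val_error))
  invisible(x)
}

as_network <- function(x) {
  if (inherits(x, "flower_cnn_fit")) x$network
  else if (inherits(x, "flower_cnn")) x
  else stop("expected a flower_cnn or flower_cnn_fit", call. = FALSE)
}

# batched positive-class probabilities for an (p, p, 3, B) 8-bit array
predict_scores <- function(network, blocks) {
  net <- as_network(network)
  fw <- net_forward(net, blocks / 255)
  softmax_probs(fw$logits)[2L, ]
}

#' Classify a single patch
#'
#' Scores one `input_size x input_size x 3` 8-bit block: pixel values are
#' normalized to `[0, 1]` by dividing by 255, the two output channels are
#' soft-maxed, and the block is labeled positive when the positive-class
#' probability exceeds 0.5 (an exact tie resolves to negative).
#'
#' @param network A `flower_cnn` or `flower_cnn_fit`.
#' @param block An integer array `input_size x input_size x 3` in `[0, 255]`.
#' @return A list with `label` (`"positive"`/`"negative"`) and `score` (the
#'   positive-class probability).
#' @export
predict_patch <- function(network, block) {
  net <- as_network(network)
  p <- net$cfg$input_size
  abort_if(!identical(dim(block), c(p, p, 3L)) &&
             !identical(dim(block), as.integer(c(p, p, 3L))),
           sprintf("block must be %d x %d x 3", p, p))
  s <- predict_scores(net, array(as.numeric(block), c(p, p, 3L, 1L)))
  list(label = if (s > 0.5) "positive" else "negative", score = unname(s))
}

#' Save / load a model checkpoint
#'
#' Checkpoints are a single portable JSON file holding the architecture and
#' every named parameter array at full precision; writing is deterministic,
#' so identical models produce byte-identical files.
#'
#' @param network A `flower_cnn` or `flower_cnn_fit`.
#' @param path Checkpoint path (JSON).
#' @return `save_model()` returns `path` invisibly; `load_model()` the
#'   restored `flower_cnn`.
#' @export
save_model <- function(network, path) {
  net <- as_network(network)
  payload <- list(
    config = list(conv_blocks = net$cfg$conv_blocks,
                  fc_widths = net$cfg$fc_widths,
                  input_size = net$cfg$input_size),
    layers = purrr::map(net$layers, function(ly) {
      if (is.null(ly$W)) list(type = ly$type)
      else list(type = ly$type, dim = dim(ly$W), W = as.vector(ly$W), b = ly$b)
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  pl <- jsonlite::read_json(path, simplifyVector = FALSE)
  cfg <- net_config(
    conv_blocks = purrr::map(pl$config$conv_blocks,
                             ~ as.integer(unlist(.x))),
    fc_widths = as.integer(unlist(pl$config$fc_widths)),
    input_size = as.integer(pl$config$input_size))
  net <- build_network(cfg, seed = 0L, init_std = 0)
  stopifnot(length(net$layers) == length(pl$layers))
  for (i in seq_along(net$layers)) {
    if (is.null(net$layers[[i]]$W)) next
    ly <- pl$layers[[i]]
    d <- as.integer(unlist(ly$dim))
    net$layers[[i]]$W <- matrix(as.numeric(unlist(ly$W)), d[1], d[2])
    net$layers[[i]]$b <- as.numeric(unlist(ly$b))
  }
  net
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.flower_cnn_fit <- function(x, ...) x$record

#' @export
glance.flower_cnn_fit <- function(x, ...) {
  last <- utils::tail(x$record, 1L)
  tibble::tibble(epochs = nrow(x$record), final_loss = last$loss,
                 final_val_error = last$val_error, final_lr = last$lr,
                 best_val_error = min(x$record$val_error))
}
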