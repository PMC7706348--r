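#' Network architecture configuration
#'
#' Describes a small VGG-style patch classifier: stacks of 3x3
#' same-padding convolutions (each followed by ReLU) with 2x2/stride-2 max
#' pooling after each stack, then fully connected layers (ReLU between hidden
#' layers) ending in exactly 2 output channels — the two-class
#' (target / background) output. The default is deliberately compact (two
#' single-conv blocks, fc 64-2) so that CPU training on desk-scale data is
#' practical; the full VGG-16-sized topology is expressible by passing deeper
#' `conv_blocks` / wider `fc_widths`.
#'
#' @param conv_blocks List of `c(n_layers, n_channels)` pairs, one per block.
#' @param fc_widths Integer vector of fully connected widths; must end in 2.
#' @param input_size Odd patch edge length the network ingests (default 31).
#' @return An object of class `net_config`.
#' @export
#' @examples
#' net_config()                      # 31x31x3 -> 16 -> 32 -> fc 64 -> 2
net_config <- function(conv_blocks = list(c(1L, 16L), c(1L, 32L)),
                       fc_widths = c(64L, 2L),
                       input_size = 31L) {
  abort_if(length(fc_widths) < 1L || utils::tail(fc_widths, 1L) != 2L,
           "the last fully connected layer must have exactly 2 channels")
  abort_if(input_size %% 2 != 1, "`input_size` must be odd")
  s <- input_size
  for (i in seq_along(conv_blocks)) {
    blk <- conv_blocks[[i]]
    abort_if(length(blk) != 2L || any(blk < 1),
             "each conv block must be c(n_layers, n_channels)")
    s <- s %/% 2L
    abort_if(s < 1L, sprintf(
      "pooling after conv block %d exhausts the spatial extent", i))
  }
  structure(list(conv_blocks = conv_blocks,
                 fc_widths = as.integer(fc_widths),
                 input_size = as.integer(input_size),
                 final_extent = as.integer(s)),
            class = "net_config")
}

#' Build an initialized network
#'
#' Allocates parameter tensors for a [net_config()] and initializes every
#' weight from N(0, `init_std`^2) using the seeded generator; all biases start
#' at 0.
#'
#' @param cfg A [net_config()].
#' @param seed Integer seed; the same seed reproduces identical parameters.
#' @param init_std Standard deviation of the Gaussian weight initialization
#'   (default 0.01).
#' @return An object of class `flower_cnn`: list with `cfg` and `layers`.
#' @export
build_network <- function(cfg, seed = 1L, init_std = 0.01) {
  stopifnot(inherits(cfg, "net_config"))
  with_stream(seed, "init", {
    layers <- list()
    cin <- 3L
    for (blk in cfg$conv_blocks) {
      for (j in seq_len(blk[1])) {
        cout <- as.integer(blk[2])
        layers[[length(layers) + 1L]] <- list(
          type = "conv", cin = cin, cout = cout,
          W = matrix(stats::rnorm(9L * cin * cout, 0, init_std),
                     9L * cin, cout),
          b = numeric(cout))
        cin <- cout
      }
      layers[[length(layers) + 1L]] <- list(type = "pool")
    }
    win <- cfg$final_extent^2 * cin
    for (k in seq_along(cfg$fc_widths)) {
      wout <- cfg$fc_widths[k]
      layers[[length(layers) + 1L]] <- list(
        type = "fc", win = as.integer(win), wout = wout,
        W = matrix(stats::rnorm(win * wout, 0, init_std), win, wout),
        b = numeric(wout))
      win <- wout
    }
    structure(list(cfg = cfg, layers = layers), class = "flower_cnn")
  })
}

#' @export
print.flower_cnn <- function(x, ...) {
  np <- sum(purrr::map_dbl(x$layers,
                           ~ if (is.null(.x$W)) 0 else length(.x$W) + length(.x$b)))
  cat(sprintf("<flower_cnn> input %dx%dx3, %d layers, %s parameters\n",
              x$cfg$input_size, x$cfg$input_size, length(x$layers),
              format(np, big.mark = ",")))
  invisible(x)
}

# ---- im2col-based layer primitives (hand-rolled; BLAS does the heavy work) --

# gather indices mapping each (3x3 offset, output position) to the
# zero-padded (H+2)x(W+2) input; cached per spatial size.
.conv_idx_cache <- new.env(parent = emptyenv())

conv_gather_index <- function(h, w) {
  key <- paste0(h, "x", w)
  if (!is.null(.conv_idx_cache[[key]])) return(.conv_idx_cache[[key]])
  hp <- h + 2L
  oi <- rep(seq_len(h), times = w)        # output rows, column-major
  oj <- rep(seq_len(w), each = h)
  m <- matrix(0L, 9L, h * w)              # offsets vary fastest per position
  k <- 0L
  for (dj in 0:2) {
    for (di in 0:2) {
      k <- k + 1L
      m[k, ] <- (oi + di) + (oj + dj - 1L) * hp
    }
  }
  I <- as.integer(m)
  res <- list(I = I, groups = sort(unique(I)))
  .conv_idx_cache[[key]] <- res
  res
}

conv_forward <- function(x, W, b) {
  d <- dim(x)  # H, W, C, B
  h <- d[1]; w <- d[2]; cc <- d[3]; bb <- d[4]
  gi <- conv_gather_index(h, w)
  pad <- array(0, c(h + 2L, w + 2L, cc, bb))
  pad[2:(h + 1L), 2:(w + 1L), , ] <- x
  flat <- matrix(pad, (h + 2L) * (w + 2L), cc * bb)
  cols0 <- flat[gi$I, , drop = FALSE]                 # (9*HW) x (C*B)
  a <- aperm(array(cols0, c(9L, h * w, cc, bb)), c(1, 3, 2, 4))
  cols <- matrix(a, 9L * cc, h * w * bb)
  out <- crossprod(W, cols) + b                       # Cout x (HW*B)
  cout <- ncol(W)
  y <- array(aperm(array(out, c(cout, h * w, bb)), c(2, 1, 3)),
             c(h, w, cout, bb))
  list(y = y, cols = cols, dims = d)
}

conv_backward <- function(dy, cache, W) {
  d <- cache$dims
  h <- d[1]; w <- d[2]; cc <- d[3]; bb <- d[4]
  cout <- ncol(W)
  dout <- matrix(aperm(array(dy, c(h * w, cout, bb)), c(2, 1, 3)),
                 cout, h * w * bb)
  dW <- tcrossprod(cache$cols, dout)                  # (9C) x Cout
  db <- rowSums(dout)
  dcols <- W %*% dout                                 # (9C) x (HW*B)
  dcols0 <- matrix(aperm(array(dcols, c(9L, cc, h * w, bb)), c(1, 3, 2, 4)),
                   9L * h * w, cc * bb)
  gi <- conv_gather_index(h, w)
  rs <- rowsum(dcols0, group = gi$I, reorder = TRUE)
  dflat <- matrix(0, (h + 2L) * (w + 2L), cc * bb)
  dflat[gi$groups, ] <- rs
  dpad <- array(dflat, c(h + 2L, w + 2L, cc, bb))
  list(dx = dpad[2:(h + 1L), 2:(w + 1L), , , drop = FALSE], dW = dW, db = db)
}

pool_forward <- function(x) {
  d <- dim(x)
  hh <- d[1] %/% 2L; ww <- d[2] %/% 2L
  ri <- seq_len(2L * hh); ci <- seq_len(2L * ww)
  s <- list(x[ri[c(TRUE, FALSE)], ci[c(TRUE, FALSE)], , , drop = FALSE],
            x[ri[c(FALSE, TRUE)], ci[c(TRUE, FALSE)], , , drop = FALSE],
            x[ri[c(TRUE, FALSE)], ci[c(FALSE, TRUE)], , , drop = FALSE],
            x[ri[c(FALSE, TRUE)], ci[c(FALSE, TRUE)], , , drop = FALSE])
  m <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  list(y = m, slices = s, dims = d)
}

pool_backward <- function(dy, cache) {
  d <- cache$dims
  m <- pmax(cache$slices[[1]], cache$slices[[2]],
            cache$slices[[3]], cache$slices[[4]])
  dx <- array(0, d)
  hh <- dim(m)[1]; ww <- dim(m)[2]
  taken <- array(FALSE, dim(m))
  offs <- list(c(1L, 1L), c(2L, 1L), c(1L, 2L), c(2L, 2L))
  for (k in 1:4) {
    hit <- (cache$slices[[k]] == m) & !taken    # ties: first slice wins
    taken <- taken | hit
    ri <- seq(offs[[k]][1], by = 2L, length.out = hh)
    ci <- seq(offs[[k]][2], by = 2L, length.out = ww)
    dx[ri, ci, , ] <- dx[ri, ci, , , drop = FALSE] + dy * hit
  }
  dx
}

# full forward pass; X is (p, p, 3, B) in [0, 1]
net_forward <- function(net, X, keep_cache = FALSE) {
  caches <- if (keep_cache) vector("list", length(net$layers)) else NULL
  x <- X
  flat <- FALSE
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    if (ly$type == "conv") {
      cf <- conv_forward(x, ly$W, ly$b)
      relu_mask <- cf$y > 0
      x <- cf$y * relu_mask
      if (keep_cache) caches[[i]] <- list(cols = cf$cols, dims = cf$dims,
                                          relu = relu_mask)
    } else if (ly$type == "pool") {
      pf <- pool_forward(x)
      x <- pf$y
      if (keep_cache) caches[[i]] <- pf
    } else {
      if (!flat) {
        b <- dim(x)[4]
        x <- matrix(x, length(x) / b, b)
        flat <- TRUE
      }
      abort_if(nrow(x) != ly$win,
               sprintf("fc layer expects %d inputs, got %d", ly$win, nrow(x)))
      z <- crossprod(ly$W, x) + ly$b
      last <- i == length(net$layers)
      relu_mask <- if (last) NULL else z > 0
      if (keep_cache) caches[[i]] <- list(xin = x, relu = relu_mask)
      x <- if (last) z else z * relu_mask
    }
  }
  list(logits = x, caches = caches)   # logits: 2 x B
}

softmax_probs <- function(logits) {
  z <- sweep(logits, 2L, apply(logits, 2L, max))
  e <- exp(z)
  sweep(e, 2L, colSums(e), "/")
}

# backprop of mean softmax cross-entropy; y in {1, 2}; returns per-layer grads
net_backward <- function(net, fw, y) {
  bsz <- ncol(fw$logits)
  p <- softmax_probs(fw$logits)
  dz <- p
  dz[cbind(y, seq_len(bsz))] <- dz[cbind(y, seq_len(bsz))] - 1
  dz <- dz / bsz
  grads <- vector("list", length(net$layers))
  dx <- dz
  for (i in rev(seq_along(net$layers))) {
    ly <- net$layers[[i]]
    ca <- fw$caches[[i]]
    if (ly$type == "fc") {
      if (!is.null(ca$relu)) dx <- dx * ca$relu
      grads[[i]] <- list(dW = tcrossprod(ca$xin, dx), db = rowSums(dx))
      dx <- ly$W %*% dx
      # reshape back to the spatial map if the next layer down is conv/pool
      if (i > 1L && net$layers[[i - 1L]]$type != "fc") {
        below <- fw$caches[[i - 1L]]
        dd <- if (net$layers[[i - 1L]]$type == "pool") {
          d0 <- below$dims
          c(d0[1] %/% 2L, d0[2] %/% 2L, d0[3], d0[4])
        } else {
          c(below$dims[1], below$dims[2], ncol(net$layers[[i - 1L]]$W),
            below$dims[4])
        }
        dx <- array(dx, dd)
      }
    } else if (ly$type == "pool") {
      dx <- pool_backward(dx, ca)
    } else {
      dx <- dx * ca$relu
      cb <- conv_backward(dx, ca, ly$W)
      grads[[i]] <- list(dW = cb$dW, db = cb$db)
      dx <- cb$dx
    }
  }
  grads
}

mean_ce_loss <- function(logits, y) {
  p <- softmax_probs(logits)
  -mean(log(pmax(p[cbind(y, seq_len(ncol(logits)))], 1e-300)))
}
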