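#' SLICO-style superpixel oversegmentation
#'
#' k-means-style clustering of pixels in joint (L, a, b, row, col) space:
#' cluster centers are seeded on a regular grid at spacing
#' `S = sqrt(H * W / n_target)`, each center only competes for pixels within
#' a `2S x 2S` search window, and 10 assignment/update iterations are run.
#' In `"slico_adaptive"` mode (SLIC zero) each cluster's color-distance
#' normalizer adapts to the maximum color distance observed in that cluster,
#' making the compactness parameter-free; `"fixed"` uses a constant
#' compactness `m`. Afterwards connectivity is enforced: each label keeps its
#' largest 4-connected component and every orphan component is relabeled to
#' the largest adjacent segment, then labels are compacted to `0..n-1`. The
#' final segment count lands within about 20% of `n_target`.
#'
#' @param image An [rgb_image()].
#' @param n_target Desired number of superpixels (1..pixel count).
#' @param compactness_mode `"slico_adaptive"` (default) or `"fixed"`.
#' @param m Compactness used by `"fixed"` mode (and as the adaptive mode's
#'   starting value).
#' @param n_iter Assignment/update iterations.
#' @return An object of class `superpixel_map`: `labels` (`H x W` integer
#'   matrix of 0-based segment labels), `n_segments`, `image_id`.
#' @export
slic_segment <- function(image, n_target,
                         compactness_mode = c("slico_adaptive", "fixed"),
                         m = 10, n_iter = 10L) {
  stopifnot(inherits(image, "rgb_image"))
  compactness_mode <- match.arg(compactness_mode)
  h <- image$height; w <- image$width
  abort_if(!is_count(n_target) || n_target > h * w,
           sprintf("`n_target` must be a count <= %d pixels", h * w))

  lab <- pixel_lab(image)                       # (H*W) x 3
  S <- sqrt(h * w / n_target)
  nr <- max(1L, round(sqrt(n_target * h / w)))
  nc <- max(1L, round(n_target / nr))
  cy <- (seq_len(nr) - 0.5) * h / nr
  cx <- (seq_len(nc) - 0.5) * w / nc
  centers_pos <- cbind(rep(cy, times = nc), rep(cx, each = nr))
  k <- nrow(centers_pos)
  cidx <- round_half_up(centers_pos[, 1]) +
    (round_half_up(centers_pos[, 2]) - 1) * h
  centers_lab <- lab[cidx, , drop = FALSE]
  mk <- rep(m, k)

  rowv <- rep(seq_len(h), times = w)
  colv <- rep(seq_len(w), each = h)

  assign_mat <- NULL
  for (iter in seq_len(n_iter)) {
    best_d <- rep(Inf, h * w)
    assign_vec <- integer(h * w)
    for (j in seq_len(k)) {
      r0 <- max(1L, floor(centers_pos[j, 1] - S)); r1 <- min(h, ceiling(centers_pos[j, 1] + S))
      c0 <- max(1L, floor(centers_pos[j, 2] - S)); c1 <- min(w, ceiling(centers_pos[j, 2] + S))
      win <- as.vector(outer((r0:r1), (c0:c1 - 1L) * h, `+`))
      dc2 <- (lab[win, 1] - centers_lab[j, 1])^2 +
        (lab[win, 2] - centers_lab[j, 2])^2 +
        (lab[win, 3] - centers_lab[j, 3])^2
      ds2 <- (rowv[win] - centers_pos[j, 1])^2 +
        (colv[win] - centers_pos[j, 2])^2
      d <- dc2 / mk[j]^2 + ds2 / S^2
      upd <- d < best_d[win]
      best_d[win[upd]] <- d[upd]
      assign_vec[win[upd]] <- j
    }
    # stray pixels outside every window (possible with extreme n_target)
    if (any(assign_vec == 0L)) {
      miss <- which(assign_vec == 0L)
      dall <- outer(rowv[miss], centers_pos[, 1], `-`)^2 +
        outer(colv[miss], centers_pos[, 2], `-`)^2
      assign_vec[miss] <- max.col(-dall, ties.method = "first")
    }
    cnt <- tabulate(assign_vec, nbins = k)
    nz <- cnt > 0
    centers_pos[nz, 1] <- rowsum(rowv, assign_vec)[, 1] / cnt[nz]
    centers_pos[nz, 2] <- rowsum(colv, assign_vec)[, 1] / cnt[nz]
    newlab <- rowsum(lab, assign_vec) / cnt[nz]
    centers_lab[nz, ] <- newlab
    if (compactness_mode == "slico_adaptive") {
      dc2 <- (lab[, 1] - centers_lab[assign_vec, 1])^2 +
        (lab[, 2] - centers_lab[assign_vec, 2])^2 +
        (lab[, 3] - centers_lab[assign_vec, 3])^2
      mnew <- sqrt(tapply(dc2, assign_vec, max))
      mk[as.integer(names(mnew))] <- pmax(mnew, 1)
    }
    assign_mat <- matrix(assign_vec, h, w)
  }

  labels <- enforce_connectivity(assign_mat)
  structure(list(labels = labels,
                 n_segments = max(labels) + 1L,
                 image_id = image$id),
            class = "superpixel_map")
}

#' @export
print.superpixel_map <- function(x, ...) {
  cat(sprintf("<superpixel_map '%s'> %d x %d, %d segments\n",
              x$image_id, nrow(x$labels), ncol(x$labels), x$n_segments))
  invisible(x)
}

# sRGB -> CIE Lab rows for every pixel (column-major)
pixel_lab <- function(image) {
  px <- image$pixels
  grDevices::convertColor(cbind(as.vector(px[, , 1]), as.vector(px[, , 2]),
                                as.vector(px[, , 3])) / 255,
                          from = "sRGB", to = "Lab")
}

# 4-connected component labeling of equal-label regions (two-pass union-find)
connected_components <- function(labels) {
  h <- nrow(labels); w <- ncol(labels)
  n <- h * w
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  lv <- as.vector(labels)
  # vertical neighbors
  a <- which(rep(c(rep(TRUE, h - 1L), FALSE), w))   # all i with i+1 in same col
  for (i in a[lv[a] == lv[a + 1L]]) {
    ra <- find(i); rb <- find(i + 1L)
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  b <- seq_len(n - h)                                # i and i+h horizontal
  for (i in b[lv[b] == lv[b + h]]) {
    ra <- find(i); rb <- find(i + h)
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  matrix(match(roots, sort(unique(roots))), h, w)
}

# keep each label's largest component; relabel orphans to the largest
# adjacent segment; compact labels to 0..n-1
enforce_connectivity <- function(assign_mat) {
  h <- nrow(assign_mat); w <- ncol(assign_mat)
  comp <- connected_components(assign_mat)
  lv <- as.vector(assign_mat)
  cv <- as.vector(comp)
  sizes <- tabulate(cv)
  # main component per label = largest component carrying that label
  comp_label <- lv[match(seq_along(sizes), cv)]
  keep <- logical(length(sizes))
  for (lbl in unique(lv)) {
    comps <- which(comp_label == lbl)
    keep[comps[which.max(sizes[comps])]] <- TRUE
  }
  orphans <- which(!keep)
  if (length(orphans) > 0L) {
    ord <- orphans[order(sizes[orphans])]
    for (oc in ord) {
      px <- which(cv == oc)
      nb <- c(px[px %% h != 1L] - 1L, px[px %% h != 0L] + 1L,
              px[px > h] - h, px[px <= (w - 1L) * h] + h)
      nb <- nb[cv[nb] != oc]
      if (length(nb) == 0L) {       # isolated; nothing adjacent to merge into
        keep[oc] <- TRUE
        next
      }
      nb_lab <- lv[nb]
      areas <- tabulate(lv + 1L)
      tgt <- unique(nb_lab)[which.max(areas[unique(nb_lab) + 1L])]
      lv[px] <- tgt
      cv[px] <- cv[nb[match(tgt, nb_lab)]]
    }
  }
  matrix(match(lv, sort(unique(lv))) - 1L, h, w)
}

#' Merge superpixels into a target number of regions
#'
#' Greedy agglomeration on the region adjacency graph: at every step the
#' 4-adjacent pair of regions with the smallest Euclidean distance between
#' mean Lab colors is merged (ties broken by the smaller label pair), until
#' exactly `n_regions_target` regions remain. Region centers are the area
#' centroids rounded to the nearest pixel, snapped onto the region itself
#' when the centroid of a non-convex region falls outside it — so a patch
#' centered there always overlaps the region.
#'
#' @param spx A [slic_segment()] result.
#' @param image The source [rgb_image()].
#' @param n_regions_target Number of merged regions (<= `spx$n_segments`).
#' @return An object of class `merged_region_set`: `region_labels` (`H x W`
#'   0-based integer matrix), `n_regions`, and `centers` (tibble `region`,
#'   `row`, `col`, 1-based).
#' @export
merge_regions <- function(spx, image, n_regions_target) {
  stopifnot(inherits(spx, "superpixel_map"), inherits(image, "rgb_image"))
  abort_if(!is_count(n_regions_target) ||
             n_regions_target > spx$n_segments,
           sprintf("`n_regions_target` must be a count <= %d segments",
                   spx$n_segments))
  h <- nrow(spx$labels); w <- ncol(spx$labels)
  lv <- as.vector(spx$labels) + 1L          # 1-based internally
  k <- spx$n_segments
  lab <- pixel_lab(image)
  area <- tabulate(lv, nbins = k)
  colsum <- rowsum(lab, lv)                 # k x 3

  # adjacency sets from 4-neighbor pairs
  pairs <- rbind(
    cbind(lv[seq_len(h * w - 1L)][seq_len(h * w - 1L) %% h != 0L],
          lv[-seq_len(1L)][seq_len(h * w - 1L) %% h != 0L]),
    cbind(lv[seq_len(h * w - h)], lv[-seq_len(h)]))
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  pairs <- unique(t(apply(pairs, 1L, sort)))
  adj <- purrr::map(seq_len(k), ~ integer(0))
  for (i in seq_len(nrow(pairs))) {
    adj[[pairs[i, 1]]] <- c(adj[[pairs[i, 1]]], pairs[i, 2])
    adj[[pairs[i, 2]]] <- c(adj[[pairs[i, 2]]], pairs[i, 1])
  }
  adj <- purrr::map(adj, unique)

  alive <- rep(TRUE, k)
  owner <- seq_len(k)                        # superpixel -> current region
  n_regions <- k
  while (n_regions > n_regions_target) {
    live <- which(alive)
    mean_col <- colsum[live, , drop = FALSE] / area[live]
    best <- NULL; best_d <- Inf
    for (ii in seq_along(live)) {
      i <- live[ii]
      nbrs <- adj[[i]]
      nbrs <- nbrs[nbrs > i]
      if (length(nbrs) == 0L) next
      mi <- mean_col[ii, ]
      for (j in sort(nbrs)) {
        mj <- colsum[j, ] / area[j]
        d <- sum((mi - mj)^2)
        if (d < best_d - 1e-12) {            # ties: keep earliest (i, j)
          best_d <- d
          best <- c(i, j)
        }
      }
    }
    abort_if(is.null(best), sprintf(
      "adjacency exhausted: cannot merge below %d disconnected regions",
      n_regions))
    i <- best[1]; j <- best[2]
    area[i] <- area[i] + area[j]
    colsum[i, ] <- colsum[i, ] + colsum[j, ]
    adj[[i]] <- setdiff(unique(c(adj[[i]], adj[[j]])), c(i, j))
    for (q in adj[[j]]) {
      adj[[q]] <- unique(c(setdiff(adj[[q]], j), i))
      adj[[q]] <- setdiff(adj[[q]], q)
    }
    adj[[j]] <- integer(0)
    alive[j] <- FALSE
    owner[owner == j] <- i
    n_regions <- n_regions - 1L
  }

  new_id <- match(owner, sort(unique(owner)))  # 1..n_regions
  region_v <- new_id[lv]
  region_labels <- matrix(region_v - 1L, h, w)

  rowv <- rep(seq_len(h), times = w)
  colv <- rep(seq_len(w), each = h)
  cnt <- tabulate(region_v, nbins = n_regions)
  cy <- rowsum(rowv, region_v)[, 1] / cnt
  cx <- rowsum(colv, region_v)[, 1] / cnt
  crow <- round_half_up(cy); ccol <- round_half_up(cx)
  for (rg in seq_len(n_regions)) {
    if (region_v[crow[rg] + (ccol[rg] - 1L) * h] != rg) {
      px <- which(region_v == rg)
      d2 <- (rowv[px] - cy[rg])^2 + (colv[px] - cx[rg])^2
      pick <- px[which.min(d2)]
      crow[rg] <- rowv[pick]; ccol[rg] <- colv[pick]
    }
  }
  structure(list(region_labels = region_labels,
                 n_regions = n_regions,
                 centers = tibble::tibble(region = seq_len(n_regions) - 1L,
                                          row = as.integer(crow),
                                          col = as.integer(ccol))),
            class = "merged_region_set")
}

#' @export
print.merged_region_set <- function(x, ...) {
  cat(sprintf("<merged_region_set> %d regions over %d x %d\n",
              x$n_regions, nrow(x$region_labels), ncol(x$region_labels)))
  invisible(x)
}

#' Superpixel-level ground truth from point marks
#'
#' Builds a ground-truth mask the way study masks are made from visual
#' interpretation: every superpixel containing at least one marked target
#' point is set to foreground whole, the rest to background.
#'
#' @param spx A [slic_segment()] result.
#' @param flower_marks Data frame or 2-column matrix of 1-based `(row, col)`
#'   marks; may be empty (all-background mask).
#' @return A [binary_mask()] with provenance `"ground_truth"`, a union of
#'   whole superpixels.
#' @export
build_ground_truth <- function(spx, flower_marks) {
  stopifnot(inherits(spx, "superpixel_map"))
  h <- nrow(spx$labels); w <- ncol(spx$labels)
  fm <- as.data.frame(flower_marks)
  if (nrow(fm) == 0L) {
    return(binary_mask(matrix(FALSE, h, w), "ground_truth"))
  }
  names(fm)[1:2] <- c("row", "col")
  abort_if(any(fm$row < 1 | fm$row > h | fm$col < 1 | fm$col > w),
           "flower marks out of image bounds")
  hit <- unique(spx$labels[cbind(fm$row, fm$col)])
  binary_mask(matrix(as.vector(spx$labels) %in% hit, h, w), "ground_truth")
}
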