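partition_ok <- function(spx) {
  lv <- as.vector(spx$labels)
  identical(sort(unique(lv)), 0:(spx$n_segments - 1L))
}

connected_ok <- function(spx) {
  comp <- flowerseg:::connected_components(spx$labels)
  max(comp) == spx$n_segments
}

test_that("slic produces a gap-free 4-connected partition near the target count", {
  img <- small_scene(seed = 41, h = 100, w = 100, n_flowers = 3)$image
  spx <- slic_segment(img, 25)
  expect_true(partition_ok(spx))
  expect_true(connected_ok(spx))
  expect_gte(spx$n_segments, 20)
  expect_lte(spx$n_segments, 30)

  # property over random images
  withr::with_seed(42, {
    for (i in 1:3) {
      px <- array(sample(0:255, 60 * 60 * 3, TRUE), c(60, 60, 3))
      s <- slic_segment(rgb_image(px), 16)
      expect_true(partition_ok(s))
      expect_true(connected_ok(s))
    }
  })

  one <- slic_segment(img, 1)
  expect_identical(one$n_segments, 1L)
  expect_true(all(one$labels == 0L))
  expect_error(slic_segment(img, 100 * 100 + 1), "count")
})

test_that("slic segments adhere to a strong color boundary", {
  px <- array(0L, c(64, 64, 3))
  px[, 1:32, ] <- 60L
  px[, 33:64, ] <- 200L
  bip <- rgb_image(px, "bipartite")
  s <- slic_segment(bip, 2)
  expect_identical(s$n_segments, 2L)
  for (lbl in 0:1) {
    vals <- unique(px[, , 1][s$labels == lbl])
    expect_length(vals, 1L)   # no segment straddles the boundary
  }
})

test_that("region merging reaches the exact target without splitting superpixels", {
  sc <- small_scene(seed = 43, h = 80, w = 80, n_flowers = 2, area = 250)
  spx <- slic_segment(sc$image, 60)

  # identity merge: centers are the superpixel centroids
  ident <- merge_regions(spx, sc$image, spx$n_segments)
  expect_identical(ident$n_regions, spx$n_segments)
  expect_identical(sort(unique(as.vector(ident$region_labels))),
                   0:(spx$n_segments - 1L))

  # the 10:1 reduction ratio used for sample-region construction
  tgt <- spx$n_segments %/% 10L
  mr <- merge_regions(spx, sc$image, tgt)
  expect_identical(mr$n_regions, tgt)
  cross <- table(spx$labels, mr$region_labels)
  expect_true(all(rowSums(cross > 0) == 1))   # regions = unions of superpixels
  expect_identical(nrow(mr$centers), tgt)
  expect_true(all(mr$region_labels[cbind(mr$centers$row, mr$centers$col)] ==
                    mr$centers$region))

  expect_error(merge_regions(spx, sc$image, spx$n_segments + 1L), "count")
})

test_that("merging a two-tone image to two regions recovers the two colors", {
  px <- array(0L, c(60, 60, 3))
  px[, 1:30, ] <- 50L
  px[, 31:60, ] <- 210L
  img <- rgb_image(px, "two-tone")
  spx <- slic_segment(img, 10)
  mr <- merge_regions(spx, img, 2)
  expect_identical(mr$n_regions, 2L)
  for (rg in 0:1) {
    expect_length(unique(px[, , 1][mr$region_labels == rg]), 1L)
  }
})

test_that("superpixel ground truth is a union of whole segments", {
  img <- small_scene(seed = 44, h = 60, w = 60, n_flowers = 1, area = 120)$image
  spx <- slic_segment(img, 30)

  # one mark selects exactly its segment
  lbl <- spx$labels[10, 10]
  gt1 <- build_ground_truth(spx, data.frame(row = 10, col = 10))
  expect_identical(gt1$values, spx$labels == lbl)
  expect_identical(gt1$provenance, "ground_truth")

  # a second mark in the same segment changes nothing
  px2 <- which(spx$labels == lbl, arr.ind = TRUE)[2, ]
  gt2 <- build_ground_truth(spx, rbind(c(10, 10), px2))
  expect_identical(gt2$values, gt1$values)

  # marks in k distinct segments select the union of their areas
  marks <- data.frame(row = c(5, 30, 55), col = c(5, 30, 55))
  hit <- unique(spx$labels[cbind(marks$row, marks$col)])
  gtk <- build_ground_truth(spx, marks)
  expect_identical(sum(gtk$values), sum(spx$labels %in% hit))
  per_segment_uniform <- tapply(as.vector(gtk$values), as.vector(spx$labels),
                                function(v) all(v) || all(!v))
  expect_true(all(per_segment_uniform))

  # empty mark list: all-background, no error
  expect_false(any(build_ground_truth(spx, data.frame())$values))
  expect_error(build_ground_truth(spx, data.frame(row = 0, col = 1)),
               "bounds")
})
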