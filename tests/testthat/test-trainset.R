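test_that("patch extraction reflects at borders and has the exact window size", {
  flat <- rgb_image(array(77L, c(40, 40, 3)))
  p <- extract_patch(flat, c(20, 20), 31)
  expect_true(all(p == 77L))
  expect_identical(dim(p), c(31L, 31L, 3L))
  expect_equal(length(p) / 3, 961)

  img <- small_scene(seed = 51)$image
  corner <- extract_patch(img, c(1, 1), 31)
  ri <- flowerseg:::reflect_index(-14:16, img$height)
  ci <- flowerseg:::reflect_index(-14:16, img$width)
  expect_identical(corner, img$pixels[ri, ci, , drop = FALSE])
  # top rows mirror the rows below the edge: patch row k equals patch row 32-k
  expect_identical(corner[1:15, , , drop = FALSE],
                   corner[31:17, , , drop = FALSE])

  expect_error(extract_patch(img, c(0, 5)), "out of bounds")
  expect_error(extract_patch(img, c(5, 5), 30), "odd")
})

test_that("positive sets have one sample per center, duplicates included", {
  imgs <- purrr::map(1:3, ~ small_scene(seed = 60 + .x)$image)
  centers <- purrr::map(1:3, ~ data.frame(row = seq(20, 36, 4),
                                          col = seq(20, 36, 4)))
  ps <- build_positive_set(imgs, centers)
  expect_identical(nrow(ps), 15L)
  expect_true(all(ps$label == "positive"))

  dup <- build_positive_set(imgs[1], list(data.frame(row = c(20, 20),
                                                     col = c(20, 20))))
  expect_identical(nrow(dup), 2L)
  expect_identical(dup$block[[1]], dup$block[[2]])

  expect_error(build_positive_set(imgs, purrr::map(1:3, ~ data.frame())),
               "no positive centers")
})

test_that("negative sampling is seeded, without replacement, and scales to 18000", {
  bgs <- purrr::map(1:2, ~ generate_scene(scene_spec(
    height = 64, width = 64, n_flowers = 0, n_distractors = 6,
    seed = 70 + .x))$image)
  a <- build_negative_set(bgs, 50, patch_size = 11, seed = 5)
  b <- build_negative_set(bgs, 50, patch_size = 11, seed = 5)
  expect_identical(a$row, b$row)
  expect_identical(a$col, b$col)
  expect_identical(a$block, b$block)
  expect_false(identical(a$row,
                         build_negative_set(bgs, 50, 11, seed = 6)$row))
  # without replacement within an image
  expect_false(any(duplicated(a[a$image_id == bgs[[1]]$id,
                                c("row", "col")])))

  # 12 background images x 1500 draws = 18000 negatives
  twelve <- purrr::map(1:12, ~ generate_scene(scene_spec(
    height = 64, width = 64, n_flowers = 0, n_distractors = 4,
    seed = 80 + .x))$image)
  big <- build_negative_set(twelve, 1500, patch_size = 5, seed = 1)
  expect_identical(nrow(big), 18000L)

  expect_identical(nrow(build_negative_set(bgs, 0, 11, seed = 1)), 0L)
  expect_error(build_negative_set(bgs, 64 * 64 + 1, 11, seed = 1), "exceeds")
})

test_that("flower-centered patches are brighter than the scene background", {
  sc <- generate_scene(scene_spec(seed = 55))
  ps <- build_positive_set(list(sc$image), list(sc$flower_centers))
  bg_mean <- mean(to_grayscale(sc$image)[!sc$truth$values])
  block_lumas <- purrr::map_dbl(ps$block, function(b) {
    mean(0.299 * b[, , 1] + 0.587 * b[, , 2] + 0.114 * b[, , 3])
  })
  expect_true(all(block_lumas > bg_mean))
})

test_that("patch sets round-trip through disk bit-exactly", {
  sc <- generate_scene(scene_spec(seed = 56))
  bg <- generate_scene(scene_spec(seed = 57, n_flowers = 0))
  ps <- scene_to_trainset(list(sc), list(bg), n_neg_per_image = 10, seed = 2)
  expect_identical(sum(ps$label == "positive"), nrow(sc$flower_centers))
  expect_identical(sum(ps$label == "negative"), 10L)
  # the positive pool and negative pool come from different images
  expect_length(intersect(ps$image_id[ps$label == "positive"],
                          ps$image_id[ps$label == "negative"]), 0L)

  d <- withr::local_tempdir()
  write_patch_set(ps, d)
  back <- read_patch_set(d)
  expect_identical(back$block, ps$block)
  expect_identical(back$label, ps$label)
  expect_identical(back$row, ps$row)
})
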