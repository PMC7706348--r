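test_that("scenes are fully determined by their seed", {
  a <- generate_scene(scene_spec(seed = 71))
  b <- generate_scene(scene_spec(seed = 71))
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth$values, b$truth$values)
  expect_identical(a$flower_centers, b$flower_centers)
  c <- generate_scene(scene_spec(seed = 72))
  expect_false(identical(a$image$pixels, c$image$pixels))
})

test_that("ground truth hits the area budget and centers lie on flowers", {
  for (seed in 73:77) {
    sc <- generate_scene(scene_spec(seed = seed))   # 5 flowers x 900 px^2
    n_true <- sum(sc$truth$values)
    expect_gte(n_true, 3150)
    expect_lte(n_true, 5850)
    expect_identical(nrow(sc$flower_centers), 5L)
    expect_true(all(sc$truth$values[cbind(sc$flower_centers$row,
                                          sc$flower_centers$col)]))
  }
  empty <- generate_scene(scene_spec(seed = 78, n_flowers = 0,
                                     n_distractors = 0))
  expect_false(any(empty$truth$values))
})

test_that("flower/background luma margins hold under both illuminations", {
  for (seed in 79:81) {
    soft <- generate_scene(scene_spec(seed = seed))
    g <- to_grayscale(soft$image)
    margin_soft <- mean(g[soft$truth$values]) - mean(g[!soft$truth$values])
    expect_gte(margin_soft, 60)

    hard <- generate_scene(scene_spec(seed = seed, illumination = "intense"))
    gh <- to_grayscale(hard$image)
    margin_hard <- mean(gh[hard$truth$values]) - mean(gh[!hard$truth$values])
    expect_gte(margin_hard, 20)
    expect_lt(margin_hard, margin_soft)
  }
})

test_that("distractors are thresholding foreground in most scenes", {
  hits <- purrr::map_lgl(82:91, function(seed) {
    sc <- generate_scene(scene_spec(seed = seed))
    m <- binarize_image(sc$image)
    fp <- m$values & !sc$truth$values
    # bright non-flower pixels leak through, and they are genuinely bright
    sum(fp) > 0 && mean(to_grayscale(sc$image)[fp]) > 180
  })
  expect_gte(mean(hits), 0.8)
})

test_that("infeasible specs are rejected with the violated bound named", {
  expect_error(scene_spec(height = 64, width = 64, n_flowers = 5,
                          flower_area_mean = 900),
               "30%")
  expect_error(scene_spec(distractor_area_range = c(10, 80)), "50")
  expect_error(scene_spec(perspective_squash = 0), "perspective_squash")
})

test_that("benchmark families are written to disk with an accurate manifest", {
  d <- withr::local_tempdir()
  bm <- generate_benchmark(scene_spec(), 6, seed = 100, dir = d)
  expect_length(bm$scenes, 6L)
  expect_identical(nrow(bm$manifest), 6L)
  expect_true(all(file.exists(bm$manifest$image_path)))
  expect_true(all(file.exists(bm$manifest$truth_path)))
  expect_identical(bm$manifest$truth_px,
                   purrr::map_int(bm$scenes, ~ sum(.x$truth$values)))

  # disjoint seed ranges never repeat a scene
  other <- generate_benchmark(scene_spec(), 6, seed = 200)
  h1 <- purrr::map_chr(bm$scenes,
                       ~ paste(utils::head(.x$image$pixels, 50), collapse = ","))
  h2 <- purrr::map_chr(other$scenes,
                       ~ paste(utils::head(.x$image$pixels, 50), collapse = ","))
  expect_length(intersect(h1, h2), 0L)

  # the family is non-degenerate: flower coverage varies across scenes
  fr <- purrr::map_dbl(bm$scenes, ~ mean(.x$truth$values))
  expect_gt(stats::var(fr), 0)
})

test_that("scene-derived training sets have the advertised composition", {
  scenes <- purrr::map(101:103, ~ generate_scene(scene_spec(seed = .x)))
  bgs <- purrr::map(104:105, ~ generate_scene(scene_spec(seed = .x,
                                                         n_flowers = 0)))
  ps <- scene_to_trainset(scenes, bgs, n_neg_per_image = 20, seed = 3)
  expect_identical(sum(ps$label == "positive"), 15L)
  expect_identical(sum(ps$label == "negative"), 40L)

  ps2 <- scene_to_trainset(scenes, bgs, n_neg_per_image = 20, seed = 3)
  expect_identical(ps$block, ps2$block)
  expect_identical(ps$row, ps2$row)

  expect_error(scene_to_trainset(scenes, scenes, 5, seed = 1),
               "n_flowers = 0")
})
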