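test_that("confusion counts match the explicit per-pixel tally", {
  withr::with_seed(61, {
    for (i in 1:20) {
      p <- random_mask(8, 8, runif(1))
      g <- random_mask(8, 8, runif(1))
      cc <- confusion(p, g)
      oracle <- loop_confusion(p$values, g$values)
      expect_identical(as.list(cc), oracle)
      # swapping arguments swaps fp and fn only
      sw <- confusion(g, p)
      expect_identical(sw$tp, cc$tp)
      expect_identical(sw$tn, cc$tn)
      expect_identical(sw$fp, cc$fn)
      expect_identical(sw$fn, cc$fp)
    }
  })
  p <- binary_mask(matrix(c(rep(TRUE, 5), rep(FALSE, 15)), 4, 5))
  expect_identical(as.list(confusion(p, p)),
                   list(tp = 5L, fp = 0L, fn = 0L, tn = 15L))
  np <- binary_mask(!p$values)
  expect_identical(confusion(p, np)$tp, 0L)
  expect_identical(confusion(p, np)$tn, 0L)
  expect_error(confusion(p, binary_mask(matrix(TRUE, 5, 4))),
               "different shapes")
})

test_that("scores follow the four formulas and the degenerate conventions", {
  s <- score_counts(data.frame(tp = 6, fp = 2, fn = 3, tn = 9))
  expect_equal(s$recall, 2 / 3)
  expect_equal(s$precision, 0.75)
  expect_equal(s$f1, 12 / 17)
  expect_equal(s$iou, 6 / 11)

  empty <- score_counts(data.frame(tp = 0, fp = 0, fn = 0, tn = 10))
  expect_equal(empty$f1, 1)
  expect_equal(empty$iou, 1)
  expect_true(is.na(empty$recall))
  expect_true(is.na(empty$precision))

  zero <- score_counts(data.frame(tp = 0, fp = 3, fn = 2, tn = 5))
  expect_equal(zero$recall, 0)
  expect_equal(zero$precision, 0)
  expect_equal(zero$f1, 0)
  expect_equal(zero$iou, 0)

  expect_error(score_counts(data.frame(tp = -1, fp = 0, fn = 0, tn = 0)),
               "non-negative")
})

test_that("f1/iou identities and scale invariance hold over random counts", {
  withr::with_seed(62, {
    counts <- data.frame(tp = sample(0:500, 300, TRUE),
                         fp = sample(0:500, 300, TRUE),
                         fn = sample(0:500, 300, TRUE),
                         tn = sample(0:500, 300, TRUE))
    s <- score_counts(counts)
    def <- !is.na(s$f1) & !is.na(s$iou)
    expect_equal(s$f1[def], (2 * s$tp / (2 * s$tp + s$fp + s$fn))[def])
    expect_equal(s$iou[def], (s$tp / (s$tp + s$fp + s$fn))[def])
    expect_equal(s$iou[def], (s$f1 / (2 - s$f1))[def])
    expect_true(all(s$iou[def] <= s$f1[def] + 1e-12))
    eq <- def & (s$iou == s$f1)
    expect_true(all(s$f1[eq] %in% c(0, 1)))

    k <- 7
    sk <- score_counts(counts * k)
    expect_equal(sk$recall, s$recall)
    expect_equal(sk$precision, s$precision)
    expect_equal(sk$f1, s$f1)
    expect_equal(sk$iou, s$iou)
  })
})

test_that("bundle evaluation reports one row per mask, reproducibly", {
  sc <- small_scene(seed = 13)
  bundle <- run_pipeline(center_luma_classifier, sc$image, stride = 2,
                         patch_size = 31)
  ev <- evaluate_bundle(bundle, sc$truth)
  expect_identical(ev$mask, c("binarization", "cnn", "combined"))

  # truth equal to a mask scores that mask perfectly
  self <- evaluate_bundle(bundle, binary_mask(bundle$combined_mask$values))
  expect_equal(self$f1[self$mask == "combined"], 1)
  expect_equal(self$iou[self$mask == "combined"], 1)

  ev2 <- evaluate_bundle(run_pipeline(center_luma_classifier, sc$image,
                                      stride = 2, patch_size = 31),
                         sc$truth)
  expect_identical(ev, ev2)

  f <- withr::local_tempfile(fileext = ".json")
  write_report(ev, f)
  expect_true(jsonlite::validate(paste(readLines(f), collapse = "")))
})
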