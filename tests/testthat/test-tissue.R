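test_that("Otsu finds a threshold between two levels", {
  img <- array(0, c(50, 50, 3))
  img[, , ] <- 200
  img[1:20, , ] <- 50  # 40% dark, 60% light
  out <- otsu_baseline(rgb_image(img))
  thr <- attr(out, "threshold")
  # the cut separates the two levels: dark class at/below, light above
  expect_gte(thr, 50)
  expect_lt(thr, 200)
  # exhaustive-search oracle over the gray histogram
  g <- round(stclean:::to_gray(rgb_image(img)))
  between <- vapply(0:254, function(t) {
    w0 <- sum(g <= t); w1 <- sum(g > t)
    if (w0 == 0 || w1 == 0) return(-1)
    w0 * w1 * (mean(g[g <= t]) - mean(g[g > t]))^2
  }, numeric(1))
  expect_identical(thr, as.numeric(which.max(between) - 1L))
  # the darker (stained) class is foreground
  expect_identical(sum(out), 20L * 50L)

  expect_warning(o2 <- otsu_baseline(rgb_image(array(128, c(10, 10, 3)))),
                 "constant")
  expect_identical(sum(o2), 0L)

  # inversion flips the classes
  inv <- rgb_image(255 - img)
  oi <- otsu_baseline(inv)
  expect_equal(as.matrix(oi), 1L - as.matrix(out), ignore_attr = TRUE)
})

test_that("RGBA blending copies RGB and maps probability to alpha", {
  img <- rgb_image(array(runif(20 * 20 * 3) * 255, c(20, 20, 3)))
  p1 <- probability_mask(matrix(1, 20, 20))
  b1 <- blend_rgba(img, p1)
  expect_identical(b1[, , 1:3], unclass(img)[, , 1:3])
  expect_true(all(b1[, , 4] == 255))
  expect_true(all(blend_rgba(img, probability_mask(
    matrix(0, 20, 20)))[, , 4] == 0))
  expect_true(all(blend_rgba(img, probability_mask(
    matrix(0.5, 20, 20)))[, , 4] == 128))
})

test_that("tissue configs carry the documented working sizes", {
  cfg <- tissue_config()
  expect_identical(cfg$working_size, 320L)
  expect_identical(cfg$small_working_size, 1000L)
  expect_identical(cfg$small_trigger, 100L)
})

test_that("detection output matches input dims and triggers the second pass", {
  # a deliberately tiny random-weight model is enough to exercise the
  # resolution plumbing; accuracy is covered by the acceptance suite
  set.seed(17)
  corpus <- list(generate_sample(small_spec(seed = 71, overlap = 0)))
  model <- fit_tissue_net(corpus, "compact", working_size = 64L,
                          epochs = 1L, seed = 2)
  img <- generate_sample(small_spec(seed = 72, overlap = 0))$image
  res <- detect_tissue(img, model,
                       tissue_config(working_size = 64L,
                                     small_working_size = 96L,
                                     variant = "compact"))
  expect_identical(dim(res$prob), dim(img)[1:2])
  expect_identical(dim(res$blend), c(dim(img)[1:2], 4L))
  expect_true(all(res$prob >= 0 & res$prob <= 1))

  # force a deterministic all-foreground prediction (zero weights, positive
  # head bias -> sigmoid(1) everywhere) so the bounding box is the full
  # slide; a trigger above the slide size must then start the second pass
  det_model <- model
  for (nm in names(det_model$params)) {
    det_model$params[[nm]]$W[] <- 0
    det_model$params[[nm]]$b[] <- 0
  }
  det_model$params$head$b[] <- 1
  expect_message(
    res2 <- detect_tissue(img, det_model,
                          tissue_config(working_size = 64L,
                                        small_working_size = 96L,
                                        small_trigger = 1000L,
                                        variant = "compact")),
    "rerunning")
  expect_true(res2$second_pass)
})
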