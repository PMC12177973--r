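test_that("difficulty classes follow the stated cut-offs", {
  expect_identical(classify_difficulty(0.85), "hard")
  expect_identical(classify_difficulty(0.5), "moderate")
  expect_identical(classify_difficulty(0), "easy")
  # boundary handling: 0.8 is moderate, 0.3 is easy
  expect_identical(classify_difficulty(0.8), "moderate")
  expect_identical(classify_difficulty(0.3), "easy")
  # from an annotation: 85 of 100 markers in tissue
  circ <- data.frame(row = runif(100, 2, 9), col = runif(100, 2, 9),
                     radius = 1, in_tissue = c(rep(TRUE, 85), rep(FALSE, 15)))
  ann <- marker_annotation(circ, binary_mask(matrix(0L, 10, 10)))
  expect_identical(classify_difficulty(ann), "hard")
})

test_that("sampling plans repeat hard x3 and moderate x2 and are seeded", {
  mk <- function(f) list(markers = structure(
    list(circles = data.frame(), mask = NULL, overlap_factor = f),
    class = "marker_annotation"))
  corpus <- list(mk(0.9), mk(0.9), mk(0.5), mk(0.1))
  cfg <- train_config(epochs = 1)
  set.seed(1); plan <- build_sampling_plan(corpus, cfg)
  expect_identical(length(plan), 2L * 3L + 2L + 1L)
  expect_identical(sum(plan == 1), 3L)
  expect_identical(sum(plan == 3), 2L)
  expect_identical(sum(plan == 4), 1L)
  set.seed(1); plan2 <- build_sampling_plan(corpus, cfg)
  expect_identical(plan, plan2)
  # all-easy corpus: epoch length equals corpus size
  easy <- list(mk(0.1), mk(0.2), mk(0))
  expect_identical(length(build_sampling_plan(easy, cfg)), 3L)
  expect_error(build_sampling_plan(list(), cfg), "empty")
})

test_that("augmentation applies identical geometry to image and mask", {
  s <- generate_sample(small_spec(seed = 3, overlap = 0.3))
  # collapsed ranges are the identity
  ident <- augment_config(flip_lr = 0, flip_ud = 0, scale = c(1, 1),
                          rotation = c(0, 0), brightness = c(1, 1),
                          blur_sigma = c(0, 0))
  set.seed(1)
  au <- augment_pair(s$image, s$markers$mask, ident)
  expect_identical(unclass(au$img), unclass(s$image))
  expect_identical(as.matrix(au$mask), as.matrix(s$markers$mask))

  # a flip applied twice is the identity (involution)
  flip <- augment_config(flip_lr = 1, flip_ud = 0, scale = c(1, 1),
                         rotation = c(0, 0), brightness = c(1, 1),
                         blur_sigma = c(0, 0))
  set.seed(1); a1 <- augment_pair(s$image, s$markers$mask, flip)
  set.seed(1); a2 <- augment_pair(a1$img, a1$mask, flip)
  expect_identical(unclass(a2$img), unclass(s$image))

  # geometric transforms move image and mask together: the marker mask
  # must keep tracking dark marker ink after rotation + scale
  geo <- augment_config(flip_lr = 0, flip_ud = 0, scale = c(0.8, 1),
                        rotation = c(-10, 10), brightness = c(1, 1),
                        blur_sigma = c(0, 0))
  set.seed(7)
  ag <- augment_pair(s$image, s$markers$mask, geo)
  ink <- to_gray_test(ag$img)
  expect_lt(mean(ink[as.matrix(ag$mask) == 1L]),
            mean(ink[as.matrix(ag$mask) == 0L]) - 30)

  # drawn scale stays within the configured [0.8, 1.0] range: shrinking
  # never pushes content outside, so foreground area never grows much
  set.seed(9)
  areas <- replicate(10, sum(augment_pair(s$image, s$markers$mask,
                                          geo)$mask))
  expect_true(all(areas <= sum(s$markers$mask) / 0.8^2 * 1.1))
})

test_that("cross-validation folds are disjoint, balanced and seeded", {
  folds <- crossval_split(24, k = 12, seed = 5)
  expect_identical(length(folds), 12L)
  test_sets <- lapply(folds, `[[`, "test")
  expect_true(all(lengths(test_sets) == 2L))
  expect_identical(sort(unlist(test_sets)), 1:24)  # disjoint cover
  for (f in folds) {
    expect_identical(sort(c(f$train, f$test)), 1:24)
    expect_length(intersect(f$train, f$test), 0)
  }
  expect_identical(crossval_split(24, 12, seed = 5), folds)
  expect_error(crossval_split(5, k = 12), "smaller than k")
})
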