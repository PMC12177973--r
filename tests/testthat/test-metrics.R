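test_that("IoU matches enumeration, including the documented edge cases", {
  g <- matrix(0L, 5, 5); g[2:4, 2:4] <- 1L
  p <- matrix(0L, 5, 5); p[2:4, 3:5] <- 1L  # shifted one column
  expect_equal(mask_iou(p, g), 6 / 12)
  expect_equal(mask_iou(g, g), 1)
  expect_equal(mask_iou(matrix(0L, 3, 3), matrix(0L, 3, 3)), 1)
  d1 <- matrix(0L, 4, 4); d1[1, 1] <- 1L
  d2 <- matrix(0L, 4, 4); d2[4, 4] <- 1L
  expect_equal(mask_iou(d1, d2), 0)
  expect_error(mask_iou(matrix(0L, 3, 3), matrix(0L, 4, 4)), "differ")

  set.seed(10)
  for (rep in 1:100) {
    p <- random_mask(); g <- random_mask()
    expect_equal(mask_iou(p, g), iou_oracle_acc(p, g), tolerance = 1e-12)
  }
})

test_that("Hausdorff distance matches the boundary oracle and is symmetric", {
  a <- matrix(0L, 8, 8); a[1, 1] <- 1L
  b <- matrix(0L, 8, 8); b[4, 5] <- 1L  # (0,0) vs (3,4): distance 5
  expect_equal(hausdorff_distance(a, b), 5)
  expect_equal(hausdorff_distance(a, a), 0)

  set.seed(11)
  for (rep in 1:100) {
    p <- random_mask(); g <- random_mask()
    if (sum(p) == 0 || sum(g) == 0) next
    expect_equal(hausdorff_distance(p, g), hd_oracle_acc(p, g),
                 tolerance = 1e-9)
    expect_equal(hausdorff_distance(p, g), hausdorff_distance(g, p))
  }
  expect_warning(hausdorff_distance(matrix(0L, 4, 4), a), "empty")
})

test_that("perimeter ratio counts boundary pixels consistently", {
  sq <- matrix(0L, 12, 12); sq[4:9, 4:9] <- 1L  # 6x6 block: 20 boundary px
  expect_equal(perimeter_ratio(sq, sq), 1)
  big <- matrix(0L, 24, 24); big[2:23, 2:23] <- 1L
  # nested rings: boundary length scales with the ring size
  expect_equal(perimeter_ratio(big, sq), (4 * 22 - 4) / 20)
  expect_equal(perimeter_ratio(matrix(0L, 12, 12), sq), 0)
  expect_warning(perimeter_ratio(sq, matrix(0L, 12, 12)), "empty")

  set.seed(12)
  for (rep in 1:50) {
    p <- random_mask(); g <- random_mask()
    if (sum(g) == 0) next
    bo <- bnd_oracle_acc(g)
    expect_equal(perimeter_ratio(p, g),
                 max(0, NROW(bnd_oracle_acc(p))) / NROW(bo))
  }
})

test_that("component difference matches flood-fill counts and is symmetric", {
  p <- matrix(0L, 20, 20)
  p[2:4, 2:4] <- 1L; p[10:12, 10:12] <- 1L; p[16:18, 2:4] <- 1L
  g <- matrix(0L, 20, 20); g[5:15, 5:15] <- 1L
  expect_identical(comp_diff(p, g), 2L)
  expect_identical(comp_diff(g, p), 2L)
  expect_identical(comp_diff(p, p), 0L)
  set.seed(13)
  for (rep in 1:50) {
    a <- random_mask(); b <- random_mask()
    expect_identical(comp_diff(a, b, 8L),
                     abs(flood_count(a, 8L) - flood_count(b, 8L)))
  }
})

test_that("SSIM satisfies identity, symmetry and the constant-image form", {
  set.seed(14)
  x <- rgb_image(array(runif(32 * 32 * 3) * 255, c(32, 32, 3)))
  y <- rgb_image(array(runif(32 * 32 * 3) * 255, c(32, 32, 3)))
  expect_equal(ssim_score(x, x), 1)
  expect_equal(ssim_score(x, y), ssim_score(y, x))
  # distinct constants: variances vanish, closed form remains
  a <- rgb_image(array(100, c(16, 16, 3)))
  b <- rgb_image(array(180, c(16, 16, 3)))
  c1 <- (0.01 * 255)^2
  expect_equal(ssim_score(a, b),
               (2 * 100 * 180 + c1) / (100^2 + 180^2 + c1),
               tolerance = 1e-12)
  expect_error(ssim_score(x, rgb_image(array(0, c(16, 16, 3)))), "differ")
})

test_that("mutual information equals marginal entropy on identical images", {
  set.seed(15)
  x <- rgb_image(array(sample(0:255, 48 * 48 * 3, TRUE), c(48, 48, 3)))
  y <- rgb_image(array(sample(0:255, 48 * 48 * 3, TRUE), c(48, 48, 3)))
  g <- stclean:::to_gray(x)
  bins <- pmin(floor(g / 256 * 64), 63)
  pb <- table(bins) / length(bins)
  entropy <- -sum(pb * log(pb))
  expect_equal(mutual_information(x, x), entropy, tolerance = 1e-9)
  expect_equal(mutual_information(x, y), mutual_information(y, x))
  expect_gte(mutual_information(x, y), -1e-9)
  flat <- rgb_image(array(7, c(48, 48, 3)))
  expect_equal(mutual_information(flat, x), 0, tolerance = 1e-12)
})

test_that("multi-class Dice follows the per-class mean", {
  a <- matrix(0L, 10, 10); a[1:4, 1:4] <- 1L; a[6:9, 6:9] <- 2L
  expect_equal(multiclass_dice(a, a), 1)
  # one class perfect, one half-overlapping with equal areas -> 0.75
  b <- a
  b[6:9, 6:9] <- 0L; b[6:9, 4:7] <- 2L  # 16 px shifted to overlap 8 px
  ov <- sum(a == 2L & b == 2L)
  expect_equal(multiclass_dice(a, b),
               (1 + 2 * ov / (16 + 16)) / 2)
  d1 <- matrix(1L, 4, 4); d2 <- matrix(0L, 4, 4); d2[1, 1] <- 2L
  expect_equal(multiclass_dice(d1, d2), 0)
  expect_error(multiclass_dice(a, a, classes = integer(0)), "no classes")
})

test_that("adjusted Rand index matches the pair-counting oracle", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  expect_equal(adjusted_rand_index(1:6, 1:6), 1)
  x <- c(1, 1, 2, 2, 3, 3)
  perm <- c(5, 5, 9, 9, 1, 1)
  expect_equal(adjusted_rand_index(x, perm), 1)  # label-permutation invariant
  set.seed(16)
  for (rep in 1:50) {
    n <- sample(5:30, 1)
    a <- sample(1:4, n, replace = TRUE)
    b <- sample(1:3, n, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), ari_oracle_acc(a, b),
                 tolerance = 1e-12)
  }
  expect_error(adjusted_rand_index(1:3, 1:4), "equal length")
})

test_that("morphology features recover known shapes", {
  disc <- stclean:::draw_disc(matrix(0L, 50, 50), c(25, 25), 20)
  f <- morphology_features(labeled_mask(disc))
  expect_gt(f$circularity, 0.9)
  expect_lt(f$circularity, 1.05)
  expect_gt(f$solidity, 0.95)
  expect_lt(f$eccentricity, 0.2)

  rect <- matrix(0L, 60, 60); rect[11:20, 11:50] <- 1L  # 10 x 40
  fr <- morphology_features(labeled_mask(rect))
  expect_equal(fr$aspect_ratio, 4, tolerance = 0.01)
  expect_equal(fr$extent, 1)
  expect_gt(fr$elongation, 0.6)

  feats <- rbind(f, fr)
  z <- standardize_features(feats)
  expect_lt(max(abs(colMeans(z))), 1e-9)
  sds <- apply(z, 2, sd)
  expect_lt(max(abs(sds[sds > 0] - 1)), 1e-9)
})

test_that("cells outside tissue are counted by the centroid rule", {
  tissue <- matrix(0L, 30, 30); tissue[1:30, 1:15] <- 1L
  lab <- matrix(0L, 30, 30)
  lab[5:7, 5:7] <- 1L     # inside
  lab[5:7, 25:27] <- 2L   # outside
  lab[10:12, 14:17] <- 3L # straddles; centroid at col 15.5 -> round 16
  expect_identical(cells_outside_tissue(labeled_mask(lab),
                                        binary_mask(tissue)), 2L)
  lab[10:12, 17] <- 0L    # pull centroid back inside
  expect_identical(cells_outside_tissue(labeled_mask(lab),
                                        binary_mask(tissue)), 1L)
})

test_that("overlay extraction isolates red circles and fills them", {
  img <- array(0, c(120, 120, 3))
  img[, , 1] <- 240; img[, , 2] <- 235; img[, , 3] <- 230
  centers <- rbind(c(25, 25), c(25, 95), c(95, 25), c(95, 95))
  for (i in 1:4) {
    ring <- stclean:::draw_disc(matrix(0L, 120, 120), centers[i, ], 7) -
      stclean:::draw_disc(matrix(0L, 120, 120), centers[i, ], 4.5)
    sel <- ring == 1L
    r <- img[, , 1]; g <- img[, , 2]; b <- img[, , 3]
    r[sel] <- 200; g[sel] <- 10; b[sel] <- 10
    img[, , 1] <- r; img[, , 2] <- g; img[, , 3] <- b
  }
  out <- extract_overlay_markers(rgb_image(img), radius_range = c(4L, 10L))
  # four filled discs recovered near the drawn centres
  expect_identical(count_components(out, 8L), 4L)
  for (i in 1:4) expect_identical(out[centers[i, 1], centers[i, 2]], 1L)
  # sub-threshold red (150) yields nothing
  faint <- array(0, c(40, 40, 3)); faint[, , 1] <- 150
  expect_identical(sum(extract_overlay_markers(rgb_image(faint))), 0L)
})
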