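test_that("read_image honours the shape and channel contracts", {
  d <- withr::local_tempdir()
  img <- rgb_image(array(runif(64 * 64 * 3) * 255, c(64, 64, 3)))
  p <- file.path(d, "a.png")
  write_image(img, p)
  back <- read_image(p)
  expect_identical(dim(back), c(64L, 64L, 3L))
  expect_identical(unclass(back), unclass(img))  # 8-bit PNG is lossless

  # grayscale TIFF replicates to three identical channels
  gm <- matrix(as.double(0:255)[1 + (0:63) %% 256], 8, 8)
  tif <- file.path(d, "g.tif")
  stclean:::write_tiff_float(gm, tif)  # float path is for masks;
  gpng <- file.path(d, "g.png")
  png::writePNG(gm / 255, gpng)
  gimg <- read_image(gpng)
  expect_identical(gimg[, , 1], gimg[, , 2])
  expect_identical(gimg[, , 1], gimg[, , 3])

  # rgba png: alpha dropped
  png::writePNG(array(runif(16 * 16 * 4), c(16, 16, 4)), file.path(d, "r.png"))
  expect_identical(dim(read_image(file.path(d, "r.png")))[3], 3L)

  # truncated/empty file is an input error naming the path
  bad <- file.path(d, "broken.png")
  writeBin(as.raw(c(137, 80, 78)), bad)
  expect_error(read_image(bad), "broken.png")
  file.create(file.path(d, "empty.png"))
  expect_error(read_image(file.path(d, "empty.png")), "empty.png")
})

test_that("8-bit grayscale and RGB TIFF images are readable", {
  d <- withr::local_tempdir()
  img <- rgb_image(array(sample(0:255, 12 * 10 * 3, TRUE), c(12, 10, 3)))
  p <- file.path(d, "x.tif")
  write_image(img, p)
  expect_identical(unclass(read_image(p)), unclass(img))
})

test_that("all three mask kinds round-trip bit-exactly", {
  d <- withr::local_tempdir()
  b <- binary_mask(random_mask(20, 17))
  pb <- file.path(d, "b.png")
  write_mask(b, pb)
  expect_identical(as.matrix(read_mask(pb)), as.matrix(b))

  lab <- segregate(probability_mask((random_mask(30, 30, 0.4))),
                   segregation_config(threshold = 0.5, min_area = 1))
  pl <- file.path(d, "l.png")
  write_mask(lab, pl)
  back <- read_mask(pl)
  expect_s3_class(back, "labeled_mask")
  expect_identical(as.matrix(back), as.matrix(lab))
  expect_identical(n_components(back), n_components(lab))

  # probability masks: exact for float32-representable values
  pm <- probability_mask(matrix(c(0, 0.5, 0.25, 1), 2, 2))
  pt <- file.path(d, "p.tif")
  write_mask(pm, pt)
  expect_identical(as.matrix(read_mask(pt)), as.matrix(pm))

  expect_error(write_mask(b, file.path(d, "no/dir/x.png")), "directory")
})

test_that("tile grids cover the image with the documented counts", {
  img <- rgb_image(array(0, c(512, 512, 3)))
  expect_identical(nrow(tile_image(img, 256, 0)$origins), 4L)
  g <- tile_image(img, 256, 128)
  expect_identical(nrow(g$origins), 9L)
  # enumerate origins at stride 128 clamped to bounds
  expect_setequal(unique(g$origins[, 1]), c(1L, 129L, 257L))

  expect_warning(g1 <- tile_image(rgb_image(array(0, c(100, 100, 3))), 256),
                 "single full-image tile")
  expect_identical(nrow(g1$origins), 1L)
  expect_identical(g1$tile_h, 100L)

  # coverage invariant for irregular size
  img2 <- rgb_image(array(0, c(300, 200, 3)))
  g2 <- tile_image(img2, 128, 32)
  cov <- matrix(0L, 300, 200)
  for (i in seq_len(nrow(g2$origins))) {
    o <- g2$origins[i, ]
    cov[o[1]:(o[1] + 127), o[2]:(o[2] + 127)] <- 1L
  }
  expect_true(all(cov == 1L))
})

test_that("stitching averages overlaps and reproduces constants exactly", {
  m1 <- matrix(0.2, 4, 6); m2 <- matrix(0.6, 4, 6)
  out <- stitch_probability(list(list(origin = c(1, 1), mask = m1),
                                 list(origin = c(1, 3), mask = m2)),
                            c(4, 8))
  expect_equal(out[1, 1], 0.2)
  expect_equal(out[1, 8], 0.6)
  expect_equal(out[1, 4], 0.4)  # mean on the overlap

  # property: tile -> stitch of a constant mask is exact for any layout
  for (ts in c(64, 96)) for (ov in c(0, 16, 48)) {
    img <- rgb_image(array(0, c(160, 160, 3)))
    g <- tile_image(img, ts, ov)
    tiles <- lapply(seq_len(nrow(g$origins)), function(i)
      list(origin = g$origins[i, ], mask = matrix(0.37, g$tile_h, g$tile_w)))
    st <- stitch_probability(tiles, c(160, 160))
    expect_equal(max(abs(st - 0.37)), 0)
  }
  expect_error(stitch_probability(list(list(origin = c(1, 1),
                                            mask = matrix(0.5, 2, 2))),
                                  c(4, 4)),
               "cover")
})

test_that("resizing keeps classes and mask values discrete", {
  img <- rgb_image(array(runif(40 * 40 * 3) * 255, c(40, 40, 3)))
  expect_identical(dim(resize_image(img, 20, 30))[1:2], c(20L, 30L))
  lab <- labeled_mask(rbind(matrix(1L, 10, 20), matrix(0L, 10, 20)))
  rl <- resize_mask(lab, 10, 10)
  expect_s3_class(rl, "labeled_mask")
  expect_true(all(rl %in% c(0L, 1L)))
  pm <- probability_mask(matrix(0.5, 16, 16))
  expect_equal(max(abs(resize_mask(pm, 8, 8) - 0.5)), 0)
})
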