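test_that("a sample is fully determined by its spec and seed", {
  sp <- small_spec(seed = 7, overlap = 0.4)
  a <- generate_sample(sp)
  b <- generate_sample(sp)
  expect_identical(unclass(a$image), unclass(b$image))
  expect_identical(as.matrix(a$markers$mask), as.matrix(b$markers$mask))
  expect_identical(a$markers$circles, b$markers$circles)
  # 4 sides x markers_per_side circles
  expect_identical(nrow(a$markers$circles), 28L)
})

test_that("ground truths are mutually consistent", {
  for (seed in c(2, 5, 11)) {
    s <- generate_sample(small_spec(seed = seed, overlap = 0.5, blobs = 2))
    # stored component count equals an independent flood-fill count
    expect_identical(s$n_tissue_components,
                     flood_count(as.matrix(s$tissue_mask), 8L))
    # overlap factor recomputed from circles and tissue reproduces stored
    ctr <- round(as.matrix(s$markers$circles[c("row", "col")]))
    flags <- as.matrix(s$tissue_mask)[ctr] == 1L
    expect_identical(flags, s$markers$circles$in_tissue)
    expect_equal(s$markers$overlap_factor, mean(flags))
  }
})

test_that("rasterized circle area is close to pi r^2", {
  for (r in c(5, 6, 8)) {
    sp <- synthetic_spec(image_size = 160, markers_per_side = 4,
                         marker_radius = r, radius_jitter = 0,
                         center_jitter = 0, deformation = 0,
                         n_tissue_blobs = 0, overlap_factor = 0,
                         stain_noise = 0, seed = 3)
    s <- generate_sample(sp)
    per_circle <- sum(s$markers$mask) / nrow(s$markers$circles)
    expect_lt(abs(per_circle - pi * r^2) / (pi * r^2), 0.15)
  }
})

test_that("zero deformation and jitter put centres on the ideal frame", {
  sp <- synthetic_spec(image_size = 160, markers_per_side = 5,
                       marker_radius = 5, radius_jitter = 0,
                       center_jitter = 0, deformation = 0,
                       n_tissue_blobs = 0, overlap_factor = 0,
                       stain_noise = 0, seed = 9)
  s <- generate_sample(sp)
  ideal <- stclean:::frame_centers(160, 5L, max(12, round(0.08 * 160)))
  expect_equal(as.matrix(s$markers$circles[c("row", "col")]),
               ideal, ignore_attr = TRUE)
})

test_that("disjoint blob requests yield matching component counts", {
  for (nb in 1:4) {
    s <- generate_sample(small_spec(seed = 20 + nb, overlap = 0, blobs = nb))
    expect_identical(s$n_tissue_components, nb)
  }
})

test_that("an infeasible overlap target is a config error", {
  expect_error(synthetic_spec(overlap_factor = 0.5, n_tissue_blobs = 0),
               "tissue blob")
})

test_that("corpus strata follow the requested mixture", {
  tmpl <- small_spec(seed = 31)
  co <- generate_corpus(12, tmpl, mix = c(hard = 0.5, moderate = 0.25,
                                          easy = 0.25))
  cls <- vapply(co, function(s) classify_difficulty(s$markers), character(1))
  expect_identical(sum(cls == "hard"), 6L)
  expect_identical(sum(cls == "moderate"), 3L)
  expect_identical(sum(cls == "easy"), 3L)

  co_easy <- generate_corpus(5, tmpl, mix = c(0, 0, 1))
  expect_true(all(vapply(co_easy, function(s) s$markers$overlap_factor,
                         numeric(1)) < 0.3))
  expect_identical(length(generate_corpus(1, tmpl, mix = c(0, 0, 1))), 1L)
  expect_identical(generate_corpus(0, tmpl, mix = c(0, 0, 1)), list())
})

test_that("a corpus persists and reloads losslessly", {
  d <- withr::local_tempdir()
  co <- list(generate_sample(small_spec(seed = 41, overlap = 0.4)))
  save_corpus(co, d)
  back <- load_corpus(d)
  expect_identical(unclass(back[[1]]$image), unclass(co[[1]]$image))
  expect_identical(as.matrix(back[[1]]$markers$mask),
                   as.matrix(co[[1]]$markers$mask))
  expect_identical(as.matrix(back[[1]]$tissue_mask),
                   as.matrix(co[[1]]$tissue_mask))
  expect_equal(back[[1]]$markers$circles$radius,
               co[[1]]$markers$circles$radius)
  expect_identical(back[[1]]$n_tissue_components,
                   co[[1]]$n_tissue_components)
})
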