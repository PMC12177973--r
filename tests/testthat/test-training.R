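# Training-loop mechanics on a miniature network; the full-width
# architecture is exercised in the acceptance suite.

mini_corpus <- function(seed = 81) {
  list(generate_sample(synthetic_spec(image_size = 128, markers_per_side = 6,
                                      marker_radius = 5, seed = seed,
                                      overlap_factor = 0,
                                      n_tissue_blobs = 1)))
}

test_that("seeded training is bit-reproducible and reduces the loss", {
  co <- mini_corpus()
  cfg_net <- tiny_net()
  cfg_tr <- train_config(epochs = 15, lr = 1e-3, tile_size = 128, seed = 3)
  m1 <- fit_marker_net(co, net = cfg_net, train = cfg_tr)
  m2 <- fit_marker_net(co, net = cfg_net, train = cfg_tr)
  expect_identical(m1$loss_trace, m2$loss_trace)
  expect_identical(m1$params, m2$params)
  expect_lt(tail(m1$loss_trace, 1), m1$loss_trace[1])
})

test_that("training rejects unusable corpora", {
  expect_error(fit_marker_net(list()), "empty")
  s <- generate_sample(synthetic_spec(image_size = 128, markers_per_side = 0L,
                                      n_tissue_blobs = 1,
                                      overlap_factor = 0, seed = 5))
  expect_error(fit_marker_net(list(s)), "no slide with annotated markers")
})

test_that("prediction on a slide smaller than the tile equals forward", {
  co <- mini_corpus()
  m <- fit_marker_net(co, net = tiny_net(),
                      train = train_config(epochs = 1, tile_size = 128,
                                           seed = 4))
  img <- co[[1]]$image
  out <- predict_slide(img, m, tile_size = 256, overlap = 32)
  fw <- stclean:::unet_forward(m$params, unclass(img) / 255)
  expect_equal(as.matrix(out$prob), fw$prob, tolerance = 1e-12)
  expect_true(all(out$mask %in% c(0L, 1L)))
})

test_that("a constant network is invariant to the tile layout", {
  m <- fit_marker_net(mini_corpus(), net = tiny_net(),
                      train = train_config(epochs = 1, tile_size = 64,
                                           seed = 6))
  for (nm in names(m$params)) { m$params[[nm]]$W[] <- 0; m$params[[nm]]$b[] <- 0 }
  img <- mini_corpus()[[1]]$image
  a <- predict_slide(img, m, tile_size = 64, overlap = 0)
  b <- predict_slide(img, m, tile_size = 64, overlap = 32)
  expect_equal(max(abs(a$prob - 0.5)), 0)
  expect_equal(as.matrix(a$prob), as.matrix(b$prob))
})

test_that("checkpoints round-trip the model and its configs", {
  d <- withr::local_tempdir()
  m <- fit_marker_net(mini_corpus(), net = tiny_net(),
                      train = train_config(epochs = 2, tile_size = 128,
                                           seed = 7))
  p <- file.path(d, "ckpt.rds")
  save_checkpoint(m, p)
  back <- load_checkpoint(p)
  expect_identical(back$params, m$params)
  expect_identical(back$train$seed, m$train$seed)
  img <- mini_corpus()[[1]]$image
  expect_identical(predict_slide(img, back)$prob, predict_slide(img, m)$prob)
})
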