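# Encoder-decoder segmentation network.
#
# A four-stage U-shaped fully convolutional network specialised for small,
# globally arranged circular targets: the first encoder block carries an
# extra 3x3 convolution and no dropout (fine detail), the fourth encoder
# block and the bottleneck carry extra 3x3 convolutions (global shape
# context). Decoder blocks upsample with 4x4 transposed convolutions;
# skips from encoder stages 3/2/1 are additive (the first through a 1x1
# projection) and the final skip concatenates the input image onto the
# last 16 learned channels, giving a 19-channel map ahead of a 4x4
# sigmoid head. Instance normalisation is used without affine parameters.
#
# Everything here is plain data (a named list of weight matrices) plus
# forward/backward functions; the exported modelling interface lives in
# marker_net.R and tissue.R.

NET_DOWNSCALE <- 16L  # four stride-2 halvings

new_conv <- function(ic, oc, kh, kw) {
  sd <- sqrt(2 / (ic * kh * kw))
  list(W = matrix(rnorm(oc * ic * kh * kw, 0, sd), oc, ic * kh * kw),
       b = numeric(oc), kh = kh, kw = kw)
}

new_deconv <- function(ic, oc, kh = 4L, kw = 4L) {
  sd <- sqrt(2 / (ic * kh * kw))
  list(W = matrix(rnorm(ic * oc * kh * kw, 0, sd), ic, oc * kh * kw),
       b = numeric(oc), kh = kh, kw = kw)
}

# Architecture constructor. widths_dec[2] must equal widths_enc[2] and
# widths_dec[3] widths_enc[1] because those skips are additive.
unet_init <- function(widths_enc = c(32L, 64L, 128L, 256L),
                      widths_dec = c(128L, 64L, 32L, 16L),
                      in_channels = 3L) {
  e <- as.integer(widths_enc); d <- as.integer(widths_dec)
  stopifnot(length(e) == 4L, length(d) == 4L)
  if (d[2] != e[2] || d[3] != e[1])
    stop("additive skips require widths_dec[2] == widths_enc[2] and ",
         "widths_dec[3] == widths_enc[1]", call. = FALSE)
  params <- list(
    enc1a = new_conv(in_channels, e[1], 4L, 4L),
    enc1b = new_conv(e[1], e[1], 3L, 3L),
    enc2  = new_conv(e[1], e[2], 4L, 4L),
    enc3  = new_conv(e[2], e[3], 4L, 4L),
    enc4a = new_conv(e[3], e[4], 4L, 4L),
    enc4b = new_conv(e[4], e[4], 3L, 3L),
    bot1  = new_conv(e[4], e[4], 3L, 3L),
    bot2  = new_conv(e[4], e[4], 3L, 3L),
    dec1d = new_deconv(e[4], d[1]),
    dec1c = new_conv(d[1], d[1], 3L, 3L),
    skip1 = new_conv(e[3], d[1], 1L, 1L),
    dec2d = new_deconv(d[1], d[2]),
    dec3d = new_deconv(d[2], d[3]),
    dec4d = new_deconv(d[3], d[4]),
    dec4c = new_conv(d[4], d[4], 3L, 3L),
    head  = new_conv(d[4] + in_channels, 1L, 4L, 4L))
  attr(params, "widths_enc") <- e
  attr(params, "widths_dec") <- d
  attr(params, "in_channels") <- in_channels
  params
}

conv_f <- function(x, p, stride = 1L, pad = 1L) {
  h <- dim(x)[1]; w <- dim(x)[2]
  oh <- if (stride == 2L) h %/% 2L else h
  ow <- if (stride == 2L) w %/% 2L else w
  cpp_conv_fwd(x, p$W, p$b, p$kh, p$kw, stride, pad, pad, oh, ow)
}

conv_b <- function(x, p, gy, stride = 1L, pad = 1L) {
  cpp_conv_bwd(x, p$W, gy, p$kh, p$kw, stride, pad, pad)
}

deconv_f <- function(x, p) {
  cpp_deconv_fwd(x, p$W, p$b, 4L, 4L, 2L, 1L, 1L,
                 2L * dim(x)[1], 2L * dim(x)[2])
}

deconv_b <- function(x, p, gy) {
  cpp_deconv_bwd(x, p$W, gy, 4L, 4L, 2L, 1L, 1L)
}

inorm_f <- function(x, eps = 1e-5) {
  d <- dim(x)
  m <- x; dim(m) <- c(d[1] * d[2], d[3])
  mu <- colMeans(m)
  v <- colMeans(m * m) - mu^2
  invstd <- 1 / sqrt(pmax(v, 0) + eps)
  xhat <- sweep(sweep(m, 2L, mu), 2L, invstd, `*`)
  y <- xhat; dim(y) <- d
  list(y = y, xhat = xhat, invstd = invstd, d = d)
}

inorm_b <- function(gy, cache) {
  d <- cache$d
  g <- gy; dim(g) <- c(d[1] * d[2], d[3])
  gmean <- colMeans(g)
  gx_mean <- colMeans(g * cache$xhat)
  gc <- sweep(g, 2L, gmean) - sweep(cache$xhat, 2L, gx_mean, `*`)
  gx <- sweep(gc, 2L, cache$invstd, `*`)
  dim(gx) <- d
  gx
}

relu_f <- function(x) { x[x < 0] <- 0; x }

dropout_mask <- function(d, rate) {
  if (rate <= 0) return(NULL)
  array((runif(prod(d)) >= rate) / (1 - rate), dim = d)
}

# Reflective padding of an H x W x C array to multiples of `mult`.
pad_reflect <- function(x, mult = NET_DOWNSCALE) {
  h <- dim(x)[1]; w <- dim(x)[2]
  ph <- (mult - h %% mult) %% mult
  pw <- (mult - w %% mult) %% mult
  if (ph == 0 && pw == 0) return(list(x = x, h = h, w = w))
  ri <- c(seq_len(h), rev(seq_len(h))[seq_len(ph)])
  ci <- c(seq_len(w), rev(seq_len(w))[seq_len(pw)])
  list(x = x[ri, ci, , drop = FALSE], h = h, w = w)
}

.pad_logged <- new.env(parent = emptyenv())

# Forward pass. x is an H x W x C array of intensities already scaled to
# [0, 1]. Returns the probability matrix, the 19-channel pre-head map
# dimensionality, and (when training) the cache needed for backprop.
unet_forward <- function(params, x, dropout = 0.5, training = FALSE) {
  stopifnot(length(dim(x)) == 3L)
  pd <- pad_reflect(x)
  if ((pd$h != dim(pd$x)[1] || pd$w != dim(pd$x)[2]) &&
      !isTRUE(.pad_logged$done)) {
    message("input dims not divisible by ", NET_DOWNSCALE,
            "; padding reflectively (reported once per session)")
    .pad_logged$done <- TRUE
  }
  x0 <- pd$x
  drop_rate <- if (training) dropout else 0

  z1a <- conv_f(x0, params$enc1a, 2L)
  z1b <- conv_f(z1a, params$enc1b)
  a1 <- relu_f(z1b)

  z2 <- conv_f(a1, params$enc2, 2L)
  n2 <- inorm_f(z2); r2 <- relu_f(n2$y)
  m2 <- dropout_mask(dim(r2), drop_rate)
  a2 <- if (is.null(m2)) r2 else r2 * m2

  z3 <- conv_f(a2, params$enc3, 2L)
  n3 <- inorm_f(z3); r3 <- relu_f(n3$y)
  m3 <- dropout_mask(dim(r3), drop_rate)
  a3 <- if (is.null(m3)) r3 else r3 * m3

  z4a <- conv_f(a3, params$enc4a, 2L)
  z4b <- conv_f(z4a, params$enc4b)
  n4 <- inorm_f(z4b); r4 <- relu_f(n4$y)
  m4 <- dropout_mask(dim(r4), drop_rate)
  a4 <- if (is.null(m4)) r4 else r4 * m4

  b1 <- conv_f(a4, params$bot1)
  b2 <- conv_f(b1, params$bot2)

  u1 <- deconv_f(b2, params$dec1d)
  v1 <- conv_f(u1, params$dec1c)
  nd1 <- inorm_f(v1); rd1 <- relu_f(nd1$y)
  md1 <- dropout_mask(dim(rd1), drop_rate)
  dd1 <- if (is.null(md1)) rd1 else rd1 * md1
  sk1 <- conv_f(a3, params$skip1, 1L, 0L)
  s1 <- dd1 + sk1

  u2 <- deconv_f(s1, params$dec2d)
  nd2 <- inorm_f(u2); rd2 <- relu_f(nd2$y)
  md2 <- dropout_mask(dim(rd2), drop_rate)
  dd2 <- if (is.null(md2)) rd2 else rd2 * md2
  s2 <- dd2 + a2

  u3 <- deconv_f(s2, params$dec3d)
  nd3 <- inorm_f(u3); rd3 <- relu_f(nd3$y)
  s3 <- rd3 + a1

  u4 <- deconv_f(s3, params$dec4d)
  v4 <- conv_f(u4, params$dec4c)
  nd4 <- inorm_f(v4); rd4 <- relu_f(nd4$y)
  d4w <- dim(rd4)[3]
  s4 <- array(c(rd4, x0), dim = c(dim(rd4)[1:2], d4w + dim(x0)[3]))

  logit <- conv_f(s4, params$head)[, , 1]
  prob <- 1 / (1 + exp(-logit))
  prob <- prob[seq_len(pd$h), seq_len(pd$w), drop = FALSE]

  cache <- NULL
  if (training) {
    cache <- list(pd = pd, x0 = x0, z1a = z1a, z1b = z1b, a1 = a1, z2 = z2, n2 = n2,
                  r2 = r2, m2 = m2, a2 = a2, z3 = z3, n3 = n3, r3 = r3,
                  m3 = m3, a3 = a3, z4a = z4a, z4b = z4b, n4 = n4, r4 = r4,
                  m4 = m4, a4 = a4, b1 = b1, b2 = b2, u1 = u1, v1 = v1,
                  nd1 = nd1, rd1 = rd1, md1 = md1, dd1 = dd1, sk1 = sk1,
                  s1 = s1, u2 = u2, nd2 = nd2, rd2 = rd2, md2 = md2,
                  dd2 = dd2, s2 = s2, u3 = u3, nd3 = nd3, rd3 = rd3,
                  s3 = s3, u4 = u4, v4 = v4, nd4 = nd4, rd4 = rd4, s4 = s4,
                  prob_full = 1 / (1 + exp(-logit)))
  }
  list(prob = prob, cache = cache, pre_head_channels = d4w + dim(x0)[3])
}

# Backward pass. dprob is dLoss/dprob on the cropped (original) grid.
# Returns a list of gradients parallel to params.
unet_backward <- function(params, cache, dprob) {
  pd <- cache$pd
  p_full <- cache$prob_full
  dp <- matrix(0, dim(p_full)[1], dim(p_full)[2])
  dp[seq_len(pd$h), seq_len(pd$w)] <- dprob
  dlogit <- dp * p_full * (1 - p_full)
  g <- array(dlogit, dim = c(dim(dlogit), 1L))

  gr <- list()
  bk <- conv_b(cache$s4, params$head, g)
  gr$head <- list(W = bk$gW, b = bk$gb)
  gs4 <- bk$gx
  d4w <- dim(cache$rd4)[3]
  grd4 <- gs4[, , seq_len(d4w), drop = FALSE]
  # gradient into the concatenated raw image channels is discarded

  gv4 <- inorm_b(grd4 * (cache$nd4$y > 0), cache$nd4)
  bk <- conv_b(cache$u4, params$dec4c, gv4)
  gr$dec4c <- list(W = bk$gW, b = bk$gb)
  bk <- deconv_b(cache$s3, params$dec4d, bk$gx)
  gr$dec4d <- list(W = bk$gW, b = bk$gb)
  gs3 <- bk$gx

  ga1_skip <- gs3
  gu3 <- inorm_b(gs3 * (cache$nd3$y > 0), cache$nd3)
  bk <- deconv_b(cache$s2, params$dec3d, gu3)
  gr$dec3d <- list(W = bk$gW, b = bk$gb)
  gs2 <- bk$gx

  ga2_skip <- gs2
  gdd2 <- if (is.null(cache$md2)) gs2 else gs2 * cache$md2
  gu2 <- inorm_b(gdd2 * (cache$nd2$y > 0), cache$nd2)
  bk <- deconv_b(cache$s1, params$dec2d, gu2)
  gr$dec2d <- list(W = bk$gW, b = bk$gb)
  gs1 <- bk$gx

  bk <- conv_b(cache$a3, params$skip1, gs1, 1L, 0L)
  gr$skip1 <- list(W = bk$gW, b = bk$gb)
  ga3_skip <- bk$gx
  gdd1 <- if (is.null(cache$md1)) gs1 else gs1 * cache$md1
  gv1 <- inorm_b(gdd1 * (cache$nd1$y > 0), cache$nd1)
  bk <- conv_b(cache$u1, params$dec1c, gv1)
  gr$dec1c <- list(W = bk$gW, b = bk$gb)
  bk <- deconv_b(cache$b2, params$dec1d, bk$gx)
  gr$dec1d <- list(W = bk$gW, b = bk$gb)
  gb2 <- bk$gx

  bk <- conv_b(cache$b1, params$bot2, gb2)
  gr$bot2 <- list(W = bk$gW, b = bk$gb)
  bk <- conv_b(cache$a4, params$bot1, bk$gx)
  gr$bot1 <- list(W = bk$gW, b = bk$gb)
  ga4 <- bk$gx

  gr4 <- if (is.null(cache$m4)) ga4 else ga4 * cache$m4
  gz4b <- inorm_b(gr4 * (cache$n4$y > 0), cache$n4)
  bk <- conv_b(cache$z4a, params$enc4b, gz4b)
  gr$enc4b <- list(W = bk$gW, b = bk$gb)
  bk <- conv_b(cache$a3, params$enc4a, bk$gx, 2L)
  gr$enc4a <- list(W = bk$gW, b = bk$gb)
  ga3 <- bk$gx + ga3_skip

  gr3 <- if (is.null(cache$m3)) ga3 else ga3 * cache$m3
  gz3 <- inorm_b(gr3 * (cache$n3$y > 0), cache$n3)
  bk <- conv_b(cache$a2, params$enc3, gz3, 2L)
  gr$enc3 <- list(W = bk$gW, b = bk$gb)
  ga2 <- bk$gx + ga2_skip

  gr2 <- if (is.null(cache$m2)) ga2 else ga2 * cache$m2
  gz2 <- inorm_b(gr2 * (cache$n2$y > 0), cache$n2)
  bk <- conv_b(cache$a1, params$enc2, gz2, 2L)
  gr$enc2 <- list(W = bk$gW, b = bk$gb)
  ga1 <- bk$gx + ga1_skip

  gz1b <- ga1 * (cache$z1b > 0)
  bk <- conv_b(cache$z1a, params$enc1b, gz1b)
  gr$enc1b <- list(W = bk$gW, b = bk$gb)
  bk <- conv_b(cache$x0, params$enc1a, bk$gx, 2L)
  gr$enc1a <- list(W = bk$gW, b = bk$gb)
  gr
}

# Adam optimiser state and update (applied tensor-wise).
adam_init <- function(params) {
  lapply(params, function(p) list(mW = p$W * 0, vW = p$W * 0,
                                  mb = p$b * 0, vb = p$b * 0))
}

adam_step <- function(params, grads, state, t, lr = 1e-4,
                      beta1 = 0.5, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (nm in names(grads)) {
    g <- grads[[nm]]; s <- state[[nm]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    params[[nm]]$W <- params[[nm]]$W -
      lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + eps)
    params[[nm]]$b <- params[[nm]]$b -
      lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    state[[nm]] <- s
  }
  list(params = params, state = state)
}
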