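# Shared fixtures: everything is generated in code at test time.

# Small slide spec used across module tests (160 px keeps the network
# fast on one CPU while leaving room for a marker frame and tissue).
small_spec <- function(seed = 1L, overlap = 0.1, blobs = 1L,
                       deformation = 2, size = 160L) {
  synthetic_spec(image_size = size, markers_per_side = 7L,
                 marker_radius = 6, deformation = deformation,
                 n_tissue_blobs = blobs, overlap_factor = overlap,
                 stain_noise = 0.02, seed = seed)
}

# Tiny network widths satisfying the additive-skip constraints; used for
# architecture-independent mechanics (gradients, shapes).
tiny_net <- function() net_config(widths_enc = c(2L, 4L, 6L, 8L),
                                  widths_dec = c(6L, 4L, 2L, 2L),
                                  dropout = 0)

# Independent recursive flood fill used as the labelling oracle.
flood_count <- function(m, connectivity = 8L) {
  h <- nrow(m); w <- ncol(m)
  seen <- matrix(FALSE, h, w)
  nb <- if (connectivity == 8L)
    cbind(c(-1,-1,-1,0,0,1,1,1), c(-1,0,1,-1,1,-1,0,1))
  else cbind(c(-1,0,0,1), c(0,-1,1,0))
  count <- 0L
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (m[i, j] == 0 || seen[i, j]) next
    count <- count + 1L
    stack <- list(c(i, j)); seen[i, j] <- TRUE
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (t in seq_len(nrow(nb))) {
        ni <- p[1] + nb[t, 1]; nj <- p[2] + nb[t, 2]
        if (ni >= 1 && ni <= h && nj >= 1 && nj <= w &&
            m[ni, nj] == 1 && !seen[ni, nj]) {
          seen[ni, nj] <- TRUE
          stack[[length(stack) + 1L]] <- c(ni, nj)
        }
      }
    }
  }
  count
}

random_mask <- function(h = 16L, w = 16L, p = 0.3) {
  matrix(rbinom(h * w, 1L, p), h, w)
}

to_gray_test <- function(img) stclean:::to_gray(img)
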