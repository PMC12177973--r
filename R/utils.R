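# Small internal helpers shared across modules.

clip01 <- function(x, eps = 0) pmin(pmax(x, eps), 1 - eps)

# Adler-32 checksum over serialized bytes (vectorised; doubles stay well
# below 2^53). Used for run manifests so reruns with identical
# configuration and outputs can be recognised; not cryptographic.
fnv1a_hash <- function(object) {
  bytes <- as.numeric(serialize(object, NULL, version = 2L))
  n <- length(bytes)
  m <- 65521
  a <- (1 + sum(bytes)) %% m
  b <- (n + sum((n - seq_len(n) + 1) * bytes)) %% m
  sprintf("%04x%04x", b, a)
}

# Grayscale luma used by the Hough transform, Otsu and mutual information.
to_gray <- function(img) {
  img <- unclass(img)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
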