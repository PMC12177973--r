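# Brute-force oracles, written independently of the package internals.

iou_oracle_acc <- function(p, g) {
  inter <- 0; uni <- 0
  for (i in seq_along(p)) {
    if (p[i] == 1 && g[i] == 1) inter <- inter + 1
    if (p[i] == 1 || g[i] == 1) uni <- uni + 1
  }
  if (uni == 0) 1 else inter / uni
}

bnd_oracle_acc <- function(m) {
  h <- nrow(m); w <- ncol(m)
  at <- function(i, j) if (i < 1 || i > h || j < 1 || j > w) 0L else m[i, j]
  out <- matrix(numeric(0), 0, 2)
  for (i in seq_len(h)) for (j in seq_len(w))
    if (m[i, j] == 1 && (at(i - 1, j) == 0 || at(i + 1, j) == 0 ||
                         at(i, j - 1) == 0 || at(i, j + 1) == 0))
      out <- rbind(out, c(i, j))
  out
}

hd_oracle_acc <- function(p, g) {
  a <- bnd_oracle_acc(p); b <- bnd_oracle_acc(g)
  dmat <- sqrt(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2)
  max(max(apply(dmat, 1, min)), max(apply(dmat, 2, min)))
}

ari_oracle_acc <- function(a, b) {
  n <- length(a)
  s11 <- s10 <- s01 <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) s11 <- s11 + 1
    else if (sa) s10 <- s10 + 1
    else if (sb) s01 <- s01 + 1
  }
  np <- choose(n, 2)
  exp_index <- (s11 + s10) * (s11 + s01) / np
  max_index <- ((s11 + s10) + (s11 + s01)) / 2
  if (max_index == exp_index) return(1)
  (s11 - exp_index) / (max_index - exp_index)
}

# multi-class Dice by direct per-class evaluation; classes absent from
# both labelings are skipped
dice_oracle_acc <- function(x, y) {
  classes <- sort(unique(c(x[x > 0], y[y > 0])))
  vals <- numeric(0)
  for (cl in classes) {
    a <- sum(x == cl); b <- sum(y == cl)
    if (a + b == 0) next
    vals <- c(vals, 2 * sum(x == cl & y == cl) / (a + b))
  }
  mean(vals)
}
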