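# Independent brute-force oracles, deliberately written as plain loops so
# they share no code path with the package implementation.

oracle_density <- function(x, mu, sigma) {
  if (sigma > 0) {
    if (x >= mu - 2 * sigma && x <= mu + 2 * sigma) {
      exp(-(x - mu)^2 / (2 * sigma^2))
    } else {
      -abs(x - mu) / (2 * sigma)
    }
  } else {
    if (x == mu) 1 else -abs(x - mu)
  }
}

oracle_inside <- function(x, mu, sigma) {
  if (sigma > 0) x >= mu - 2 * sigma && x <= mu + 2 * sigma else x == mu
}

oracle_resolve <- function(x, fs) {
  n <- nrow(fs)
  dens <- numeric(n)
  aff <- 0L
  for (i in seq_len(n)) {
    dens[i] <- oracle_density(x, fs$mean[i], fs$sd[i])
    if (oracle_inside(x, fs$mean[i], fs$sd[i])) aff <- aff + 1L
  }
  if (aff > n - aff) max(dens) else min(dens)
}

random_feature_set <- function(k) {
  fs <- data.frame(mean = runif(k, 50, 200),
                   sd = ifelse(runif(k) < 0.1, 0, runif(k, 0.5, 20)),
                   n_pixels = sample(10:500, k, replace = TRUE))
  class(fs) <- c("feature_set", "data.frame")
  fs
}

oracle_metrics <- function(pred, truth) {
  o <- which(pred != 0); g <- which(truth != 0)
  all_px <- seq_len(length(pred))
  b <- setdiff(all_px, g)
  og <- length(intersect(o, g))
  list(fpe = length(intersect(o, b)) / length(g),
       fne = (length(g) - og) / length(g),
       si = 2 * og / (length(o) + length(g)))
}

# Small elliptical mask for geometry tests.
make_disk <- function(n, cx, cy, r) {
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  rows <- matrix(seq_len(n), n, n)
  matrix(as.numeric((cols - cx)^2 + (rows - cy)^2 <= r^2), n, n)
}

boundary_pixels <- function(mask) {
  er <- mask
  er[] <- 0
  nr <- nrow(mask); nc <- ncol(mask)
  inner <- mask[2:(nr - 1), 2:(nc - 1)] & mask[1:(nr - 2), 2:(nc - 1)] &
    mask[3:nr, 2:(nc - 1)] & mask[2:(nr - 1), 1:(nc - 2)] &
    mask[2:(nr - 1), 3:nc]
  er[2:(nr - 1), 2:(nc - 1)] <- as.numeric(inner)
  which(mask != 0 & er == 0, arr.ind = TRUE)
}

hausdorff_dist <- function(mask_a, mask_b) {
  pa <- boundary_pixels(mask_a); pb <- boundary_pixels(mask_b)
  d2 <- outer(pa[, 1], pb[, 1], "-")^2 + outer(pa[, 2], pb[, 2], "-")^2
  max(sqrt(max(apply(d2, 1, min))), sqrt(max(apply(d2, 2, min))))
}

grad_mag <- function(m) {
  gx <- (m[, c(2:ncol(m), ncol(m))] - m[, c(1, 1:(ncol(m) - 1))]) / 2
  gy <- (m[c(2:nrow(m), nrow(m)), ] - m[c(1, 1:(nrow(m) - 1)), ]) / 2
  sqrt(gx^2 + gy^2)
}
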