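# Independent brute-force oracles, deliberately written as plain double
# loops so they share no code with the package implementations.

# Gyration tensor via the pairwise-difference double sum:
# (1/2N^2) sum_{l,m} (r_i(l) - r_i(m)) (r_j(l) - r_j(m))
oracle_gyration <- function(x, y) {
  n <- length(x)
  rxx <- rxy <- ryy <- 0
  for (l in seq_len(n)) {
    for (m in seq_len(n)) {
      rxx <- rxx + (x[l] - x[m])^2
      ryy <- ryy + (y[l] - y[m])^2
      rxy <- rxy + (x[l] - x[m]) * (y[l] - y[m])
    }
  }
  c(rxx = rxx, rxy = rxy, ryy = ryy) / (2 * n^2)
}

# Silhouette with the D_W average running over the full own cluster
# (including the point itself).
oracle_silhouette <- function(x, labels) {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- function(i, j) sqrt(sum((x[i, ] - x[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    dw <- mean(vapply(own, function(j) d(i, j), numeric(1)))
    dd <- Inf
    for (cl in setdiff(unique(labels), labels[i])) {
      members <- which(labels == cl)
      dd <- min(dd, mean(vapply(members, function(j) d(i, j), numeric(1))))
    }
    s[i] <- if (max(dw, dd) > 0) (dd - dw) / max(dw, dd) else 0
  }
  s
}

# Time-averaged MSD over all overlapping pairs at each integer lag.
oracle_msd <- function(x, y, k_max) {
  n <- length(x)
  vapply(seq_len(k_max), function(k) {
    tot <- 0
    for (i in seq_len(n - k)) {
      tot <- tot + (x[i + k] - x[i])^2 + (y[i + k] - y[i])^2
    }
    tot / (n - k)
  }, numeric(1))
}

# Rotate a track table about the origin by `angle` radians.
rotate_track <- function(tracks, angle) {
  co <- cos(angle); si <- sin(angle)
  dplyr::mutate(tracks,
                x_new = co * x_um - si * y_um,
                y_new = si * x_um + co * y_um,
                x_um = x_new, y_um = y_new) |>
    dplyr::select(-x_new, -y_new)
}
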