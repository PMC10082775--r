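# internal numeric helpers

# Deterministic, seedless jitter derived from point index via a splitmix-like
# integer hash.  Magnitude 1e-6 nm: ~7 orders below localization precision,
# guarantees general position for the Delaunay predicates.
.jitter_points <- function(xyz, magnitude = 1e-6) {
  n <- nrow(xyz)
  if (n == 0L) return(xyz)
  idx <- rep(seq_len(n) - 1L, 3L) * 3L + rep(0:2, each = n)
  h <- (idx * 2654435761) %% 4294967296
  h <- (h * 40503 + 9176) %% 4294967296
  u <- h / 4294967296  # in [0,1)
  xyz + matrix((u - 0.5) * magnitude, n, 3L)
}

# squared euclidean distances between rows of a (m x 3) and b (k x 3)
.cross_dist2 <- function(a, b) {
  outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
}

# absolute volumes of tetrahedra; pts (n x 3), tetra (m x 4) index matrix
.tetra_volumes <- function(pts, tetra) {
  if (nrow(tetra) == 0L) return(numeric(0))
  a <- pts[tetra[, 1], , drop = FALSE]
  u <- pts[tetra[, 2], , drop = FALSE] - a
  v <- pts[tetra[, 3], , drop = FALSE] - a
  w <- pts[tetra[, 4], , drop = FALSE] - a
  det <- u[, 1] * (v[, 2] * w[, 3] - v[, 3] * w[, 2]) -
         u[, 2] * (v[, 1] * w[, 3] - v[, 3] * w[, 1]) +
         u[, 3] * (v[, 1] * w[, 2] - v[, 2] * w[, 1])
  abs(det) / 6
}

# longest edge per tetrahedron
.tetra_max_edge <- function(pts, tetra) {
  if (nrow(tetra) == 0L) return(numeric(0))
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  mx <- rep(0, nrow(tetra))
  for (k in seq_len(6)) {
    d <- pts[tetra[, pairs[k, 1]], , drop = FALSE] -
         pts[tetra[, pairs[k, 2]], , drop = FALSE]
    mx <- pmax(mx, sqrt(rowSums(d^2)))
  }
  mx
}
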