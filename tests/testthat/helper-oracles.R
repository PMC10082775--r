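# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (incremental Delaunay, igraph components, findInterval
# counting) so that agreement is a real cross-check.

# O(n^2) cumulative pair count, strict d < r
brute_h <- function(pts, r_grid) {
  d <- numeric(0)
  n <- nrow(pts)
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      d <- c(d, sqrt(sum((pts[i, ] - pts[j, ])^2)))
  vapply(r_grid, function(r) sum(d < r), numeric(1))
}

# O(n^2) half-open histogram of pair distances
brute_pair_hist <- function(pts, epsilon, r_max) {
  n <- nrow(pts)
  counts <- rep(0L, floor(r_max / epsilon))
  for (i in seq_len(n - 1))
    for (j in (i + 1):n) {
      d <- sqrt(sum((pts[i, ] - pts[j, ])^2))
      k <- floor(d / epsilon) + 1
      if (k <= length(counts)) counts[k] <- counts[k] + 1L
    }
  counts
}

# every tetrahedron's circumsphere is empty of all other points
# (the defining property of a Delaunay tetrahedralization)
empty_circumsphere_ok <- function(pts, tetra, rel_tol = 1e-9) {
  n <- nrow(pts)
  for (r in seq_len(nrow(tetra))) {
    v <- tetra[r, ]
    A <- pts[v, , drop = FALSE]
    M <- 2 * (A[1:3, ] - matrix(A[4, ], 3, 3, byrow = TRUE))
    rhs <- rowSums(A[1:3, ]^2) - sum(A[4, ]^2)
    cen <- tryCatch(solve(M, rhs), error = function(e) NULL)
    if (is.null(cen)) next  # flat sliver: no finite circumsphere
    R2 <- sum((A[1, ] - cen)^2)
    d2 <- rowSums((pts - matrix(cen, n, 3, byrow = TRUE))^2)
    d2[v] <- Inf
    if (min(d2) < R2 * (1 - rel_tol)) return(FALSE)
  }
  TRUE
}

# brute-force convex hull volume by facet enumeration (small n only):
# a triple is a hull facet iff all remaining points lie on one side
brute_hull_volume <- function(pts) {
  n <- nrow(pts)
  c0 <- colMeans(pts)
  total <- 0
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    a <- pts[i, ]; b <- pts[j, ]; cc <- pts[k, ]
    nv <- c((b[2] - a[2]) * (cc[3] - a[3]) - (b[3] - a[3]) * (cc[2] - a[2]),
            (b[3] - a[3]) * (cc[1] - a[1]) - (b[1] - a[1]) * (cc[3] - a[3]),
            (b[1] - a[1]) * (cc[2] - a[2]) - (b[2] - a[2]) * (cc[1] - a[1]))
    s <- (pts - matrix(a, n, 3, byrow = TRUE)) %*% nv
    s[c(i, j, k)] <- 0
    tol <- 1e-12 * max(abs(s))
    if (all(s <= tol) || all(s >= -tol))
      total <- total + abs(sum((c0 - a) * nv)) / 6
  }
  total
}

# independent segmentation oracle on a tetra list: per-tet 6-edge check,
# then connected components over shared vertices by breadth-first search
# with plain union-find (no igraph)
brute_segment_labels <- function(pts, tetra, a_max) {
  surv <- logical(nrow(tetra))
  for (r in seq_len(nrow(tetra))) {
    v <- tetra[r, ]
    ok <- TRUE
    for (a in 1:3) for (b in (a + 1):4) {
      if (sqrt(sum((pts[v[a], ] - pts[v[b], ])^2)) >= a_max) ok <- FALSE
    }
    surv[r] <- ok
  }
  parent <- seq_len(nrow(pts))
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (r in which(surv)) {
    v <- tetra[r, ]
    for (b in 2:4) {
      ra <- find(v[1]); rb <- find(v[b])
      if (ra != rb) parent[rb] <- ra
    }
  }
  labels <- rep(NA_integer_, nrow(pts))
  pts_in <- sort(unique(as.vector(tetra[surv, , drop = FALSE])))
  roots <- vapply(pts_in, find, integer(1))
  labels[pts_in] <- match(roots, unique(roots))
  list(survives = surv, point_labels = labels)
}

# dominant covariance eigenvector by power iteration (PCA axis oracle)
power_axis <- function(pts, iters = 500) {
  cv <- cov(pts)
  v <- c(1, 1, 1) / sqrt(3)
  for (i in seq_len(iters)) {
    v <- cv %*% v
    v <- v / sqrt(sum(v^2))
  }
  v <- as.vector(v)
  if (v[3] < 0) v <- -v
  v
}

# small isotropic gaussian cluster fixture
make_cluster <- function(center, n, sd = 30, seed = 1) {
  set.seed(seed)
  cbind(rnorm(n, center[1], sd), rnorm(n, center[2], sd),
        rnorm(n, center[3], sd))
}

# regular tetrahedron with edge a
regular_tetra <- function(a) {
  rbind(c(0, 0, 0), c(a, 0, 0), c(a / 2, a * sqrt(3) / 2, 0),
        c(a / 2, a * sqrt(3) / 6, a * sqrt(2 / 3)))
}

# two-channel toy tables
toy_table <- function(coords, channel) {
  loc_table(x = coords[, 1], y = coords[, 2], z = coords[, 3],
            channel = rep(channel, nrow(coords)))
}
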