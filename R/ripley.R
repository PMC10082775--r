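# 3D inter-distance statistics: cumulative pair counts H(r), the unedged
# Ripley K(r) estimator, L(r) = (3K/4pi)^(1/3), epsilon-binned distance
# histograms and their local maxima (MFDs).

.pair_distances <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2L) return(numeric(0))
  as.vector(dist(points))
}

#' Cumulative pair-count function H(r)
#'
#' `H(r)` counts the unordered point pairs with distance strictly below
#' `r`; once `r` exceeds the largest pairwise distance it equals
#' `n (n - 1) / 2` (all distances counted).
#' With a `subjects` subset, ordered pairs (i in subjects, j != i anywhere)
#' are counted instead -- the interior (minus-sampling) evaluation used to
#' avoid boundary bias.
#'
#' @param points n x 3 coordinate matrix (nm).
#' @param r_grid increasing radii (nm) at which to evaluate.
#' @param subjects optional integer row indices used as pair sources.
#' @return integer pair counts, one per grid radius.
#' @export
cumulative_h <- function(points, r_grid, subjects = NULL) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 2L) {
    warning("fewer than 2 points: H(r) is identically zero")
    return(rep(0, length(r_grid)))
  }
  if (is.null(subjects)) {
    d <- sort(.pair_distances(points))
  } else {
    d2 <- .cross_dist2(points[subjects, , drop = FALSE], points)
    d2[cbind(seq_along(subjects), subjects)] <- Inf  # drop self pairs
    d <- sort(sqrt(pmax(d2, 0)))
  }
  findInterval(r_grid, d, left.open = TRUE)  # strict d < r
}

#' Unedged 3D Ripley K function
#'
#' The plain estimator `K(r) = V n^-2 sum_{i != j} 1(d_ij < r)`, i.e.
#' `2 V n^-2 H(r)`, with no edge correction; near the boundary it is
#' negatively biased, which the interior evaluation (`subjects`) avoids:
#' there `K(r) = V / (n n_I) * C(r)` with `C` the ordered pair count from
#' the `n_I` interior subject points.
#'
#' @inheritParams cumulative_h
#' @param volume analysis volume V in nm^3 (e.g. bounding-box volume).
#' @return K values (nm^3) on the grid.
#' @seealso [interior_subjects()] for the minus-sampling subset.
#' @export
ripley_k <- function(points, volume, r_grid, subjects = NULL) {
  if (!is.numeric(volume) || length(volume) != 1L || volume <= 0)
    stop("volume must be a positive number (nm^3)")
  points <- as.matrix(points)
  n <- nrow(points)
  h <- cumulative_h(points, r_grid, subjects)
  if (is.null(subjects)) 2 * volume * h / n^2
  else volume * h / (n * length(subjects))
}

#' L function and clustering classification
#'
#' `L(r) = (3 K(r) / (4 pi))^(1/3)`, the radius of the sphere whose volume
#' is K under complete spatial randomness (CSR). `L(r) - r > 0` indicates
#' clustering, `< 0` a regular (ordered) pattern, and `= 0` (within
#' `tolerance`) CSR.
#'
#' @param k K values (nm^3), non-negative.
#' @param r_grid the radii K was evaluated at.
#' @param tolerance absolute tolerance (nm) for calling a value CSR.
#' @return list with `l`, `l_minus_r`, and per-radius `classification`
#'   (`"clustered"`, `"regular"`, `"CSR"`).
#' @export
l_function <- function(k, r_grid, tolerance = 1e-8) {
  if (any(k < 0)) stop("K values must be non-negative")
  l <- (3 * k / (4 * pi))^(1 / 3)
  lmr <- l - r_grid
  cls <- ifelse(abs(lmr) <= tolerance, "CSR",
                ifelse(lmr > 0, "clustered", "regular"))
  list(l = l, l_minus_r = lmr, classification = cls)
}

#' Epsilon-binned inter-distance histogram
#'
#' Pair counts per half-open bin `[k e, (k+1) e)` up to `r_max`; identical
#' to differencing the cumulative table H at the bin edges (scanning the
#' volume with a spherical shell of thickness epsilon).
#'
#' @param points n x 3 coordinate matrix (nm).
#' @param epsilon bin width (nm).
#' @param r_max largest radius (nm); must be at least `epsilon`.
#' @param subjects optional interior subset (ordered pair counts).
#' @return list of class `distance_histogram`: `epsilon`, `r_max`,
#'   `bin_start`, `bin_end`, `counts`.
#' @export
distance_histogram <- function(points, epsilon, r_max, subjects = NULL) {
  if (!is.numeric(epsilon) || epsilon <= 0) stop("epsilon must be positive")
  if (r_max < epsilon) stop("r_max must be at least epsilon")
  edges <- seq(0, by = epsilon, length.out = floor(r_max / epsilon) + 1L)
  h <- cumulative_h(points, edges, subjects)
  structure(list(epsilon = epsilon, r_max = edges[length(edges)],
                 bin_start = edges[-length(edges)], bin_end = edges[-1],
                 counts = diff(h)),
            class = "distance_histogram")
}

#' @export
print.distance_histogram <- function(x, ...) {
  cat(sprintf("distance_histogram: %d bins of %g nm up to %g nm, %d pair(s)\n",
              length(x$counts), x$epsilon, x$r_max, sum(x$counts)))
  invisible(x)
}

#' Most frequent distribution values (MFDs) of a histogram
#'
#' Strict local maxima of the bin counts whose height is at least
#' `min_prominence` times the global maximum; endpoints are not eligible.
#' Returned as bin centers, ascending.
#'
#' @param histogram a `distance_histogram`.
#' @param min_prominence fraction of the global maximum (default 0.1).
#' @return numeric vector of MFD radii (nm); empty for flat histograms.
#' @export
find_mfds <- function(histogram, min_prominence = 0.1) {
  stopifnot(inherits(histogram, "distance_histogram"))
  ct <- histogram$counts
  if (length(ct) < 3L || max(ct) == 0) return(numeric(0))
  i <- 2:(length(ct) - 1L)
  is_max <- ct[i] > ct[i - 1L] & ct[i] > ct[i + 1L] &
    ct[i] >= min_prominence * max(ct)
  centers <- (histogram$bin_start + histogram$bin_end) / 2
  sort(centers[i][is_max])
}

#' Ratio of two inter-distance histograms (variation function)
#'
#' Divides the first histogram by the second after normalizing each to
#' unit total, giving a scale-invariant per-bin comparison of two imaged
#' samples. Bins where the second histogram is empty are `NA` (flagged
#' undefined).
#'
#' @param h1,h2 `distance_histogram`s with identical binning.
#' @return list with `bin_start`, `bin_end`, `ratio`, `undefined`.
#' @export
histogram_ratio <- function(h1, h2) {
  stopifnot(inherits(h1, "distance_histogram"),
            inherits(h2, "distance_histogram"))
  if (h1$epsilon != h2$epsilon || h1$r_max != h2$r_max)
    stop("histograms must share epsilon and r_max")
  p1 <- h1$counts / sum(h1$counts)
  p2 <- h2$counts / sum(h2$counts)
  undef <- p2 == 0
  ratio <- ifelse(undef, NA_real_, p1 / p2)
  list(bin_start = h1$bin_start, bin_end = h1$bin_end,
       ratio = ratio, undefined = undef)
}

#' Interior subset of points for minus-sampling
#'
#' Row indices of the points at least `r_max` inside every face of the
#' bounding box (by default the axis-aligned bounding box of the points).
#'
#' @param points n x 3 coordinate matrix (nm).
#' @param r_max margin in nm.
#' @param bounds optional 2 x 3 matrix `rbind(lower, upper)`.
#' @export
interior_subjects <- function(points, r_max, bounds = NULL) {
  points <- as.matrix(points)
  if (is.null(bounds))
    bounds <- rbind(apply(points, 2, min), apply(points, 2, max))
  lo <- bounds[1, ] + r_max
  hi <- bounds[2, ] - r_max
  which(points[, 1] >= lo[1] & points[, 1] <= hi[1] &
        points[, 2] >= lo[2] & points[, 2] <= hi[2] &
        points[, 3] >= lo[3] & points[, 3] <= hi[3])
}

#' Full Ripley analysis on a radius grid
#'
#' Convenience wrapper computing H, K, L, L - r, the epsilon-binned
#' histogram and its MFDs in one pass.
#'
#' @param points n x 3 coordinate matrix or [loc_table].
#' @param epsilon grid step / bin width (nm), default 10.
#' @param r_max largest radius (nm), default 5000 (spans intra-nucleoid,
#'   intra-cluster and inter-nucleoid distance ranges).
#' @param volume analysis volume in nm^3; default: bounding box of the
#'   points.
#' @param interior if TRUE, pair counts are restricted to source points at
#'   least `r_max` inside the bounding box (removes boundary bias for CSR
#'   testing); K then uses the minus-sampling normalization.
#' @param min_prominence MFD prominence threshold.
#' @return list of class `ripley_result` with `r_grid`, `h`, `k`, `l`,
#'   `l_minus_r`, `classification`, `histogram`, `mfds`, `n`, `volume`.
#' @export
ripley_result <- function(points, epsilon = 10, r_max = 5000,
                          volume = NULL, interior = FALSE,
                          min_prominence = 0.1) {
  if (is.loc_table(points)) points <- loc_coords(points)
  points <- as.matrix(points)
  if (is.null(volume)) {
    rng <- apply(points, 2, range)
    volume <- prod(rng[2, ] - rng[1, ])
  }
  subjects <- if (interior) interior_subjects(points, r_max) else NULL
  r_grid <- seq(epsilon, by = epsilon, length.out = floor(r_max / epsilon))
  h <- cumulative_h(points, r_grid, subjects)
  k <- if (is.null(subjects)) 2 * volume * h / nrow(points)^2
       else volume * h / (nrow(points) * length(subjects))
  lf <- l_function(k, r_grid)
  hist <- structure(list(epsilon = epsilon, r_max = r_grid[length(r_grid)],
                         bin_start = c(0, r_grid[-length(r_grid)]),
                         bin_end = r_grid,
                         counts = diff(c(0L, h))),
                    class = "distance_histogram")
  structure(list(r_grid = r_grid, h = h, k = k, l = lf$l,
                 l_minus_r = lf$l_minus_r,
                 classification = lf$classification,
                 histogram = hist,
                 mfds = find_mfds(hist, min_prominence),
                 n = nrow(points), n_subjects = length(subjects),
                 volume = volume, r_max = r_max, epsilon = epsilon),
            class = "ripley_result")
}

#' @export
print.ripley_result <- function(x, ...) {
  cat(sprintf(
    "ripley_result: n = %d, V = %.4g nm^3, r <= %g nm (step %g nm)\n",
    x$n, x$volume, x$r_max, x$epsilon))
  cat(sprintf("  mean L(r)-r = %.3g nm; MFDs at {%s} nm\n",
              mean(x$l_minus_r), paste(x$mfds, collapse = ", ")))
  invisible(x)
}
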