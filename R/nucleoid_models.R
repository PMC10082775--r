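#' Volume-equivalent sphere model of a segmented nucleoid
#'
#' Approximates a segmented object by spheres of equal volume: `d_d` is the
#' diameter of the sphere whose volume equals the polyhedron volume V_D,
#' and `d_smooth` the diameter for the smoothed (convexified) polyhedron,
#' i.e. the convex hull of the member localizations (tetrahedra added to
#' obtain a convex shape).
#'
#' @param object a `segmented_object`.
#' @param complex the `tetra_complex` it came from.
#' @return list of class `sphere_model`: `d_d`, `d_smooth` (nm), `v_d`,
#'   `v_smooth` (nm^3), `degenerate` flag.
#' @export
sphere_model <- function(object, complex) {
  stopifnot(inherits(object, "segmented_object"))
  v_d <- object$volume_vd
  pts <- complex$points[object$member_points, , drop = FALSE]
  v_smooth <- if (nrow(pts) >= 4L) convex_hull_volume(pts) else 0
  degenerate <- v_d <= 0
  structure(list(d_d = sphere_diameter(v_d),
                 d_smooth = sphere_diameter(v_smooth),
                 v_d = v_d, v_smooth = v_smooth,
                 degenerate = degenerate),
            class = "sphere_model")
}

#' Diameter of the sphere with a given volume
#' @param volume volume in nm^3.
#' @return diameter `(6 V / pi)^(1/3)` in nm.
#' @export
sphere_diameter <- function(volume) (6 * volume / pi)^(1 / 3)

#' PCA rotational-ellipsoid model of a segmented nucleoid
#'
#' Refines the sphere model by principal component analysis of the member
#' localizations. The longest axis is the principal eigenvector of the
#' coordinate covariance (sign chosen so the z component is >= 0); the
#' aspect ratio d_max/d_min is `sqrt(l1) / sqrt((l2 + l3)/2)` of the
#' covariance eigenvalues (a rotational ellipsoid has two equal short
#' axes), and the absolute scale is fixed so the ellipsoid volume
#' `(pi/6) d_max d_min^2` equals the polyhedron volume V_D.
#'
#' @param object a `segmented_object`.
#' @param complex the `tetra_complex` it came from.
#' @return list of class `ellipsoid_model`: `d_max`, `d_min` (nm), `axis`
#'   (unit vector), `theta` (degrees from the z axis, in 0..90), `a_r`
#'   (radial projection of the axis), `degenerate` flag.
#' @export
ellipsoid_model <- function(object, complex) {
  stopifnot(inherits(object, "segmented_object"))
  pts <- complex$points[object$member_points, , drop = FALSE]
  v_d <- object$volume_vd
  if (nrow(pts) < 4L || v_d <= 0)
    return(structure(list(d_max = NA_real_, d_min = NA_real_,
                          axis = c(NA, NA, NA), theta = NA_real_,
                          a_r = NA_real_, degenerate = TRUE),
                     class = "ellipsoid_model"))
  cv <- cov(pts)
  eg <- eigen(cv, symmetric = TRUE)
  if (eg$values[3] <= 0 || eg$values[1] <= 0)
    return(structure(list(d_max = NA_real_, d_min = NA_real_,
                          axis = c(NA, NA, NA), theta = NA_real_,
                          a_r = NA_real_, degenerate = TRUE),
                     class = "ellipsoid_model"))
  axis <- eg$vectors[, 1]
  if (axis[3] < 0) axis <- -axis
  ratio <- sqrt(eg$values[1]) / sqrt(mean(eg$values[2:3]))
  # (pi/6) d_max d_min^2 = V_D with d_max = ratio * d_min
  d_min <- (6 * v_d / (pi * ratio))^(1 / 3)
  d_max <- ratio * d_min
  structure(list(d_max = d_max, d_min = d_min, axis = axis,
                 theta = axis_theta(axis), a_r = sqrt(sum(axis[1:2]^2)),
                 degenerate = FALSE),
            class = "ellipsoid_model")
}

#' Orientation angle and axial ratio of an ellipsoid axis
#'
#' `axis_theta()` is the angle theta (degrees, in 0..90) between a
#' direction vector and the optical (z) axis, computed as
#' `atan(sqrt(ax^2 + ay^2) / |az|)`. `axis_ratio()` is the ratio
#' `|A_r / a_z|` of the radial projection to the axial component, which
#' equals `tan(theta)` and crosses 1 exactly at theta = 45 degrees.
#'
#' @param axis numeric length-3 direction vector (need not be unit).
#' @export
axis_theta <- function(axis) {
  stopifnot(length(axis) == 3L)
  atan2(sqrt(sum(axis[1:2]^2)), abs(axis[3])) * 180 / pi
}

#' @rdname axis_theta
#' @export
axis_ratio <- function(axis) {
  stopifnot(length(axis) == 3L)
  sqrt(sum(axis[1:2]^2)) / abs(axis[3])
}

#' Filter ellipsoid models by orientation
#'
#' Localization precision along the optical axis is worse than lateral, so
#' objects elongated along z are the likelier reconstruction artifacts;
#' the default therefore excludes models with theta < `theta_cut` (longest
#' axis near z). The boundary theta == `theta_cut` is always kept.
#'
#' @param models list of `ellipsoid_model`.
#' @param theta_cut angle in degrees, strictly inside (0, 90).
#' @param keep `"above"` (default: keep theta >= cut) or `"below"`
#'   (keep theta <= cut).
#' @return the retained sublist; degenerate models are dropped.
#' @export
orientation_filter <- function(models, theta_cut = 45,
                               keep = c("above", "below")) {
  keep <- match.arg(keep)
  if (!is.numeric(theta_cut) || length(theta_cut) != 1L ||
      theta_cut <= 0 || theta_cut >= 90)
    stop("theta_cut must lie strictly between 0 and 90 degrees")
  sel <- vapply(models, function(m) {
    if (isTRUE(m$degenerate) || is.na(m$theta)) return(FALSE)
    if (keep == "above") m$theta >= theta_cut else m$theta <= theta_cut
  }, logical(1))
  models[sel]
}

#' Fixed-width diameter histogram with its mode (MFD)
#'
#' Histograms diameters into fixed-width bins anchored at 0 and reports
#' the most frequent distribution value (MFD): the center of a maximal
#' bin, the smallest such bin winning ties.
#'
#' @param diameters numeric vector of diameters (nm).
#' @param bin_width bin width in nm (default 10).
#' @return list of class `diameter_distribution`: `bin_edges`, `counts`,
#'   `mfd` (NA and flagged when empty).
#' @export
diameter_distribution <- function(diameters, bin_width = 10) {
  if (!is.numeric(bin_width) || bin_width <= 0)
    stop("bin_width must be positive")
  diameters <- diameters[is.finite(diameters)]
  if (!length(diameters)) {
    return(structure(list(bin_edges = numeric(0), counts = integer(0),
                          mfd = NA_real_, empty = TRUE),
                     class = "diameter_distribution"))
  }
  nb <- floor(max(diameters) / bin_width) + 1L
  edges <- seq(0, nb * bin_width, by = bin_width)
  idx <- pmin(floor(diameters / bin_width) + 1L, nb)
  counts <- tabulate(idx, nbins = nb)
  mode_bin <- which.max(counts)  # first (smallest) maximal bin
  structure(list(bin_edges = edges, counts = counts,
                 mfd = (mode_bin - 0.5) * bin_width, empty = FALSE),
            class = "diameter_distribution")
}

#' @export
print.diameter_distribution <- function(x, ...) {
  if (isTRUE(x$empty)) cat("diameter_distribution: empty (MFD undefined)\n")
  else cat(sprintf("diameter_distribution: %d value(s), MFD = %g nm\n",
                   sum(x$counts), x$mfd))
  invisible(x)
}
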