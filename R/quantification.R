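#' Nucleoid spatial density
#'
#' Number of nucleoids per cubic micrometer of analyzed volume, used in
#' place of per-cell counts when the cell volume is unknown. The analysis
#' volume defaults to the convex hull of all localizations (the imaged
#' cytoplasmic region); a degenerate (flat) hull falls back to the
#' bounding box with a warning.
#'
#' @param records list of `nucleoid_record`s or an `overlap_result`, or a
#'   plain count of nucleoids.
#' @param localizations [loc_table] or n x 3 matrix defining the analyzed
#'   volume.
#' @param volume_method `"hull"` (default) or `"bbox"`.
#' @return list of class `density_result`: `n_nucleoids`,
#'   `analysis_volume_nm3`, `analysis_volume_um3`, `rho_nucl`
#'   (nucleoids/um^3), `volume_method`.
#' @export
nucleoid_density <- function(records, localizations,
                             volume_method = c("hull", "bbox")) {
  volume_method <- match.arg(volume_method)
  n <- if (inherits(records, "overlap_result")) length(records$records)
       else if (is.numeric(records) && length(records) == 1L) records
       else length(records)
  pts <- if (is.loc_table(localizations)) loc_coords(localizations)
         else as.matrix(localizations)
  if (nrow(pts) < 1L) stop("need at least one localization to define a volume")
  vol <- if (volume_method == "hull") convex_hull_volume(pts) else NA
  if (volume_method == "hull" && (!is.finite(vol) || vol <= 0)) {
    warning("degenerate convex hull: falling back to bounding box")
    volume_method <- "bbox"
  }
  if (volume_method == "bbox") {
    rng <- apply(pts, 2, range)
    vol <- prod(rng[2, ] - rng[1, ])
  }
  structure(list(n_nucleoids = n,
                 analysis_volume_nm3 = vol,
                 analysis_volume_um3 = vol / 1e9,
                 rho_nucl = n / (vol / 1e9),
                 volume_method = volume_method),
            class = "density_result")
}

#' @export
print.density_result <- function(x, ...) {
  cat(sprintf(
    "density_result: %d nucleoid(s) in %.4g um^3 (%s) -> rho_nucl = %.4g /um^3\n",
    x$n_nucleoids, x$analysis_volume_um3, x$volume_method, x$rho_nucl))
  invisible(x)
}

#' Fold change between two nucleoid densities
#'
#' @param a,b `density_result`s; returns `a$rho_nucl / b$rho_nucl`.
#' @export
fold_change <- function(a, b) {
  stopifnot(inherits(a, "density_result"), inherits(b, "density_result"))
  if (b$rho_nucl <= 0) stop("reference density must be positive")
  a$rho_nucl / b$rho_nucl
}

#' mtDNA copy number from qPCR amplicon amounts
#'
#' The ratio between the mitochondrial amplicon amount and half of the
#' nuclear amplicon amount (the nuclear genome is diploid) estimates the
#' number of mtDNA molecules per cell.
#'
#' @param mito_amount mitochondrial amplicon amount (arbitrary units).
#' @param nuclear_amount nuclear amplicon amount (same units), > 0.
#' @return list of class `copy_number`: inputs and `c_n`.
#' @export
copy_number <- function(mito_amount, nuclear_amount) {
  if (!is.numeric(mito_amount) || !is.numeric(nuclear_amount))
    stop("amplicon amounts must be numeric")
  if (any(nuclear_amount <= 0)) stop("nuclear_amount must be positive")
  if (any(mito_amount < 0)) stop("mito_amount must be non-negative")
  structure(list(mito_amplicon_amount = mito_amount,
                 nuclear_amplicon_amount = nuclear_amount,
                 c_n = mito_amount / (nuclear_amount / 2)),
            class = "copy_number")
}

#' @export
print.copy_number <- function(x, ...) {
  cat(sprintf("copy_number: C_N = %.4g copies/cell\n", x$c_n))
  invisible(x)
}
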