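# VTK legacy ASCII export for 3D viewers (ParaView and friends).

#' Export localizations as VTK polydata points
#'
#' Writes a legacy-format VTK file with one vertex per localization and
#' the channel as point scalars, for rendering scenes in a VTK-based 3D
#' viewer.
#'
#' @param table a [loc_table] (or n x 3 matrix).
#' @param path output `.vtk` path.
#' @param scalars optional numeric per-point scalar (defaults to the
#'   channel; e.g. a disposition code from [count_overlaps()]).
#' @export
write_vtk_points <- function(table, path, scalars = NULL) {
  pts <- if (is.loc_table(table)) loc_coords(table) else as.matrix(table)
  n <- nrow(pts)
  if (is.null(scalars))
    scalars <- if (is.loc_table(table)) table$channel else rep(1, n)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "localization point cloud", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d float", n)), con)
  writeLines(apply(pts, 1, function(p) paste(format(p, trim = TRUE),
                                             collapse = " ")), con)
  writeLines(sprintf("VERTICES %d %d", n, 2L * n), con)
  writeLines(paste(1L, seq_len(n) - 1L), con)
  writeLines(c(sprintf("POINT_DATA %d", n),
               "SCALARS channel float 1", "LOOKUP_TABLE default"), con)
  writeLines(format(as.numeric(scalars), trim = TRUE), con)
  invisible(path)
}

#' Export surviving tetrahedra as a VTK unstructured grid
#'
#' Writes the surviving tetrahedra of a culled complex (optionally only
#' those of one segmented object) with the object label as cell scalars.
#'
#' @param complex a culled `tetra_complex`.
#' @param path output `.vtk` path.
#' @param segmentation optional `segmentation` whose object ids label the
#'   cells.
#' @export
write_vtk_tetrahedra <- function(complex, path, segmentation = NULL) {
  stopifnot(inherits(complex, "tetra_complex"))
  if (is.null(complex$survives))
    stop("apply cull_tetrahedra() before export")
  sel <- which(complex$survives)
  labels <- rep(0, length(sel))
  if (!is.null(segmentation)) {
    for (o in segmentation$objects)
      labels[match(o$member_tetra, sel)] <- o$id
  }
  tt <- complex$tetra[sel, , drop = FALSE]
  n <- nrow(complex$points)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "culled Delaunay tetrahedra", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d float", n)), con)
  writeLines(apply(complex$points, 1,
                   function(p) paste(format(p, trim = TRUE),
                                     collapse = " ")), con)
  writeLines(sprintf("CELLS %d %d", nrow(tt), 5L * nrow(tt)), con)
  writeLines(apply(tt - 1L, 1,
                   function(v) paste(c(4L, v), collapse = " ")), con)
  writeLines(sprintf("CELL_TYPES %d", nrow(tt)), con)
  writeLines(rep("10", nrow(tt)), con)  # VTK_TETRA
  writeLines(c(sprintf("CELL_DATA %d", nrow(tt)),
               "SCALARS object float 1", "LOOKUP_TABLE default"), con)
  writeLines(format(as.numeric(labels), trim = TRUE), con)
  invisible(path)
}
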