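#' 3D Delaunay tessellation of a localization point set
#'
#' Tetrahedralizes a set of 3D points (nm). Exact duplicate coordinates are
#' collapsed to a single representative before tessellation (the original
#' rows are retained so per-object localization counts keep multiplicity).
#' A deterministic jitter of 1e-6 nm, derived from the point index, is
#' applied inside the Delaunay predicates so that degenerate
#' (coplanar/cospherical) configurations are in general position; stored
#' coordinates, edge lengths and volumes all use the original positions.
#'
#' @param points numeric matrix (n x 3) of x, y, z coordinates in nm, or a
#'   [loc_table] (in which case `channel` is taken from it).
#' @param channel optional integer vector of per-row channel labels.
#' @return an object of class `tetra_complex`: a list with elements
#'   `points` (unique coordinates), `tetra` (m x 4 vertex index
#'   matrix), `max_edge` and `volume` per tetrahedron, `dup_of` mapping
#'   each original row to its unique point, `channel`, and culling state
#'   (`survives`, `a_max`, set by [cull_tetrahedra()]).
#' @details Fewer than 4 unique points (or a rank-deficient configuration)
#'   raises a condition of class `nucleotess_degenerate`; callers that can
#'   treat such sets as zero-volume objects should catch it.
#' @seealso [cull_tetrahedra()], [segment()], [polyhedron_volume()]
#' @export
delaunay_tessellate <- function(points, channel = NULL) {
  if (is.loc_table(points)) {
    channel <- points$channel
    points <- loc_coords(points)
  }
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  stopifnot(ncol(points) == 3L)
  if (anyNA(points) || any(!is.finite(points)))
    stop("coordinates must be finite")
  n_orig <- nrow(points)
  key <- paste(points[, 1], points[, 2], points[, 3], sep = "\r")
  uniq <- !duplicated(key)
  upts <- points[uniq, , drop = FALSE]
  dup_of <- match(key, key[uniq])
  n_dup <- n_orig - nrow(upts)
  if (n_dup > 0L)
    message(sprintf("collapsed %d duplicate coordinate(s) for tessellation",
                    n_dup))
  if (nrow(upts) < 4L) {
    cond <- structure(
      class = c("nucleotess_degenerate", "error", "condition"),
      list(message = "fewer than 4 unique points: zero-volume object",
           call = sys.call(-1)))
    stop(cond)
  }
  sv <- svd(scale(upts, center = TRUE, scale = FALSE), nu = 0, nv = 0)$d
  if (sv[3] <= 1e-9 * sv[1])
    warning("coplanar/collinear configuration: resolved by the ",
            "deterministic 1e-6 nm jitter; volumes are near zero")
  # jitter is applied only inside the Delaunay predicates; all stored
  # coordinates, edge lengths and volumes use the original positions (a
  # triangulation valid for the perturbed points is a valid -- possibly
  # partly flat -- triangulation of the originals, so volume sums are exact)
  jpts <- .jitter_points(upts)
  tetra <- tryCatch(
    .delaunay3d_cpp(jpts),
    error = function(e) {
      if (grepl("span 3 dimensions", conditionMessage(e))) {
        cond <- structure(
          class = c("nucleotess_degenerate", "error", "condition"),
          list(message = conditionMessage(e), call = sys.call(-1)))
        stop(cond)
      }
      stop(e)
    })
  structure(
    list(points = upts,
         tetra = tetra,
         max_edge = .tetra_max_edge(upts, tetra),
         volume = .tetra_volumes(upts, tetra),
         dup_of = dup_of,
         channel = channel,
         survives = NULL,
         a_max = NA_real_),
    class = "tetra_complex")
}

#' @export
print.tetra_complex <- function(x, ...) {
  cat(sprintf("tetra_complex: %d points (%d rows), %d tetrahedra",
              nrow(x$points), length(x$dup_of), nrow(x$tetra)))
  if (!is.na(x$a_max))
    cat(sprintf("; culled at A_max = %g nm (%d survive)",
                x$a_max, sum(x$survives)))
  cat("\n")
  invisible(x)
}

#' Cull tetrahedra by the maximum-edge threshold A_max
#'
#' A tetrahedron survives iff all six of its edges are strictly shorter
#' than `a_max` (nm). Surviving connected tetrahedra are what [segment()]
#' groups into objects (rough nucleoid models).
#'
#' @param complex a `tetra_complex` from [delaunay_tessellate()].
#' @param a_max positive edge-length threshold in nm.
#' @return the complex with `survives` and `a_max` set.
#' @export
cull_tetrahedra <- function(complex, a_max) {
  stopifnot(inherits(complex, "tetra_complex"))
  if (!is.numeric(a_max) || length(a_max) != 1L || !is.finite(a_max) ||
      a_max <= 0)
    stop("a_max must be a positive number (nm)")
  complex$survives <- complex$max_edge < a_max
  complex$a_max <- a_max
  complex
}

#' Segment surviving tetrahedra into connected objects
#'
#' Groups surviving tetrahedra into connected components and returns the
#' segmented objects together with the exclusion set (localizations in no
#' surviving tetrahedron -- the "green points" of a rendered scene).
#'
#' @param complex a culled `tetra_complex`.
#' @param connectivity `"vertex"` (default: tetrahedra sharing at least one
#'   vertex are connected, so no localization can belong to two objects) or
#'   `"face"` (sharing a triangular face; a vertex shared between two
#'   face-components is assigned to the lower-indexed object to preserve
#'   the partition property).
#' @return a list of class `segmentation` with `objects` (list of
#'   `segmented_object`: `member_points` unique-point ids, `member_rows`
#'   original row ids, `member_tetra`, `volume_vd` nm^3, `channel_counts`,
#'   `n_localizations`) and `exclusion` (original row ids).
#' @export
segment <- function(complex, connectivity = c("vertex", "face")) {
  stopifnot(inherits(complex, "tetra_complex"))
  connectivity <- match.arg(connectivity)
  if (is.null(complex$survives))
    stop("apply cull_tetrahedra() before segment()")
  n_upts <- nrow(complex$points)
  surv <- which(complex$survives)
  tet <- complex$tetra[surv, , drop = FALSE]
  if (nrow(tet) == 0L) {
    return(structure(list(objects = list(),
                          exclusion = seq_along(complex$dup_of),
                          complex = complex),
                     class = "segmentation"))
  }
  if (connectivity == "vertex") {
    edges <- rbind(cbind(tet[, 1], tet[, 2]),
                   cbind(tet[, 1], tet[, 3]),
                   cbind(tet[, 1], tet[, 4]))
    g <- igraph::graph_from_edgelist(matrix(as.character(edges), ncol = 2),
                                     directed = FALSE)
    comp <- igraph::components(g)
    vert_ids <- as.integer(igraph::V(g)$name)
    memb <- comp$membership
    tet_comp <- memb[match(as.character(tet[, 1]), igraph::V(g)$name)]
    pt_comp <- rep(NA_integer_, n_upts)
    pt_comp[vert_ids] <- memb
  } else {
    # face connectivity: tetrahedra adjacent iff they share 3 vertices
    faces <- rbind(tet[, c(2, 3, 4)], tet[, c(1, 3, 4)],
                   tet[, c(1, 2, 4)], tet[, c(1, 2, 3)])
    faces <- t(apply(faces, 1L, sort))
    fkey <- paste(faces[, 1], faces[, 2], faces[, 3], sep = ".")
    ftet <- rep(seq_len(nrow(tet)), 4L)
    dupk <- fkey[duplicated(fkey)]
    idx <- split(ftet, fkey)
    pair <- idx[lengths(idx) == 2L]
    g <- igraph::make_empty_graph(n = nrow(tet), directed = FALSE)
    if (length(pair))
      g <- igraph::add_edges(g, unlist(pair))
    tet_comp <- igraph::components(g)$membership
    # vertex shared between components -> lower object index wins
    pt_comp <- rep(NA_integer_, n_upts)
    ord <- order(tet_comp)
    for (t in ord) {
      vs <- tet[t, ]
      fill <- vs[is.na(pt_comp[vs])]
      pt_comp[fill] <- tet_comp[t]
    }
  }
  # deterministic object order independent of input row order: sort
  # components by member-centroid (x, y, z) lexicographically
  comp_ids <- sort(unique(tet_comp))
  cent <- t(vapply(comp_ids, function(cid) {
    vs <- unique(as.vector(tet[tet_comp == cid, , drop = FALSE]))
    colMeans(complex$points[vs, , drop = FALSE])
  }, numeric(3)))
  comp_ids <- comp_ids[order(cent[, 1], cent[, 2], cent[, 3])]
  objects <- vector("list", length(comp_ids))
  for (k in seq_along(comp_ids)) {
    cid <- comp_ids[k]
    tets_k <- surv[tet_comp == cid]
    pts_k <- sort(unique(as.vector(complex$tetra[tets_k, , drop = FALSE])))
    if (connectivity == "face")
      pts_k <- pts_k[pt_comp[pts_k] == cid]
    rows_k <- which(complex$dup_of %in% pts_k)
    cc <- if (is.null(complex$channel)) NULL else
      table(channel = complex$channel[rows_k])
    objects[[k]] <- structure(
      list(id = k,
           member_points = pts_k,
           member_rows = rows_k,
           member_tetra = tets_k,
           volume_vd = sum(complex$volume[tets_k]),
           channel_counts = cc,
           n_localizations = length(rows_k)),
      class = "segmented_object")
  }
  assigned <- unlist(lapply(objects, `[[`, "member_rows"))
  structure(list(objects = objects,
                 exclusion = setdiff(seq_along(complex$dup_of), assigned),
                 complex = complex),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("segmentation: %d object(s), %d excluded localization(s)\n",
              length(x$objects), length(x$exclusion)))
  invisible(x)
}

#' @export
print.segmented_object <- function(x, ...) {
  cat(sprintf(
    "segmented_object %d: %d localizations (%d unique), %d tetrahedra, V_D = %.4g nm^3\n",
    x$id, x$n_localizations, length(x$member_points),
    length(x$member_tetra), x$volume_vd))
  invisible(x)
}

#' Polyhedron volume of a segmented object
#'
#' Sum of the absolute volumes of the object's member tetrahedra, i.e. the
#' volume V_D of the polyhedron that models the nucleoid.
#'
#' @param object a `segmented_object`.
#' @param complex the `tetra_complex` it was segmented from.
#' @return volume in nm^3.
#' @export
polyhedron_volume <- function(object, complex) {
  stopifnot(inherits(object, "segmented_object"),
            inherits(complex, "tetra_complex"))
  sum(.tetra_volumes(complex$points,
                     complex$tetra[object$member_tetra, , drop = FALSE]))
}

#' Filter objects by minimum localization count
#'
#' Keeps objects reconstructed from strictly more than `min_points`
#' localizations (default 10, the reporting threshold for nucleoids).
#'
#' @param objects list of `segmented_object`.
#' @param min_points non-negative count; strict inequality is applied.
#' @export
filter_min_localizations <- function(objects, min_points = 10) {
  stopifnot(min_points >= 0)
  Filter(function(o) o$n_localizations > min_points, objects)
}

#' Convex hull volume of a 3D point set
#'
#' The union of all Delaunay tetrahedra of a point set is its convex hull,
#' so the hull volume is the sum of all tetrahedron volumes of the
#' (unculled) tessellation. Degenerate sets (fewer than 4 unique points or
#' not spanning 3 dimensions) have volume 0.
#'
#' @param points numeric matrix (n x 3), nm.
#' @return volume in nm^3.
#' @export
convex_hull_volume <- function(points) {
  cx <- tryCatch(delaunay_tessellate(points),
                 nucleotess_degenerate = function(e) NULL)
  if (is.null(cx)) return(0)
  sum(cx$volume)
}
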