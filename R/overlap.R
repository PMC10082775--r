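# Two-step overlap procedure: mixed-channel Delaunay segmentation, followed
# by per-channel re-tessellation inside each mixed object; probe-channel
# components become hybridization loci, and the loci counted within each
# refined nucleoid give n_mtDNA per nucleoid.

.locus_new <- function(rows, coords) {
  extent <- if (nrow(coords) > 1L) max(dist(coords)) else 0
  structure(list(member_rows = rows,
                 coords = coords,
                 centroid = colMeans(coords),
                 extent = extent,
                 singleton = nrow(coords) == 1L),
            class = "probe_locus")
}

#' Mixed-channel segmentation (first step of the overlap procedure)
#'
#' Pools both channels into one point set (channel labels retained),
#' tessellates, culls at `a_max_mixed` and segments, so that nucleoids are
#' identified together with their attached probe loci.
#'
#' @param nucleoid_ch,probe_ch [loc_table]s of the nucleoid-stain and
#'   probe channels (registered, nm).
#' @param a_max_mixed culling threshold in nm (default 80).
#' @return a `segmentation` whose `pooled` element is the combined
#'   [loc_table] (nucleoid rows first).
#' @export
mixed_segmentation <- function(nucleoid_ch, probe_ch, a_max_mixed = 80) {
  if (nrow(nucleoid_ch) == 0L) {
    warning("empty nucleoid channel: nothing to segment")
    empty <- structure(list(objects = list(), exclusion = integer(0),
                            complex = NULL, pooled = nucleoid_ch),
                       class = "segmentation")
    return(empty)
  }
  pooled <- rbind(as.data.frame(nucleoid_ch), as.data.frame(probe_ch))
  cx <- delaunay_tessellate(as.matrix(pooled[, c("x", "y", "z")]),
                            channel = pooled$channel)
  seg <- segment(cull_tetrahedra(cx, a_max_mixed))
  seg$pooled <- pooled
  seg
}

# segment a (possibly tiny) point subset; for < 4 unique points or
# rank-deficient sets fall back to single-linkage clustering at a_max,
# yielding zero-volume objects
.segment_subset <- function(coords, rows, a_max) {
  res <- tryCatch({
    cx <- delaunay_tessellate(coords)
    seg <- segment(cull_tetrahedra(cx, a_max))
    list(seg = seg, complex = cx)
  }, nucleotess_degenerate = function(e) NULL)
  if (!is.null(res)) {
    objs <- lapply(res$seg$objects, function(o) {
      o$member_rows <- rows[o$member_rows]
      o
    })
    leftover <- rows[res$seg$exclusion]
    leftover_coords <- coords[res$seg$exclusion, , drop = FALSE]
    return(list(objects = objs, complex = res$complex,
                leftover_rows = leftover, leftover_coords = leftover_coords))
  }
  # degenerate: single-linkage components at a_max, volume 0
  comp <- .single_linkage(coords, a_max)
  objs <- lapply(sort(unique(comp)), function(cid) {
    sel <- comp == cid
    structure(list(id = cid,
                   member_points = which(sel),
                   member_rows = rows[sel],
                   member_tetra = integer(0),
                   volume_vd = 0,
                   channel_counts = NULL,
                   n_localizations = sum(sel)),
              class = "segmented_object")
  })
  list(objects = objs, complex = NULL,
       leftover_rows = integer(0),
       leftover_coords = coords[0, , drop = FALSE])
}

# single-linkage components at threshold (<=) on a small coordinate set
.single_linkage <- function(coords, threshold) {
  n <- nrow(coords)
  if (n == 1L) return(1L)
  d <- as.matrix(dist(coords))
  g <- igraph::graph_from_adjacency_matrix(d <= threshold, mode = "undirected",
                                           diag = FALSE)
  igraph::components(g)$membership
}

#' Per-channel refinement inside one mixed object (second step)
#'
#' Re-tessellates the nucleoid-channel localizations of a mixed object at
#' `a_max_nucleoid` (yielding refined nucleoid sub-objects) and the
#' probe-channel localizations at `a_max_probe`; each connected probe
#' component becomes one candidate locus. Probe localizations covered by
#' no surviving tetrahedron become singleton loci (a single probe blink
#' still marks a hybridized locus), so no probe localization is discarded.
#'
#' @param mixed_object a `segmented_object` from [mixed_segmentation()].
#' @param pooled the pooled [loc_table] of the mixed segmentation.
#' @param a_max_nucleoid culling threshold (nm) for the nucleoid channel
#'   (typically the most frequent first-pass diameter, see
#'   [count_overlaps()]).
#' @param a_max_probe culling threshold (nm) for the probe channel
#'   (default 80 = the maximum probe extension).
#' @param nucleoid_channel,probe_channel channel labels (defaults 1 and 2).
#' @return list with `nucleoids` (sub-objects; `member_rows` index
#'   `pooled`), `nucleoid_complex`, `loci` (list of `probe_locus`),
#'   `excluded_rows` (nucleoid-channel rows in no surviving tetrahedron).
#' @export
refine_per_channel <- function(mixed_object, pooled, a_max_nucleoid,
                               a_max_probe = 80,
                               nucleoid_channel = 1L, probe_channel = 2L) {
  rows <- mixed_object$member_rows
  ch <- pooled$channel[rows]
  nuc_rows <- rows[ch == nucleoid_channel]
  pr_rows <- rows[ch == probe_channel]
  if (length(nuc_rows) == 0L)
    stop("mixed object contains no nucleoid-channel localization")
  coords <- as.matrix(pooled[, c("x", "y", "z")])
  nres <- .segment_subset(coords[nuc_rows, , drop = FALSE], nuc_rows,
                          a_max_nucleoid)
  loci <- list()
  if (length(pr_rows) > 0L) {
    pres <- .segment_subset(coords[pr_rows, , drop = FALSE], pr_rows,
                            a_max_probe)
    loci <- lapply(pres$objects, function(o)
      .locus_new(o$member_rows, coords[o$member_rows, , drop = FALSE]))
    # uncovered probe points: one singleton locus each
    if (length(pres$leftover_rows))
      loci <- c(loci, lapply(seq_along(pres$leftover_rows), function(i)
        .locus_new(pres$leftover_rows[i],
                   pres$leftover_coords[i, , drop = FALSE])))
  }
  list(nucleoids = nres$objects,
       nucleoid_complex = nres$complex,
       loci = loci,
       excluded_rows = nres$leftover_rows)
}

#' Merge loci closer than the probe extent
#'
#' Loci whose member localizations are single-linkage connected at
#' `max_extent` (nm) are unioned into one locus: multiple blinking within
#' a spatial region smaller than the maximum probe extension is one
#' hybridized mtDNA locus. The result is independent of input order.
#'
#' @param loci list of `probe_locus` belonging to one nucleoid/object.
#' @param max_extent merge radius in nm (default 80).
#' @export
merge_close_loci <- function(loci, max_extent = 80) {
  if (length(loci) <= 1L) return(loci)
  allc <- do.call(rbind, lapply(loci, `[[`, "coords"))
  grp <- rep(seq_along(loci), vapply(loci, function(l) nrow(l$coords),
                                     integer(1)))
  comp_pt <- .single_linkage(allc, max_extent)
  # loci merge iff any of their member points share a linkage component:
  # bipartite locus--component graph, take connected components
  g <- igraph::graph_from_edgelist(
    cbind(paste0("L", grp), paste0("C", comp_pt)), directed = FALSE)
  cmp <- igraph::components(g)$membership
  lmemb <- cmp[paste0("L", seq_along(loci))]
  merged <- lapply(unique(lmemb), function(m) {
    sel <- which(lmemb == m)
    rows <- sort(unlist(lapply(loci[sel], `[[`, "member_rows")))
    coords <- do.call(rbind, lapply(loci[sel], `[[`, "coords"))
    ord <- order(unlist(lapply(loci[sel], `[[`, "member_rows")))
    .locus_new(rows, coords[ord, , drop = FALSE])
  })
  cent <- t(vapply(merged, `[[`, numeric(3), "centroid"))
  merged[order(cent[, 1], cent[, 2], cent[, 3])]
}

#' Assign loci to refined nucleoid sub-objects
#'
#' Within one mixed object, each locus is assigned to the refined nucleoid
#' sub-object whose member localizations come nearest to the locus
#' centroid; ties go to the lower object index. If the mixed object has
#' loci but no surviving nucleoid sub-object, the loci are orphaned (and
#' reported, not counted).
#'
#' @param nucleoids list of refined `segmented_object`s (with
#'   `member_rows` indexing `pooled`).
#' @param loci list of `probe_locus`.
#' @param pooled the pooled [loc_table].
#' @return list with `assignment` (locus index -> nucleoid index, NA for
#'   orphans) and `orphans` (locus indices).
#' @export
assign_loci <- function(nucleoids, loci, pooled) {
  if (length(loci) == 0L)
    return(list(assignment = integer(0), orphans = integer(0)))
  if (length(nucleoids) == 0L)
    return(list(assignment = rep(NA_integer_, length(loci)),
                orphans = seq_along(loci)))
  coords <- as.matrix(pooled[, c("x", "y", "z")])
  assignment <- vapply(loci, function(lc) {
    d <- vapply(nucleoids, function(no) {
      m <- coords[no$member_rows, , drop = FALSE]
      sqrt(min(.cross_dist2(matrix(lc$centroid, 1L), m)))
    }, numeric(1))
    which.min(d)  # first minimum = lower object index on ties
  }, integer(1))
  list(assignment = assignment, orphans = integer(0))
}

#' Count probe loci per nucleoid across a whole two-channel acquisition
#'
#' Runs the full two-step procedure: mixed segmentation at `a_max_mixed`,
#' per-channel refinement within each mixed object, locus merging at the
#' probe extent, locus-to-nucleoid assignment, the
#' more-than-`min_points`-localizations filter, and sphere/ellipsoid
#' modeling of the retained nucleoids.
#'
#' @param nucleoid_ch,probe_ch [loc_table]s of the two channels (nm).
#' @param a_max_mixed first-step culling threshold (nm, default 80).
#' @param a_max_nucleoid second-step nucleoid threshold (nm); `"auto"`
#'   (default) uses the most frequent diameter (MFD) of a first-pass
#'   nucleoid-only segmentation, falling back to 80 nm when no first-pass
#'   distribution is available.
#' @param a_max_probe probe-channel threshold (nm, default 80).
#' @param merge_extent locus merge radius (nm, default 80 -- the same
#'   physical quantity as `a_max_probe`, the maximum probe extension).
#' @param min_points nucleoids must have strictly more localizations than
#'   this (default 10).
#' @param theta_filter apply the ellipsoid orientation filter before
#'   reporting (default FALSE).
#' @param theta_cut,theta_keep see [orientation_filter()].
#' @param nucleoid_channel,probe_channel channel labels.
#' @return list of class `overlap_result`: `records` (list of
#'   `nucleoid_record`), `orphan_loci`, `disposition` (per pooled row:
#'   `"nucleoid"`, `"locus"`, `"orphan_locus"`, `"excluded_mixed"`,
#'   `"excluded_refine"`, `"small_object"`, `"filtered_theta"`),
#'   `a_max_nucleoid` actually used, and the pooled table.
#' @export
count_overlaps <- function(nucleoid_ch, probe_ch,
                           a_max_mixed = 80, a_max_nucleoid = "auto",
                           a_max_probe = 80, merge_extent = 80,
                           min_points = 10,
                           theta_filter = FALSE, theta_cut = 45,
                           theta_keep = "above",
                           nucleoid_channel = 1L, probe_channel = 2L) {
  seg <- mixed_segmentation(nucleoid_ch, probe_ch, a_max_mixed)
  pooled <- seg$pooled
  if (length(seg$objects) == 0L) {
    return(structure(list(records = list(), orphan_loci = list(),
                          disposition = rep("excluded_mixed", nrow(pooled)),
                          a_max_nucleoid = NA_real_, pooled = pooled,
                          mixed = seg),
                     class = "overlap_result"))
  }
  if (identical(a_max_nucleoid, "auto")) {
    a_max_nucleoid <- .auto_a_max(nucleoid_ch, a_max_mixed, min_points)
  }
  disposition <- rep("excluded_mixed", nrow(pooled))
  records <- list()
  orphans <- list()
  for (mo in seg$objects) {
    has_nuc <- !is.null(pooled$channel) &&
      any(pooled$channel[mo$member_rows] == nucleoid_channel)
    if (!has_nuc) {
      # probe-only mixed object: loci with no nucleoid -> orphans
      pr <- mo$member_rows
      orphans <- c(orphans, list(.locus_new(pr,
        as.matrix(pooled[pr, c("x", "y", "z")]))))
      disposition[pr] <- "orphan_locus"
      next
    }
    ref <- refine_per_channel(mo, pooled, a_max_nucleoid, a_max_probe,
                              nucleoid_channel, probe_channel)
    loci <- merge_close_loci(ref$loci, merge_extent)
    asg <- assign_loci(ref$nucleoids, loci, pooled)
    disposition[ref$excluded_rows] <- "excluded_refine"
    for (oi in asg$orphans) {
      orphans <- c(orphans, list(loci[[oi]]))
      disposition[loci[[oi]]$member_rows] <- "orphan_locus"
    }
    for (k in seq_along(ref$nucleoids)) {
      no <- ref$nucleoids[[k]]
      k_loci <- if (length(loci)) loci[which(asg$assignment == k)] else list()
      records <- c(records, list(structure(
        list(nucleoid = no,
             mixed_id = mo$id,
             centroid = colMeans(
               as.matrix(pooled[no$member_rows, c("x", "y", "z")])),
             loci = k_loci,
             n_mtdna = length(k_loci),
             sphere = NULL, ellipsoid = NULL),
        class = "nucleoid_record")))
      disposition[no$member_rows] <- "nucleoid"
      for (lc in k_loci) disposition[lc$member_rows] <- "locus"
    }
  }
  # size filter, then geometric models (on the retained nucleoids)
  keep <- vapply(records, function(r)
    r$nucleoid$n_localizations > min_points, logical(1))
  for (r in records[!keep])
    disposition[r$nucleoid$member_rows] <- "small_object"
  records <- records[keep]
  coords <- as.matrix(pooled[, c("x", "y", "z")])
  records <- lapply(records, function(r) {
    pts <- coords[r$nucleoid$member_rows, , drop = FALSE]
    r$sphere <- .sphere_model_points(pts, r$nucleoid$volume_vd)
    r$ellipsoid <- .ellipsoid_model_points(pts, r$nucleoid$volume_vd)
    r
  })
  if (theta_filter) {
    sel <- vapply(records, function(r) {
      th <- r$ellipsoid$theta
      if (is.na(th)) return(FALSE)
      if (theta_keep == "above") th >= theta_cut else th <= theta_cut
    }, logical(1))
    for (r in records[!sel])
      disposition[r$nucleoid$member_rows] <- "filtered_theta"
    records <- records[sel]
  }
  structure(list(records = records, orphan_loci = orphans,
                 disposition = disposition,
                 a_max_nucleoid = a_max_nucleoid,
                 pooled = pooled, mixed = seg),
            class = "overlap_result")
}

# sphere / ellipsoid models from raw member coordinates + V_D (used by the
# overlap pipeline, where sub-objects carry their own point subsets)
.sphere_model_points <- function(pts, v_d) {
  v_smooth <- if (nrow(pts) >= 4L) convex_hull_volume(pts) else 0
  structure(list(d_d = sphere_diameter(v_d),
                 d_smooth = sphere_diameter(v_smooth),
                 v_d = v_d, v_smooth = v_smooth, degenerate = v_d <= 0),
            class = "sphere_model")
}

.ellipsoid_model_points <- function(pts, v_d) {
  obj <- structure(list(member_points = seq_len(nrow(pts)),
                        volume_vd = v_d),
                   class = "segmented_object")
  cx <- list(points = pts)
  ellipsoid_model(obj, cx)
}

# "auto" second-pass threshold: MFD of a first-pass nucleoid-only diameter
# distribution (d_D, 10 nm bins); falls back to the first-step default
.auto_a_max <- function(nucleoid_ch, a_max_mixed, min_points,
                        fallback = 80) {
  res <- tryCatch({
    cx <- delaunay_tessellate(nucleoid_ch)
    seg <- segment(cull_tetrahedra(cx, a_max_mixed))
    objs <- filter_min_localizations(seg$objects, min_points)
    if (length(objs) == 0L) return(fallback)
    dd <- vapply(objs, function(o) sphere_diameter(o$volume_vd), numeric(1))
    mfd <- diameter_distribution(dd)$mfd
    if (is.finite(mfd) && mfd > 0) mfd else fallback
  }, nucleotess_degenerate = function(e) fallback)
  res
}

#' @export
print.overlap_result <- function(x, ...) {
  n <- vapply(x$records, `[[`, integer(1), "n_mtdna")
  cat(sprintf(
    "overlap_result: %d nucleoid(s) (%d with >=1 locus), %d orphan loci\n",
    length(n), sum(n >= 1), length(x$orphan_loci)))
  cat(sprintf("  second-pass A_max = %g nm; dispositions: %s\n",
              x$a_max_nucleoid,
              paste(names(table(x$disposition)),
                    table(x$disposition), sep = "=", collapse = ", ")))
  invisible(x)
}

#' Histogram of loci counts per nucleoid
#'
#' Percentages of nucleoids containing n = 1, 2, 3, ... loci, with the
#' nucleoids having at least one locus set as 100%. Zero-locus nucleoids
#' are reported separately (`n_zero`) and excluded from the denominator.
#' The weighted average restricted to n < 7 (`weighted_average_lt7`)
#' discards classes that may be inflated by noise or multiple blinking.
#'
#' @param records list of `nucleoid_record`s, or an `overlap_result`, or a
#'   bare integer vector of per-nucleoid counts.
#' @return list of class `count_histogram`: `classes`, `counts`,
#'   `percent`, `denominator`, `n_zero`, `weighted_average_lt7`.
#' @export
count_histogram <- function(records) {
  n <- if (inherits(records, "overlap_result"))
    vapply(records$records, `[[`, integer(1), "n_mtdna")
  else if (is.numeric(records)) as.integer(records)
  else vapply(records, `[[`, integer(1), "n_mtdna")
  n_zero <- sum(n == 0L)
  n <- n[n >= 1L]
  if (!length(n)) {
    return(structure(list(classes = integer(0), counts = integer(0),
                          percent = numeric(0), denominator = 0L,
                          n_zero = n_zero,
                          weighted_average_lt7 = NA_real_, empty = TRUE),
                     class = "count_histogram"))
  }
  tab <- table(n)
  classes <- as.integer(names(tab))
  counts <- as.integer(tab)
  lt7 <- n[n < 7L]
  structure(list(classes = classes, counts = counts,
                 percent = 100 * counts / length(n),
                 denominator = length(n), n_zero = n_zero,
                 weighted_average_lt7 =
                   if (length(lt7)) mean(lt7) else NA_real_,
                 empty = FALSE),
            class = "count_histogram")
}

#' @export
print.count_histogram <- function(x, ...) {
  if (isTRUE(x$empty)) {
    cat("count_histogram: no nucleoid with >= 1 locus\n")
    return(invisible(x))
  }
  cat(sprintf(
    "count_histogram: %d nucleoid(s) with overlaps (= 100%%), %d with none\n",
    x$denominator, x$n_zero))
  for (i in seq_along(x$classes))
    cat(sprintf("  n = %d: %5.1f%% (%d)\n", x$classes[i], x$percent[i],
                x$counts[i]))
  cat(sprintf("  weighted average (n < 7): %.3g\n", x$weighted_average_lt7))
  invisible(x)
}

#' Diameter distributions stratified by loci count
#'
#' One diameter histogram per loci-count class n = 1..6 plus a pooled
#' class `">=7"`; empty classes are omitted. Correlates nucleoid size with
#' the number of mtDNA molecules per nucleoid.
#'
#' @param records list of `nucleoid_record`s or an `overlap_result`.
#' @param bin_width histogram bin width (nm).
#' @param which `"d_d"` (default) or `"d_smooth"`.
#' @return named list of [diameter_distribution]s.
#' @export
diameter_by_count <- function(records, bin_width = 10, which = "d_d") {
  if (inherits(records, "overlap_result")) records <- records$records
  n <- vapply(records, `[[`, integer(1), "n_mtdna")
  d <- vapply(records, function(r) r$sphere[[which]], numeric(1))
  cls <- ifelse(n >= 7L, ">=7", as.character(n))
  keep <- n >= 1L
  cls <- cls[keep]; d <- d[keep]
  lev <- c(as.character(1:6), ">=7")
  out <- list()
  for (lv in lev) {
    if (any(cls == lv))
      out[[lv]] <- diameter_distribution(d[cls == lv], bin_width)
  }
  out
}
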