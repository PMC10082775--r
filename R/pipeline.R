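# End-to-end orchestration: one config drives read/simulate -> mixed
# segmentation -> per-channel refinement -> models -> loci counting ->
# Ripley statistics -> density, with all outputs written as CSV/JSON.

#' Pipeline configuration
#'
#' A flat list of every tunable parameter of the end-to-end run. Exactly
#' one of `nucleoid_path`/`probe_path` (canonical localization CSVs) or
#' `scene` (a [scene_spec()] to simulate) must be supplied.
#'
#' @param nucleoid_path,probe_path input CSVs (canonical dialect).
#' @param scene a [scene_spec()] for synthetic input.
#' @param max_uncertainty optional accuracy filter threshold (nm).
#' @param a_max_mixed,a_max_nucleoid,a_max_probe,merge_extent,min_points
#'   see [count_overlaps()].
#' @param theta_filter,theta_cut,theta_keep orientation filter settings.
#' @param epsilon,r_max,min_prominence Ripley grid and MFD settings (the
#'   Ripley pass runs on the nucleoid channel).
#' @param volume_method `"hull"` or `"bbox"` for the density volume.
#' @param out_dir output directory (`NULL`: nothing written).
#' @param seed integer seed recorded in the summary.
#' @export
pipeline_config <- function(nucleoid_path = NULL, probe_path = NULL,
                            scene = NULL, max_uncertainty = NULL,
                            a_max_mixed = 80, a_max_nucleoid = "auto",
                            a_max_probe = 80, merge_extent = 80,
                            min_points = 10, theta_filter = FALSE,
                            theta_cut = 45, theta_keep = "above",
                            epsilon = 10, r_max = 2000,
                            min_prominence = 0.1,
                            volume_method = "hull",
                            out_dir = NULL, seed = 1L) {
  if (is.null(scene) && (is.null(nucleoid_path) || is.null(probe_path)))
    stop("config requires either 'scene' or both 'nucleoid_path' and ",
         "'probe_path'")
  for (p in c(a_max_mixed, a_max_probe, merge_extent, epsilon, r_max))
    if (!is.numeric(p) || p <= 0) stop("thresholds must be positive")
  structure(list(nucleoid_path = nucleoid_path, probe_path = probe_path,
                 scene = scene, max_uncertainty = max_uncertainty,
                 a_max_mixed = a_max_mixed, a_max_nucleoid = a_max_nucleoid,
                 a_max_probe = a_max_probe, merge_extent = merge_extent,
                 min_points = min_points, theta_filter = theta_filter,
                 theta_cut = theta_cut, theta_keep = theta_keep,
                 epsilon = epsilon, r_max = r_max,
                 min_prominence = min_prominence,
                 volume_method = volume_method,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Nucleoid records as a data frame
#'
#' @param result an `overlap_result`.
#' @return one row per nucleoid: diameters, ellipsoid axes, theta,
#'   localization and loci counts.
#' @export
nucleoid_table <- function(result) {
  stopifnot(inherits(result, "overlap_result"))
  if (!length(result$records))
    return(data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), d_d = numeric(0),
                      d_smooth = numeric(0), d_max = numeric(0),
                      d_min = numeric(0), theta = numeric(0),
                      n_localizations = integer(0), n_mtdna = integer(0)))
  do.call(rbind, lapply(seq_along(result$records), function(i) {
    r <- result$records[[i]]
    data.frame(id = i, x = r$centroid[1], y = r$centroid[2],
               z = r$centroid[3], d_d = r$sphere$d_d,
               d_smooth = r$sphere$d_smooth, d_max = r$ellipsoid$d_max,
               d_min = r$ellipsoid$d_min, theta = r$ellipsoid$theta,
               n_localizations = r$nucleoid$n_localizations,
               n_mtdna = r$n_mtdna)
  }))
}

#' Probe loci as a data frame
#' @param result an `overlap_result`.
#' @export
locus_table <- function(result) {
  stopifnot(inherits(result, "overlap_result"))
  rows <- list()
  for (i in seq_along(result$records)) {
    for (lc in result$records[[i]]$loci)
      rows[[length(rows) + 1L]] <-
        data.frame(nucleoid_id = i, x = lc$centroid[1], y = lc$centroid[2],
                   z = lc$centroid[3], extent = lc$extent,
                   n_localizations = length(lc$member_rows),
                   singleton = lc$singleton, orphan = FALSE)
  }
  for (lc in result$orphan_loci)
    rows[[length(rows) + 1L]] <-
      data.frame(nucleoid_id = NA_integer_, x = lc$centroid[1],
                 y = lc$centroid[2], z = lc$centroid[3], extent = lc$extent,
                 n_localizations = length(lc$member_rows),
                 singleton = lc$singleton, orphan = TRUE)
  if (!length(rows))
    return(data.frame(nucleoid_id = integer(0), x = numeric(0),
                      y = numeric(0), z = numeric(0), extent = numeric(0),
                      n_localizations = integer(0), singleton = logical(0),
                      orphan = logical(0)))
  do.call(rbind, rows)
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes read/simulate, optional accuracy filtering, the two-step
#' overlap procedure, loci-count and diameter histograms, the Ripley pass
#' on the nucleoid channel, and the density estimate. With `out_dir` set,
#' writes `nucleoid_table.csv`, `locus_table.csv`, `count_histogram.csv`,
#' `diameter_by_count.csv`, `ripley.csv`, `distance_histogram.csv`,
#' `summary.json` and a serialized copy of the configuration; reruns with
#' the same config are identical.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_summary` with the result objects and
#'   stage-by-stage localization counts.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  truth <- NULL
  if (!is.null(config$scene)) {
    sim <- simulate_scene(config$scene)
    tbl <- sim$table
    truth <- sim$truth
  } else {
    for (p in c(config$nucleoid_path, config$probe_path))
      if (!file.exists(p)) stop("input not found: ", p)
    nuc <- read_localizations(config$nucleoid_path)
    prb <- read_localizations(config$probe_path)
    prb$channel <- 2L
    nuc$channel <- 1L
    tbl <- loc_table(x = c(nuc$x, prb$x), y = c(nuc$y, prb$y),
                     z = c(nuc$z, prb$z),
                     channel = c(nuc$channel, prb$channel))
  }
  n_input <- nrow(tbl)
  if (!is.null(config$max_uncertainty))
    tbl <- filter_by_uncertainty(tbl, config$max_uncertainty)
  chans <- split_channels(tbl)
  nucleoid_ch <- chans[["1"]]
  probe_ch <- if ("2" %in% names(chans)) chans[["2"]] else
    loc_table(metadata = list())
  overlaps <- count_overlaps(
    nucleoid_ch, probe_ch,
    a_max_mixed = config$a_max_mixed,
    a_max_nucleoid = config$a_max_nucleoid,
    a_max_probe = config$a_max_probe,
    merge_extent = config$merge_extent,
    min_points = config$min_points,
    theta_filter = config$theta_filter,
    theta_cut = config$theta_cut,
    theta_keep = config$theta_keep)
  counts <- count_histogram(overlaps)
  bycount <- diameter_by_count(overlaps)
  ripley <- ripley_result(nucleoid_ch, epsilon = config$epsilon,
                          r_max = config$r_max,
                          min_prominence = config$min_prominence)
  density <- nucleoid_density(overlaps, tbl,
                              volume_method = config$volume_method)
  summary <- structure(
    list(config = config,
         overlaps = overlaps,
         count_histogram = counts,
         diameter_by_count = bycount,
         ripley = ripley,
         density = density,
         truth = truth,
         stage_counts = list(
           input = n_input,
           after_uncertainty_filter = nrow(tbl),
           nucleoid_channel = nrow(nucleoid_ch),
           probe_channel = nrow(probe_ch),
           disposition = as.list(table(overlaps$disposition)),
           nucleoids_reported = length(overlaps$records),
           nucleoids_with_overlap = counts$denominator,
           orphan_loci = length(overlaps$orphan_loci))),
    class = "pipeline_summary")
  if (!is.null(config$out_dir)) .write_outputs(summary, config$out_dir)
  summary
}

.write_outputs <- function(summary, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ov <- summary$overlaps
  write.csv(nucleoid_table(ov), file.path(out_dir, "nucleoid_table.csv"),
            row.names = FALSE)
  write.csv(locus_table(ov), file.path(out_dir, "locus_table.csv"),
            row.names = FALSE)
  ch <- summary$count_histogram
  write.csv(data.frame(n_mtdna = ch$classes, count = ch$counts,
                       percent = ch$percent),
            file.path(out_dir, "count_histogram.csv"), row.names = FALSE)
  bc <- summary$diameter_by_count
  if (length(bc)) {
    rows <- do.call(rbind, lapply(names(bc), function(cl) {
      d <- bc[[cl]]
      data.frame(class = cl, bin_start = d$bin_edges[-length(d$bin_edges)],
                 bin_end = d$bin_edges[-1], count = d$counts, mfd = d$mfd)
    }))
    write.csv(rows, file.path(out_dir, "diameter_by_count.csv"),
              row.names = FALSE)
  }
  rp <- summary$ripley
  write.csv(data.frame(r = rp$r_grid, h = rp$h, k = rp$k, l = rp$l,
                       l_minus_r = rp$l_minus_r),
            file.path(out_dir, "ripley.csv"), row.names = FALSE)
  write.csv(data.frame(bin_start = rp$histogram$bin_start,
                       bin_end = rp$histogram$bin_end,
                       count = rp$histogram$counts),
            file.path(out_dir, "distance_histogram.csv"), row.names = FALSE)
  js <- list(
    parameters = summary$config[!vapply(summary$config, is.null,
                                        logical(1))],
    package_version = as.character(utils::packageVersion("nucleotess")),
    a_max_nucleoid_used = ov$a_max_nucleoid,
    stage_counts = summary$stage_counts,
    density = unclass(summary$density),
    weighted_average_lt7 = summary$count_histogram$weighted_average_lt7,
    ripley_mfds = summary$ripley$mfds)
  js$parameters$scene <- if (!is.null(summary$config$scene))
    unclass(summary$config$scene) else NULL
  jsonlite::write_json(js, file.path(out_dir, "summary.json"),
                       digits = NA, auto_unbox = TRUE, na = "null",
                       force = TRUE)
  invisible(out_dir)
}

#' @export
print.pipeline_summary <- function(x, ...) {
  cat("pipeline_summary\n")
  print(x$overlaps)
  print(x$count_histogram)
  print(x$density)
  invisible(x)
}

#' Compare two pipeline runs
#'
#' Density fold-change, per-class loci-histogram deltas, and the
#' inter-distance histogram ratio (variation function) between two
#' completed runs.
#'
#' @param a,b `pipeline_summary` objects with identical Ripley binning.
#' @return list of class `run_comparison`.
#' @export
compare_runs <- function(a, b) {
  stopifnot(inherits(a, "pipeline_summary"), inherits(b, "pipeline_summary"))
  if (a$config$epsilon != b$config$epsilon ||
      a$config$r_max != b$config$r_max)
    stop("runs use different Ripley binning (epsilon/r_max)")
  ca <- a$count_histogram; cb <- b$count_histogram
  classes <- sort(union(ca$classes, cb$classes))
  pa <- setNames(rep(0, length(classes)), classes)
  pb <- pa
  pa[as.character(ca$classes)] <- ca$percent
  pb[as.character(cb$classes)] <- cb$percent
  structure(list(
    fold_change = fold_change(a$density, b$density),
    histogram_delta = data.frame(class = classes,
                                 percent_a = unname(pa),
                                 percent_b = unname(pb),
                                 delta_pp = unname(pa - pb)),
    variation_function = histogram_ratio(a$ripley$histogram,
                                         b$ripley$histogram)),
    class = "run_comparison")
}

#' @export
print.run_comparison <- function(x, ...) {
  cat(sprintf("run_comparison: density fold-change %.3g\n", x$fold_change))
  print(x$histogram_delta)
  invisible(x)
}
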