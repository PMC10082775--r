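# Ground-truth recovery: compare an overlap_result against the generator's
# scene_ground_truth.

#' Match recovered nucleoids to ground truth and score count recovery
#'
#' Each recovered nucleoid is matched to the nearest true nucleoid center;
#' a true nucleoid's recovered loci count is the total over the records
#' matched to it (so an erroneously split nucleoid does not silently
#' pass). Unrecovered nucleoids count as misses.
#'
#' @param result an `overlap_result` from [count_overlaps()].
#' @param truth a `scene_ground_truth` from [simulate_scene()].
#' @return list of class `recovery_result`: `per_nucleoid` (data.frame
#'   with `true_n`, `recovered_n`, `n_records`, `exact`),
#'   `fraction_exact`, `n_true`, `n_recovered_records`.
#' @export
recovery_rate <- function(result, truth) {
  stopifnot(inherits(result, "overlap_result"),
            inherits(truth, "scene_ground_truth"))
  gt <- truth$nucleoids
  n_true <- nrow(gt)
  recovered_n <- rep(0L, n_true)
  n_records <- rep(0L, n_true)
  found <- rep(FALSE, n_true)
  if (length(result$records)) {
    cent <- t(vapply(result$records, `[[`, numeric(3), "centroid"))
    gtc <- as.matrix(gt[, c("x", "y", "z")])
    nearest <- max.col(-.cross_dist2(cent, gtc), ties.method = "first")
    for (k in seq_along(result$records)) {
      i <- nearest[k]
      recovered_n[i] <- recovered_n[i] + result$records[[k]]$n_mtdna
      n_records[i] <- n_records[i] + 1L
      found[i] <- TRUE
    }
  }
  per <- data.frame(id = gt$id, true_n = gt$n_loci,
                    recovered_n = recovered_n, n_records = n_records,
                    exact = found & recovered_n == gt$n_loci &
                      n_records == 1L)
  structure(list(per_nucleoid = per,
                 fraction_exact = mean(per$exact),
                 n_true = n_true,
                 n_recovered_records = length(result$records)),
            class = "recovery_result")
}

#' @export
print.recovery_result <- function(x, ...) {
  cat(sprintf(
    "recovery_result: %.1f%% exact (%d/%d true nucleoids; %d records)\n",
    100 * x$fraction_exact, sum(x$per_nucleoid$exact), x$n_true,
    x$n_recovered_records))
  invisible(x)
}

#' Compare recovered and true loci-count histograms
#'
#' Per-class difference (percentage points) between the recovered
#' [count_histogram()] and the one computed from true loci counts.
#'
#' @param result an `overlap_result`.
#' @param truth a `scene_ground_truth`.
#' @return data.frame with `class`, `percent_recovered`, `percent_true`,
#'   `delta_pp`.
#' @export
histogram_vs_truth <- function(result, truth) {
  hr <- count_histogram(result)
  ht <- count_histogram(truth$nucleoids$n_loci)
  classes <- sort(union(hr$classes, ht$classes))
  pr <- setNames(rep(0, length(classes)), classes)
  pt <- pr
  pr[as.character(hr$classes)] <- hr$percent
  pt[as.character(ht$classes)] <- ht$percent
  data.frame(class = classes, percent_recovered = unname(pr),
             percent_true = unname(pt), delta_pp = unname(pr - pt))
}
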