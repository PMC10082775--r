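# compact shell nucleoid + probe blinks fixtures
shell_cloud <- function(center, r = 60, n = 40, seed = 1) {
  set.seed(seed)
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  u * runif(n, r, r + 20) + matrix(center, n, 3, byrow = TRUE)
}

test_that("mixed segmentation attaches inside probes and rejects distant
           ones", {
  nuc <- toy_table(shell_cloud(c(0, 0, 0)), 1L)
  inside <- toy_table(rbind(c(0, 0, 0), c(20, 0, 0), c(0, 20, 0),
                            c(10, 10, 10)), 2L)
  seg <- mixed_segmentation(nuc, inside, 80)
  expect_length(seg$objects, 1L)
  cc <- seg$objects[[1]]$channel_counts
  expect_equal(as.integer(cc[c("1", "2")]), c(40L, 4L))

  far <- toy_table(matrix(c(1000, 0, 0), 1), 2L)
  seg2 <- mixed_segmentation(nuc, far, 80)
  for (o in seg2$objects) {
    ch <- seg2$pooled$channel[o$member_rows]
    expect_false(all(ch == 2L) && any(seg2$pooled$x[o$member_rows] > 900))
  }
  probe_row <- which(seg2$pooled$channel == 2L)
  in_obj <- any(vapply(seg2$objects, function(o)
    probe_row %in% o$member_rows, logical(1)))
  expect_false(in_obj)  # distant single probe blink is excluded

  expect_warning(empty <- mixed_segmentation(loc_table(), far, 80), "empty")
  expect_length(empty$objects, 0L)
})

test_that("refinement groups probe blinks by distance and keeps
           singletons", {
  nuc <- toy_table(shell_cloud(c(0, 0, 0), r = 70, n = 60), 1L)
  # two blinks 30 nm apart -> one locus; plus one blink 200 nm away inside
  # nothing -> its own locus
  probes <- toy_table(rbind(c(0, 0, 0), c(30, 0, 0)), 2L)
  seg <- mixed_segmentation(nuc, probes, 80)
  ref <- refine_per_channel(seg$objects[[1]], seg$pooled, 80, 80)
  loci <- merge_close_loci(ref$loci, 80)
  expect_length(loci, 1L)
  expect_equal(length(loci[[1]]$member_rows), 2L)

  probes2 <- toy_table(rbind(c(-60, 0, 0), c(140, 0, 0)), 2L)
  seg2 <- mixed_segmentation(nuc, probes2, 80)
  expect_length(seg2$objects, 1L)
  ref2 <- refine_per_channel(seg2$objects[[1]], seg2$pooled, 80, 80)
  loci2 <- merge_close_loci(ref2$loci, 80)
  expect_length(loci2, 2L)
  expect_true(all(vapply(loci2, `[[`, logical(1), "singleton")))
})

test_that("locus merging is transitive via single linkage and monotone in
           the merge radius", {
  mkloc <- function(x) nucleotess:::.locus_new(1L, matrix(c(x, 0, 0), 1))
  chain <- list(mkloc(0), mkloc(70), mkloc(140))  # A-B 70, B-C 70, A-C 140
  merged <- merge_close_loci(chain, 80)
  expect_length(merged, 1L)
  expect_equal(merged[[1]]$extent, 140)
  apart <- list(mkloc(0), mkloc(200))
  expect_length(merge_close_loci(apart, 80), 2L)
  # monotonicity: growing the radius can only reduce the locus count
  set.seed(50)
  loci <- lapply(1:6, function(i)
    nucleotess:::.locus_new(i, matrix(runif(3, 0, 400), 1)))
  n_prev <- Inf
  for (ext in c(20, 60, 120, 250, 500)) {
    n_now <- length(merge_close_loci(loci, ext))
    expect_lte(n_now, n_prev)
    n_prev <- n_now
  }
})

test_that("loci are assigned to the nearest refined nucleoid with the
           lower-index tie rule", {
  n1 <- shell_cloud(c(0, 0, 0), seed = 2)
  n2 <- shell_cloud(c(400, 0, 0), seed = 3)
  pooled <- rbind(toy_table(rbind(n1, n2), 1L),
                  toy_table(rbind(c(60, 0, 0), c(360, 0, 0)), 2L))
  nucleoids <- list(
    structure(list(member_rows = 1:40, n_localizations = 40L),
              class = "segmented_object"),
    structure(list(member_rows = 41:80, n_localizations = 40L),
              class = "segmented_object"))
  loci <- list(nucleotess:::.locus_new(81L, matrix(c(60, 0, 0), 1)),
               nucleotess:::.locus_new(82L, matrix(c(360, 0, 0), 1)))
  asg <- assign_loci(nucleoids, loci, pooled)
  expect_equal(asg$assignment, c(1L, 2L))
  # locus equidistant from both point sets -> lower object index
  mid <- list(nucleotess:::.locus_new(83L, matrix(c(210, 0, 0), 1)))
  sym <- list(
    structure(list(member_rows = which(pooled$x == 60)[1]),
              class = "segmented_object"),
    structure(list(member_rows = which(pooled$x == 360)[1]),
              class = "segmented_object"))
  mid_next <- assign_loci(sym, mid, pooled)
  expect_equal(mid_next$assignment, 1L)
  # no nucleoid -> orphans
  orphan <- assign_loci(list(), loci, pooled)
  expect_equal(orphan$orphans, 1:2)
})

test_that("count histogram percentages, denominator and the n<7 weighted
           average follow the definitions", {
  ch <- count_histogram(c(1L, 1L, 2L, 3L))
  expect_equal(ch$percent, c(50, 25, 25))
  expect_equal(ch$weighted_average_lt7, 1.75)
  expect_equal(sum(ch$percent), 100)
  ch2 <- count_histogram(c(1L, 2L, 7L, 8L))
  expect_equal(ch2$weighted_average_lt7, 1.5)  # 7 and 8 excluded
  expect_equal(ch2$denominator, 4L)            # but still in the histogram
  ch3 <- count_histogram(rep(1L, 9))
  expect_equal(ch3$percent, 100)
  expect_equal(ch3$weighted_average_lt7, 1)
  ch4 <- count_histogram(c(0L, 0L, 2L))
  expect_equal(ch4$n_zero, 2L)
  expect_equal(ch4$denominator, 1L)
  expect_true(count_histogram(c(0L, 0L))$empty)
})

test_that("diameter-by-count pools classes >= 7 and omits empty ones", {
  mk <- function(n, d) structure(
    list(n_mtdna = n, sphere = list(d_d = d, d_smooth = d)),
    class = "nucleoid_record")
  recs <- list(mk(3L, 100), mk(3L, 120), mk(9L, 300))
  out <- diameter_by_count(recs)
  expect_named(out, c("3", ">=7"))
  expect_equal(sum(out[["3"]]$counts), 2L)
})

test_that("every localization ends in exactly one disposition and the
           result is invariant to input row order", {
  sp <- scene_spec(stain_fill = "volume", sigma_xy = 10, sigma_z = 20,
                   blink_mean = 2, background_density = 0.4,
                   n_tubules = 2, box = c(6000, 6000, 2500), seed = 60L)
  sim <- simulate_scene(sp)
  ch <- split_channels(sim$table)
  ov <- count_overlaps(ch[["1"]], ch[["2"]])
  expect_length(ov$disposition, nrow(ov$pooled))
  expect_false(any(is.na(ov$disposition)))
  probe_disp <- ov$disposition[ov$pooled$channel == 2L]
  expect_true(all(probe_disp %in%
    c("locus", "orphan_locus", "excluded_mixed", "small_object")))

  # permutation invariance of the counted quantities
  set.seed(99)
  perm1 <- sample(nrow(ch[["1"]]))
  perm2 <- sample(nrow(ch[["2"]]))
  ov2 <- count_overlaps(ch[["1"]][perm1, ], ch[["2"]][perm2, ])
  n1 <- sort(vapply(ov$records, `[[`, integer(1), "n_mtdna"))
  n2 <- sort(vapply(ov2$records, `[[`, integer(1), "n_mtdna"))
  expect_identical(n1, n2)
  expect_equal(length(ov$orphan_loci), length(ov2$orphan_loci))
  expect_equal(table(ov$disposition), table(ov2$disposition))
})

test_that("zero-probe scenes give all-zero counts and an empty histogram", {
  nuc <- toy_table(shell_cloud(c(0, 0, 0), n = 50, seed = 9), 1L)
  ov <- count_overlaps(nuc, loc_table())
  expect_true(all(vapply(ov$records, `[[`, integer(1), "n_mtdna") == 0L))
  expect_true(count_histogram(ov)$empty)
})
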