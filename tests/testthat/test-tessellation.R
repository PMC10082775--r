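test_that("a regular tetrahedron tessellates to one tetrahedron of the
           closed-form volume", {
  a <- 60
  cx <- delaunay_tessellate(regular_tetra(a))
  expect_equal(nrow(cx$tetra), 1L)
  expect_equal(cx$volume, a^3 / (6 * sqrt(2)), tolerance = 1e-12)
  seg <- segment(cull_tetrahedra(cx, 61))
  expect_equal(polyhedron_volume(seg$objects[[1]], cx),
               a^3 / (6 * sqrt(2)), tolerance = 1e-12)
})

test_that("unit-cube corners (a cospherical, degenerate set) conserve
           volume exactly", {
  cube <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1)) * 1.0
  cx <- delaunay_tessellate(cube)
  expect_equal(sum(cx$volume), 1.0, tolerance = 1e-12)
  expect_setequal(unique(as.vector(cx$tetra)), 1:8)
})

test_that("tessellation is Delaunay and volume-conserving on random
           clouds (brute-force circumsphere + hull oracles)", {
  set.seed(42)
  pts <- matrix(runif(150, 0, 1000), ncol = 3)  # 50 points
  cx <- delaunay_tessellate(pts)
  expect_setequal(unique(as.vector(cx$tetra)), seq_len(nrow(pts)))
  expect_true(empty_circumsphere_ok(.jitterless <- cx$points, cx$tetra,
                                    rel_tol = 1e-7))
  expect_equal(sum(cx$volume), brute_hull_volume(pts), tolerance = 1e-9)
})

test_that("culling applies the strict all-edges inequality", {
  a <- 50
  cx <- delaunay_tessellate(regular_tetra(a))
  expect_true(cull_tetrahedra(cx, 60)$survives)
  expect_false(cull_tetrahedra(cx, 40)$survives)
  expect_false(cull_tetrahedra(cx, 50)$survives)  # strict <
  expect_error(cull_tetrahedra(cx, 0), "positive")
  # random cloud: survival equals the independent per-tet 6-edge check
  set.seed(7)
  pts <- matrix(runif(600, 0, 400), ncol = 3)  # 200 points
  cx <- cull_tetrahedra(delaunay_tessellate(pts), 80)
  oracle <- brute_segment_labels(cx$points, cx$tetra, 80)
  expect_identical(cx$survives, oracle$survives)
})

test_that("segmentation separates distant clusters and matches the
           union-find oracle labels", {
  c1 <- make_cluster(c(0, 0, 0), 12, sd = 20, seed = 1)
  c2 <- make_cluster(c(500, 0, 0), 12, sd = 20, seed = 2)
  cx <- cull_tetrahedra(delaunay_tessellate(rbind(c1, c2)), 80)
  seg <- segment(cx)
  expect_length(seg$objects, 2L)
  # one compact cluster: everything in one object
  cx1 <- cull_tetrahedra(delaunay_tessellate(c1), 200)
  seg1 <- segment(cx1)
  expect_length(seg1$objects, 1L)
  expect_equal(seg1$objects[[1]]$n_localizations, 12L)

  # random scene vs brute-force component labels
  set.seed(12)
  pts <- matrix(runif(900, 0, 600), ncol = 3)
  cx <- cull_tetrahedra(delaunay_tessellate(pts), 90)
  seg <- segment(cx)
  oracle <- brute_segment_labels(cx$points, cx$tetra, 90)
  mine <- rep(NA_integer_, nrow(pts))
  for (o in seg$objects) mine[o$member_points] <- o$id
  expect_identical(is.na(mine), is.na(oracle$point_labels))
  both <- !is.na(mine)
  # same partition up to label names
  expect_equal(length(unique(mine[both])),
               length(unique(oracle$point_labels[both])))
  expect_true(all(!duplicated(unique(
    paste(mine[both], oracle$point_labels[both])))))
})

test_that("objects plus exclusion set partition the input rows", {
  set.seed(3)
  pts <- matrix(runif(450, 0, 500), ncol = 3)
  cx <- cull_tetrahedra(delaunay_tessellate(pts), 70)
  seg <- segment(cx)
  rows <- sort(c(unlist(lapply(seg$objects, `[[`, "member_rows")),
                 seg$exclusion))
  expect_identical(rows, seq_len(nrow(pts)))
})

test_that("survivors grow and objects only merge as A_max increases", {
  set.seed(9)
  pts <- matrix(runif(360, 0, 400), ncol = 3)
  cx <- delaunay_tessellate(pts)
  s1 <- cull_tetrahedra(cx, 60)
  s2 <- cull_tetrahedra(cx, 100)
  expect_true(all(which(s1$survives) %in% which(s2$survives)))
  seg1 <- segment(s1); seg2 <- segment(s2)
  # each object at 60 nm is contained in exactly one object at 100 nm
  for (o in seg1$objects) {
    parents <- unique(vapply(seg2$objects, function(p)
      all(o$member_points %in% p$member_points), logical(1)))
    expect_true(any(parents))
  }
})

test_that("object volume never exceeds the member hull volume", {
  set.seed(11)
  pts <- matrix(runif(300, 0, 300), ncol = 3)
  cx <- cull_tetrahedra(delaunay_tessellate(pts), 120)
  for (o in segment(cx)$objects) {
    hull <- convex_hull_volume(cx$points[o$member_points, , drop = FALSE])
    expect_lte(o$volume_vd, hull * (1 + 1e-9))
  }
})

test_that("duplicates collapse for tessellation but keep multiplicity in
           counts; tiny inputs signal degeneracy", {
  pts <- regular_tetra(50)
  dup <- rbind(pts, pts[1, ], pts[1, ])
  expect_message(cx <- delaunay_tessellate(dup), "duplicate")
  expect_equal(nrow(cx$points), 4L)
  seg <- segment(cull_tetrahedra(cx, 60))
  expect_equal(seg$objects[[1]]$n_localizations, 6L)
  expect_error(delaunay_tessellate(pts[1:3, ]),
               class = "nucleotess_degenerate")
  # exactly coplanar sets are resolved by the deterministic jitter: a
  # warning is emitted and the tessellation carries (near) zero volume
  flat <- cbind(matrix(runif(20), ncol = 2), 0)
  expect_warning(cxf <- delaunay_tessellate(flat), "jitter")
  expect_lt(sum(cxf$volume), 1e-6)
})

test_that("localization-count filter is strictly greater-than", {
  mk <- function(n) structure(list(n_localizations = n, member_rows = 1:n),
                              class = "segmented_object")
  objs <- list(mk(10L), mk(11L))
  kept <- filter_min_localizations(objs, 10)
  expect_length(kept, 1L)
  expect_equal(kept[[1]]$n_localizations, 11L)
  expect_length(filter_min_localizations(objs, 0), 2L)
  expect_length(filter_min_localizations(list(mk(5L), mk(5L)), 10), 0L)
})

test_that("face connectivity is at least as fine as vertex connectivity
           and keeps the partition property", {
  set.seed(21)
  pts <- matrix(runif(600, 0, 500), ncol = 3)
  cx <- cull_tetrahedra(delaunay_tessellate(pts), 85)
  segv <- segment(cx, connectivity = "vertex")
  segf <- segment(cx, connectivity = "face")
  expect_gte(length(segf$objects), length(segv$objects))
  rows <- sort(c(unlist(lapply(segf$objects, `[[`, "member_rows")),
                 segf$exclusion))
  expect_identical(rows, seq_len(nrow(pts)))
  # every face-component lies inside one vertex-component
  for (o in segf$objects) {
    inside <- vapply(segv$objects, function(p)
      all(o$member_points %in% p$member_points), logical(1))
    expect_equal(sum(inside), 1L)
  }
})
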