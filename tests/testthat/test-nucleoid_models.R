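make_object <- function(pts, a_max = 1e6) {
  cx <- cull_tetrahedra(delaunay_tessellate(pts), a_max)
  seg <- segment(cx)
  list(object = seg$objects[[1]], complex = cx)
}

test_that("sphere diameter follows the closed form (6V/pi)^(1/3)", {
  expect_equal(sphere_diameter(14137167), 300, tolerance = 1e-6)
  expect_equal(sphere_diameter(pi / 6), 1)
  expect_equal(sphere_diameter(0), 0)
})

test_that("d_smooth >= d_d, with the hull volume matching the brute-force
           facet oracle on a non-convex object", {
  # star: two elongated lobes meeting at the origin -> culled polyhedron
  # is non-convex, hull fills the gap
  set.seed(4)
  lobe1 <- cbind(runif(25, 0, 300), runif(25, 0, 40), runif(25, 0, 40))
  lobe2 <- cbind(runif(25, 0, 40), runif(25, 0, 300), runif(25, 0, 40))
  pts <- rbind(lobe1, lobe2)
  ob <- make_object(pts, a_max = 90)
  sm <- sphere_model(ob$object, ob$complex)
  expect_gte(sm$d_smooth, sm$d_d)
  member <- ob$complex$points[ob$object$member_points, , drop = FALSE]
  expect_equal(sm$v_smooth, brute_hull_volume(member), tolerance = 1e-9)
})

test_that("degenerate zero-volume objects are flagged with zero diameters", {
  ob <- structure(list(member_points = 1:3, volume_vd = 0),
                  class = "segmented_object")
  cx <- list(points = diag(3))
  sm <- sphere_model(ob, cx)
  expect_true(sm$degenerate)
  expect_equal(sm$d_d, 0)
})

test_that("PCA ellipsoid recovers the generating axis and matches the
           power-iteration oracle", {
  set.seed(8)
  n <- 2000
  raw <- cbind(rnorm(n, 0, 100), rnorm(n, 0, 40), rnorm(n, 0, 40))
  ang <- 30 * pi / 180  # rotate long axis into the x-z plane, 60 deg off z
  R <- rbind(c(cos(ang), 0, -sin(ang)), c(0, 1, 0), c(sin(ang), 0, cos(ang)))
  pts <- raw %*% t(R)
  ob <- make_object(pts)
  em <- ellipsoid_model(ob$object, ob$complex)
  truth <- as.vector(R[, 1])
  if (truth[3] < 0) truth <- -truth
  ang_err <- acos(min(1, abs(sum(em$axis * truth)))) * 180 / pi
  expect_lt(ang_err, 5)
  oracle <- power_axis(ob$complex$points[ob$object$member_points, ])
  expect_lt(acos(min(1, abs(sum(em$axis * oracle)))) * 180 / pi, 1e-4)
  # rotational-ellipsoid volume equals V_D
  expect_equal(pi / 6 * em$d_max * em$d_min^2, ob$object$volume_vd,
               tolerance = 1e-9)
})

test_that("near-linear and isotropic point sets give the symmetric
           limits of theta and axis ratio", {
  set.seed(10)
  line <- cbind(rnorm(200, 0, 2), rnorm(200, 0, 2), seq(0, 300, length = 200))
  ob <- make_object(line)
  em <- ellipsoid_model(ob$object, ob$complex)
  expect_lt(em$theta, 2)
  iso <- make_cluster(c(0, 0, 0), 1500, sd = 50, seed = 5)
  obi <- make_object(iso)
  emi <- ellipsoid_model(obi$object, obi$complex)
  expect_lt(emi$d_max / emi$d_min, 1.15)
})

test_that("orientation filter defaults exclude z-elongated models and
           keep the boundary", {
  mk <- function(axis) {
    axis <- axis / sqrt(sum(axis^2))
    structure(list(axis = axis, theta = axis_theta(axis), degenerate = FALSE),
              class = "ellipsoid_model")
  }
  models <- list(mk(c(0, 0, 1)), mk(c(1, 0, 0)), mk(c(1, 0, 1)))
  kept <- orientation_filter(models)
  th <- vapply(kept, `[[`, numeric(1), "theta")
  expect_equal(sort(th), c(45, 90))           # z-aligned excluded
  kept_b <- orientation_filter(models, keep = "below")
  expect_equal(sort(vapply(kept_b, `[[`, numeric(1), "theta")), c(0, 45))
  expect_error(orientation_filter(models, theta_cut = 95), "between")
  # the axial ratio |A_r/a_z| is exactly 1 on the 45-degree boundary
  expect_identical(axis_ratio(c(1, 0, 1)), 1)
  expect_equal(axis_theta(c(1, 0, 1)), 45, tolerance = 1e-12)
})

test_that("diameter distribution reports the tie-broken histogram mode", {
  dd <- diameter_distribution(c(50, 52, 300), bin_width = 10)
  expect_equal(dd$mfd, 55)
  expect_equal(sum(dd$counts), 3L)
  expect_equal(diameter_distribution(123)$mfd, 125)
  # tie: bins [40,50) and [200,210) both hold two -> smallest bin wins
  tie <- diameter_distribution(c(41, 42, 201, 202), bin_width = 10)
  expect_equal(tie$mfd, 45)
  expect_true(diameter_distribution(numeric(0))$empty)
  expect_error(diameter_distribution(1:3, bin_width = 0), "positive")
  # bimodal mixture: MFD sits at the majority mode
  set.seed(6)
  mix <- c(rnorm(300, 80, 8), rnorm(80, 300, 15))
  expect_lt(abs(diameter_distribution(mix)$mfd - 80), 15)
})

test_that("all models are rotation-invariant about z to 1e-9", {
  set.seed(14)
  pts <- cbind(rnorm(300, 0, 80), rnorm(300, 0, 35), rnorm(300, 0, 45))
  ob <- make_object(pts, a_max = 120)
  sm <- sphere_model(ob$object, ob$complex)
  em <- ellipsoid_model(ob$object, ob$complex)
  ang <- 73 * pi / 180
  R <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0), c(0, 0, 1))
  obr <- make_object(pts %*% t(R), a_max = 120)
  smr <- sphere_model(obr$object, obr$complex)
  emr <- ellipsoid_model(obr$object, obr$complex)
  expect_equal(smr$d_d, sm$d_d, tolerance = 1e-9)
  expect_equal(smr$d_smooth, sm$d_smooth, tolerance = 1e-9)
  expect_equal(emr$d_max, em$d_max, tolerance = 1e-9)
  expect_equal(emr$d_min, em$d_min, tolerance = 1e-9)
  expect_equal(emr$theta, em$theta, tolerance = 1e-9)
})
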