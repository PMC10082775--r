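test_that("probe label arithmetic: labels every 40 nt, floor division", {
  expect_length(make_probe(250, 40), 6L)
  expect_length(make_probe(1100, 40), 27L)
  expect_length(make_probe(39, 40), 0L)
  expect_equal(make_probe(120, 40), c(40L, 80L, 120L))
  expect_error(make_probe(0, 40), "positive")
  expect_error(make_probe(250, -1), "positive")
})

test_that("scenes are a deterministic function of the spec", {
  sp <- scene_spec(n_tubules = 2, box = c(6000, 6000, 2500), seed = 5L)
  a <- simulate_scene(sp)
  b <- simulate_scene(sp)
  expect_identical(as.data.frame(a$table), as.data.frame(b$table))
  expect_identical(a$truth$nucleoids, b$truth$nucleoids)
  c <- simulate_scene(scene_spec(n_tubules = 2, box = c(6000, 6000, 2500),
                                 seed = 6L))
  expect_false(identical(as.data.frame(a$table), as.data.frame(c$table)))
  # the generator does not disturb the caller's RNG stream
  set.seed(123); before <- runif(3)
  set.seed(123); invisible(simulate_scene(sp)); after <- runif(3)
  expect_identical(before, after)
})

test_that("localization counts per nucleoid stay within the configured
           range and every localization has one parent", {
  sp <- scene_spec(seed = 7L)
  sim <- simulate_scene(sp)
  per <- table(sim$truth$parent$nucleoid_id[
    sim$truth$parent$parent == "nucleoid"])
  expect_true(all(per >= 10 & per <= 500) ||
              mean(per >= 10 & per <= 500) >= 0.99)
  expect_equal(nrow(sim$truth$parent), nrow(sim$table))
  expect_true(all(sim$truth$parent$parent %in%
                  c("nucleoid", "locus", "background")))
  # channel convention: nucleoid stain in 1, probes in 2
  expect_true(all(sim$table$channel[
    sim$truth$parent$parent == "nucleoid"] == 1L))
  expect_true(all(sim$table$channel[
    sim$truth$parent$parent == "locus"] == 2L))
})

test_that("recovered smoothed diameters of noise-free shell nucleoids are
           a bounded, monotone-biased estimate of the true diameter", {
  sp <- scene_spec(stain_fill = "shell", sigma_xy = 0, sigma_z = 0,
                   blink_mean = 1, background_density = 0,
                   fluor_range = c(60, 160), fluor_density = 1,
                   diameter_meanlog = log(150), diameter_sdlog = 0.3,
                   diameter_range = c(80, 300), n_tubules = 3, seed = 8L)
  sim <- simulate_scene(sp)
  ch <- split_channels(sim$table)
  ov <- count_overlaps(ch[["1"]], loc_table())
  rec <- recovery_rate(ov, sim$truth)
  matched <- rec$per_nucleoid$n_records == 1L
  cent <- t(vapply(ov$records, `[[`, numeric(3), "centroid"))
  gtc <- as.matrix(sim$truth$nucleoids[, c("x", "y", "z")])
  for (k in seq_along(ov$records)) {
    i <- which.min(rowSums((gtc - matrix(cent[k, ], nrow(gtc), 3,
                                         byrow = TRUE))^2))
    true_d <- sim$truth$nucleoids$diameter[i]
    d <- ov$records[[k]]$sphere$d_smooth
    # hull of finitely many shell points: slightly inside the decorated
    # sphere, never beyond true D + 2 * shell thickness (sigma = 0)
    expect_lte(d, true_d + 2 * sp$shell_thickness + 1e-9)
    expect_gte(d, 0.9 * true_d)
  }
})

test_that("CSR generator fills the cube uniformly and reproducibly", {
  a <- simulate_csr(2000, 10000, seed = 3L)
  b <- simulate_csr(2000, 10000, seed = 3L)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_equal(nrow(a), 2000L)
  expect_true(all(loc_coords(a) >= 0 & loc_coords(a) <= 10000))
  expect_gt(mean(a$x), 4000); expect_lt(mean(a$x), 6000)
  expect_equal(nrow(simulate_csr(2, 100, seed = 1L)), 2L)
})

test_that("ground truth round-trips through JSON", {
  sp <- scene_spec(n_tubules = 2, box = c(5000, 5000, 2000), seed = 9L)
  sim <- simulate_scene(sp)
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(sim$truth, path)
  back <- read_ground_truth(path)
  expect_equal(back$nucleoids$diameter, sim$truth$nucleoids$diameter)
  expect_equal(back$nucleoids$n_loci, sim$truth$nucleoids$n_loci)
  expect_equal(back$loci$x, sim$truth$loci$x)
  expect_equal(back$parent$parent, sim$truth$parent$parent)
  expect_error(read_ground_truth("no/such/file.json"), "not found")
})
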