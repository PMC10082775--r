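test_that("H(r) counts pairs strictly below r and saturates at n(n-1)/2", {
  two <- rbind(c(0, 0, 0), c(10, 0, 0))
  expect_equal(cumulative_h(two, c(5, 10, 15)), c(0, 0, 1))  # strict <
  tri <- rbind(c(0, 0, 0), c(10, 0, 0), c(5, 5 * sqrt(3), 0))
  expect_equal(cumulative_h(tri, 15), 3)  # = n(n-1)/2
  expect_warning(h0 <- cumulative_h(matrix(0, 1, 3), c(1, 2)), "fewer")
  expect_equal(h0, c(0, 0))
})

test_that("H, K and the binned histogram match the O(n^2) brute-force
           oracle exactly", {
  set.seed(33)
  pts <- matrix(runif(360, 0, 500), ncol = 3)  # 120 points
  rg <- seq(20, 400, by = 20)
  expect_identical(as.numeric(cumulative_h(pts, rg)), brute_h(pts, rg))
  V <- 500^3
  k <- ripley_k(pts, V, rg)
  expect_identical(k, 2 * V * brute_h(pts, rg) / nrow(pts)^2)
  dh <- distance_histogram(pts, 20, 400)
  expect_identical(as.integer(dh$counts),
                   as.integer(brute_pair_hist(pts, 20, 400)))
})

test_that("K follows the direct substitution cases and the count/distance
           identity holds to machine precision", {
  two <- rbind(c(0, 0, 0), c(5, 0, 0))
  expect_equal(ripley_k(two, 1000, 10), 1000 * (1 / 4) * 2)  # = 500
  expect_equal(ripley_k(two, 1000, 0), 0)
  expect_error(ripley_k(two, -1, 10), "positive")
  set.seed(15)
  pts <- matrix(runif(900, 0, 800), ncol = 3)
  rg <- seq(10, 790, by = 30)
  h <- cumulative_h(pts, rg)
  k <- ripley_k(pts, 123456, rg)
  expect_identical(k, 2 * 123456 * h / nrow(pts)^2)
})

test_that("L inverts the CSR sphere volume and classifies patterns", {
  expect_equal(l_function(4 / 3 * pi * 8, 1)$l, 2)
  expect_equal(l_function(0, 1)$l, 0)
  expect_error(l_function(-1, 1), "non-negative")
  lf <- l_function(c(4 / 3 * pi * 8, 4 / 3 * pi, 0), c(1, 1, 1))
  expect_equal(lf$classification, c("clustered", "CSR", "regular"))
})

test_that("interior CSR evaluation gives K ~ (4/3) pi r^3 and
           mean L - r ~ 0", {
  tb <- simulate_csr(2000, 10000, seed = 77)
  pts <- loc_coords(tb)
  box <- rbind(c(0, 0, 0), c(10000, 10000, 10000))
  subj <- interior_subjects(pts, 1000, bounds = box)
  rg <- seq(100, 1000, by = 50)
  k <- ripley_k(pts, 1e12, rg, subjects = subj)
  csr <- 4 / 3 * pi * rg^3
  expect_lt(max((abs(k - csr) / csr)[rg >= 500]), 0.2)
  lf <- l_function(k, rg)
  expect_lt(abs(mean(lf$l_minus_r)), 15)
})

test_that("histogram differencing equals the cumulative table and
           conserves the total count", {
  pts <- rbind(c(0, 0, 0), c(10, 0, 0), c(5, sqrt(625 - 25), 0))
  # pair distances: 10, 25, 25
  dh <- distance_histogram(pts, 10, 30)
  expect_equal(dh$counts, c(0, 1, 2))
  h <- cumulative_h(pts, seq(10, 30, 10))
  expect_equal(sum(dh$counts), h[3])
  one_pair <- rbind(c(0, 0, 0), c(14, 0, 0))
  expect_equal(sum(distance_histogram(one_pair, 10, 50)$counts == 1), 1)
  expect_error(distance_histogram(pts, 0, 10), "positive")
})

test_that("MFD detection finds planted modes and ignores endpoints", {
  mk <- function(counts) structure(
    list(epsilon = 10, r_max = 10 * length(counts),
         bin_start = 10 * (seq_along(counts) - 1),
         bin_end = 10 * seq_along(counts), counts = counts),
    class = "distance_histogram")
  expect_equal(find_mfds(mk(c(1, 5, 1))), 15)
  expect_length(find_mfds(mk(c(1, 2, 3, 4, 5))), 0)  # monotone: none
  expect_length(find_mfds(mk(c(2, 2, 2))), 0)        # flat: none
  expect_length(find_mfds(mk(c(0, 0, 0))), 0)
  # prominence threshold suppresses minor wiggles
  expect_equal(find_mfds(mk(c(1, 100, 1, 2, 1)), 0.1), 15)
  expect_equal(find_mfds(mk(c(1, 100, 1, 20, 1)), 0.1), c(15, 35))
  # planted bimodal pair-distance construction
  set.seed(18)
  a <- cbind(rnorm(40, 0, 12), rnorm(40, 0, 12), rnorm(40, 0, 12))
  scene <- rbind(a, a + matrix(c(200, 0, 0), 40, 3, byrow = TRUE))
  dh <- distance_histogram(scene, 10, 400)
  mfds <- find_mfds(dh, 0.05)
  expect_true(any(mfds <= 50))             # intra-cluster mode
  expect_true(any(abs(mfds - 200) <= 20))  # planted separation
})

test_that("histogram ratio is unity for identical shapes, scale-invariant,
           and localizes a planted excess", {
  pts <- matrix(runif(300, 0, 300), ncol = 3)
  h1 <- distance_histogram(pts, 30, 300)
  r <- histogram_ratio(h1, h1)
  expect_true(all(r$ratio[!r$undefined] == 1))
  h2 <- h1
  h2$counts <- h1$counts * 2L  # doubled counts, same shape
  r2 <- histogram_ratio(h2, h1)
  expect_true(all(abs(r2$ratio[!r2$undefined] - 1) < 1e-12))
  h3 <- h1
  h3$counts[4] <- h3$counts[4] * 5L
  r3 <- histogram_ratio(h3, h1)
  defined <- which(!r3$undefined)
  expect_equal(which.max(r3$ratio[defined]), match(4, defined))
  h4 <- distance_histogram(pts, 15, 300)
  expect_error(histogram_ratio(h1, h4), "epsilon")
})

test_that("ripley_result assembles monotone H, K, L and a conserving
           histogram", {
  set.seed(40)
  pts <- matrix(runif(600, 0, 1000), ncol = 3)
  rr <- ripley_result(pts, epsilon = 25, r_max = 900)
  expect_true(all(diff(rr$h) >= 0))
  expect_true(all(diff(rr$k) >= 0))
  expect_true(all(diff(rr$l) >= 0))
  expect_equal(rr$k, 2 * rr$volume * rr$h / rr$n^2)
  expect_equal(sum(rr$histogram$counts), rr$h[length(rr$h)])
  expect_equal(rr$k[1] >= 0, TRUE)
})
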