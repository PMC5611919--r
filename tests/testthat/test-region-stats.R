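# Region sampling, clustering summaries, pairwise tests and the clearing
# time-course.

make_surface <- function(nx, ny, idx = 5L) {
  structure(list(surface_index = matrix(idx, nx, ny),
                 valid_mask = matrix(TRUE, nx, ny)), class = "surface_map")
}

test_that("regions holding exactly the requested count return every voxel once", {
  arr <- array(seq_len(20 * 5 * 5), dim = c(20, 5, 5))
  s <- make_surface(5, 5, 3L)
  # slab of 8 pixels x 25 columns = 200 voxels
  rg <- region_spec("all", c(1, 5), c(1, 5), c(0, 8), sample_count = 200)
  ss <- extract_region(arr, s, rg, seed = 1, delta_um = 1)
  expect_equal(ss$n, 200)
  manual <- as.vector(arr[3:10, , ])
  expect_setequal(ss$values, manual)
})

test_that("constant volumes sample the constant and seeds reproduce exactly", {
  arr <- array(2.5, dim = c(30, 6, 6))
  s <- make_surface(6, 6)
  rg <- region_spec("c", c(1, 6), c(1, 6), c(0, 20), sample_count = 50)
  ss <- extract_region(arr, s, rg, seed = 3, delta_um = 1)
  expect_true(all(ss$values == 2.5))
  expect_equal(ss$n, 50)

  set.seed(77)
  arr2 <- array(stats::runif(30 * 36), dim = c(30, 6, 6))
  a <- extract_region(arr2, s, rg, seed = 9, delta_um = 1)
  b <- extract_region(arr2, s, rg, seed = 9, delta_um = 1)
  d <- extract_region(arr2, s, rg, seed = 10, delta_um = 1)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values, d$values))
})

test_that("seeded subsamples stay within two standard errors of the region mean", {
  set.seed(12)
  arr <- array(stats::rnorm(60 * 10 * 10, mean = 5), dim = c(60, 10, 10))
  s <- make_surface(10, 10)
  full <- extract_region(arr, s,
                         region_spec("f", c(1, 10), c(1, 10), c(0, 40),
                                     sample_count = 10^6),
                         seed = 1, delta_um = 1)
  sub <- extract_region(arr, s,
                        region_spec("s", c(1, 10), c(1, 10), c(0, 40),
                                    sample_count = 300),
                        seed = 4, delta_um = 1)
  se <- stats::sd(full$values) / sqrt(300)
  expect_lt(abs(mean(sub$values) - mean(full$values)), 2 * se)
})

test_that("intensity-attenuation pairing computes exact centroids", {
  one <- structure(list(values = rep(2, 5), label = "a", units = "int", n = 5),
                   class = "sample_set")
  two <- structure(list(values = rep(0.4, 5), label = "a", units = "mm^-1", n = 5),
                   class = "sample_set")
  p <- pair_intensity_attenuation(one, two)
  expect_equal(p$centroids$intensity, 2)
  expect_equal(p$centroids$attenuation, 0.4)
  expect_equal(p$centroids$sd_intensity, 0)

  set.seed(5)
  g1i <- stats::rnorm(40, 10); g1a <- stats::rnorm(40, 0.3, 0.02)
  g2i <- stats::rnorm(40, 20); g2a <- stats::rnorm(40, 0.6, 0.02)
  mk <- function(v, lab) structure(list(values = v, label = lab,
                                        units = "", n = length(v)),
                                   class = "sample_set")
  p2 <- pair_intensity_attenuation(list(mk(g1i, "GM"), mk(g2i, "WM")),
                                   list(mk(g1a, "GM"), mk(g2a, "WM")))
  expect_equal(p2$centroids$intensity, c(mean(g1i), mean(g2i)))
  expect_equal(p2$centroids$attenuation, c(mean(g1a), mean(g2a)))
  # centroid ordering matches the generating parameters
  expect_lt(p2$centroids$intensity[1], p2$centroids$intensity[2])
  expect_gt(p2$separation$centroid_distance_pooled_sd, 5)
  expect_error(pair_intensity_attenuation(mk(g1i, "x"), mk(g1a[1:10], "x")),
               "samples")
})

test_that("Bonferroni arithmetic and degenerate groups behave exactly", {
  x <- c(1, 2, 3, 4, 5)
  out <- compare_groups(list(a = x, b = x), alpha = 0.05)
  expect_equal(out$p_value, 1)
  expect_equal(out$p_adjusted, 1)
  expect_false(out$significant)

  # zero-variance identical groups take the p = 1 path without erroring
  z <- compare_groups(list(a = rep(2, 5), b = rep(2, 5)))
  expect_equal(z$p_adjusted, 1)

  set.seed(21)
  g <- list(a = rnorm(20), b = rnorm(20, 0.5), c = rnorm(20, 1))
  out3 <- compare_groups(g)
  expect_equal(nrow(out3), 3)
  expect_equal(out3$p_adjusted, pmin(1, 3 * out3$p_value))
  # relabeling leaves the adjusted p values unchanged
  out3r <- compare_groups(g[c(3, 1, 2)])
  expect_setequal(round(out3r$p_adjusted, 12), round(out3$p_adjusted, 12))
  # a raw p of 0.02 with three pairs is no longer significant at 0.05
  mid <- out3[out3$p_value > 0.0167 & out3$p_value < 0.05, ]
  if (nrow(mid)) expect_false(any(mid$significant))
})

test_that("adjusted p values grow with the number of comparisons", {
  set.seed(22)
  a <- rnorm(30); b <- rnorm(30, 0.4); c3 <- rnorm(30, 5); d <- rnorm(30, 9)
  p2 <- compare_groups(list(a = a, b = b))
  p4 <- compare_groups(list(a = a, b = b, c = c3, d = d))
  row_ab <- p4[p4$group1 == "a" & p4$group2 == "b", ]
  expect_gt(row_ab$p_adjusted, p2$p_adjusted)
  expect_equal(row_ab$p_value, p2$p_value)
})

test_that("well-separated groups are significant and agree with a permutation oracle", {
  set.seed(30)
  wm <- rnorm(200, 12, 1.5)
  gm <- rnorm(200, 9, 1.5)
  pl <- rnorm(200, 16, 2.5)
  out <- compare_groups(list(WM = wm, GM = gm, plaque = pl), alpha = 0.05)
  expect_true(all(out$significant))
  expect_true(all(out$p_adjusted < 0.001))
  # permutation oracle on one pair
  obs <- mean(wm) - mean(gm)
  pool <- c(wm, gm)
  perm <- replicate(10000, {
    idx <- sample.int(400, 200)
    mean(pool[idx]) - mean(pool[-idx])
  })
  p_perm <- (1 + sum(abs(perm) >= abs(obs))) / 10001
  expect_lt(p_perm, 0.001)
})

test_that("null resampling keeps the Bonferroni family-wise error controlled", {
  n_rep <- 1000
  frac <- with_seed_local(808, {
    hits <- 0L
    total <- 0L
    for (r in seq_len(n_rep)) {
      g <- list(a = rnorm(50), b = rnorm(50), c = rnorm(50))
      out <- compare_groups(g, alpha = 0.05)
      hits <- hits + sum(out$significant)
      total <- total + nrow(out)
    }
    hits / total
  })
  se <- sqrt(0.05 * 0.95 / (3 * n_rep))
  expect_lte(frac, 0.05 + 2 * se)
})

test_that("clearing time-courses normalize to the first measurement", {
  nz <- 40
  mk_tom <- function(scale) tomogram(array(sqrt(scale), dim = c(nz, 5, 5)) * (1 + 0i),
                                     1e-3)
  s <- make_surface(5, 5)
  roi <- region_spec("roi", c(1, 5), c(1, 5), c(0, 20))
  toms <- list(mk_tom(4), mk_tom(4), mk_tom(4))
  tc <- clearing_timecourse(toms, list(s, s, s), roi, times = c(0, 30, 60))
  expect_equal(tc$points$mean_amplitude, rep(1, 3))
  expect_equal(unname(tc$trend["slope"]), 0)
  expect_equal(tc$points$mean_amplitude[1], 1)
  expect_error(clearing_timecourse(toms, list(s, s, s), roi,
                                   times = c(0, 60, 30)), "increasing")
})

test_that("stepwise-reduced backscatter gives strictly decreasing amplitudes", {
  inst <- test_instrument(512)
  toms <- list(); surfs <- list()
  for (i in seq_along(c(0.004, 0.003, 0.002))) {
    bs <- c(0.004, 0.003, 0.002)[i]
    tr <- layer_truth(0.3, backscatter = bs, nx = 10, ny = 10,
                      extent = 60, step = 2, top = 15)
    v <- simulate_volume(tr, inst, seed = 40 + i, noise = FALSE)
    toms[[i]] <- reconstruct(v)
    surfs[[i]] <- detect_surface(toms[[i]])
  }
  roi <- region_spec("roi", c(1, 10), c(1, 10), c(5, 40))
  tc <- clearing_timecourse(toms, surfs, roi, times = c(0, 30, 60))
  expect_equal(tc$points$mean_amplitude[1], 1)
  expect_true(all(diff(tc$points$mean_amplitude) < 0))
  expect_lt(unname(tc$trend["slope"]), 0)
})
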