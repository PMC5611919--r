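# k-space resampling, background removal, dispersion, FFT reconstruction,
# surface detection and en-face projection.

test_that("resampling is the identity for input already uniform in k", {
  k <- seq(2 * pi / 685, 2 * pi / 425, length.out = 256)
  lambda <- 2 * pi / rev(k)          # wavelength axis whose k grid is uniform
  vals <- sin(seq_len(256) / 7) + 2
  out <- resample_to_k(vals, lambda)
  expect_rel_equal(out$values, rev(vals), 1e-6)
})

test_that("constant spectra are interpolation-invariant", {
  lambda <- seq(425, 685, length.out = 200)
  out <- resample_to_k(rep(3.5, 200), lambda)
  expect_equal(out$values, rep(3.5, 200), tolerance = 1e-9)
})

test_that("a pure fringe resamples to the predicted depth bin", {
  lambda <- seq(425, 685, length.out = 1024)
  k_in <- 2 * pi / lambda
  z0 <- 30000  # nm
  vals <- cos(2 * k_in * z0)
  rs <- resample_to_k(vals, lambda)
  P <- length(rs$k)
  A <- Mod(stats::fft(rs$values))[seq_len(P %/% 2)]
  dk <- diff(rs$k[1:2])
  delta_nm <- pi / (P * dk)
  expect_equal(which.max(A) - 1, round(z0 / delta_nm))
  # oracle cross-check: nonuniform DFT of the raw samples peaks at z0
  zg <- seq(25000, 35000, by = 10)
  expect_lt(abs(zg[which.max(oracle_ascan(vals, k_in, zg))] - z0), 200)
})

test_that("non-monotone wavelength calibration is rejected", {
  lambda <- seq(425, 685, length.out = 64)
  lambda[10] <- lambda[12]
  expect_error(resample_to_k(rnorm(64), lambda), "monotone")
})

test_that("background removal handles estimate, supplied and zero references", {
  lambda <- seq(425, 685, length.out = 128)
  one <- 100 + 20 * cos(seq_len(128) / 5)
  vol <- spectral_volume(array(rep(one, 12), dim = c(128, 4, 3)), lambda)
  # identical A-lines, estimate mode: exact cancellation
  out <- remove_background(vol, "estimate")
  expect_equal(max(abs(out$counts)), 0)
  # explicit zero background: identity
  out0 <- remove_background(vol, rep(0, 128))
  expect_equal(out0$counts, vol$counts + 0)
  expect_error(remove_background(vol, rep(0, 100)), "length")
})

test_that("estimate-mode removal suppresses the DC pedestal of random-phase fringes", {
  set.seed(7)
  lambda <- seq(425, 685, length.out = 512)
  k <- 2 * pi / lambda
  n_lines <- 64
  pedestal <- 500
  spectra <- sapply(seq_len(n_lines), function(j) {
    pedestal + 30 * cos(2 * k * 25000 + stats::runif(1, 0, 2 * pi))
  })
  vol <- spectral_volume(array(spectra, dim = c(512, n_lines, 1)), lambda)
  corrected <- remove_background(vol, "estimate")
  tom <- reconstruct(corrected, background = NULL)
  A <- Mod(tom$field[, 1, 1])
  dc <- A[1]
  fringe <- max(A[-(1:3)])
  expect_gt(20 * log10(fringe / dc), 20)
})

test_that("dispersion application is unit-modulus and invertible", {
  k <- seq(2 * pi / 685, 2 * pi / 425, length.out = 256)
  spec <- complex(real = rnorm(256), imaginary = rnorm(256))
  model <- dispersion_model(c(a2 = 14, a3 = -6))
  # zero model is the identity
  expect_equal(apply_dispersion(spec, k, dispersion_model(0)), spec + 0i)
  # model followed by its negation restores the input
  round_trip <- apply_dispersion(apply_dispersion(spec, k, model), k,
                                 negate_dispersion(model))
  expect_lt(max(Mod(round_trip - spec)) / max(Mod(spec)), 1e-12)
  # magnitude untouched
  expect_lt(max(abs(Mod(apply_dispersion(spec, k, model)) - Mod(spec))), 1e-12)
})

test_that("reconstruction conserves spectral energy (Parseval)", {
  tr <- point_truth(c(30, 55), 0.004)
  v <- simulate_volume(tr, test_instrument(512), seed = 1,
                       noise = FALSE, quantize = FALSE)
  corrected <- remove_background(v)
  rs <- specoct:::resample_volume(corrected)
  tom <- reconstruct(corrected, background = NULL, keep = "full")
  e_spec <- sum(rs$spectra^2)
  e_depth <- sum(Mod(tom$field)^2)
  expect_rel_equal(e_depth, e_spec, 1e-6)
})

test_that("a single simulated reflector reconstructs within one pixel", {
  inst <- test_instrument(512)
  z0 <- 47.3
  tr <- point_truth(z0, 0.004)
  v <- simulate_volume(tr, inst, seed = 1, noise = FALSE)
  tom <- reconstruct(v)
  got <- which.max(tomogram_intensity(tom)[, 1, 1]) - 1
  expect_lte(abs(got - z0 * 1000 / (tom$axial_pitch * 1e6)), 1)
})

test_that("two reflectors two micrometres apart are resolved with the full band", {
  inst <- test_instrument(1024)
  tr <- point_truth(c(50, 52), 0.004)
  v <- simulate_volume(tr, inst, seed = 1, noise = FALSE, quantize = FALSE)
  tom <- reconstruct(v)
  pitch <- tom$axial_pitch * 1000
  A <- Mod(tom$field[, 1, 1])
  sel <- round(48 / pitch):round(54 / pitch)
  a <- A[sel]
  pk <- which(diff(sign(diff(a))) == -2) + 1
  expect_gte(length(pk), 2)
  # the two dominant maxima are the reflectors; the dip between them is deep
  pk2 <- pk[order(a[pk], decreasing = TRUE)][1:2]
  dip <- min(a[min(pk2):max(pk2)])
  expect_lt(dip, 0.8 * min(a[pk2]))
})

test_that("dispersion estimation corrects an injected mismatch", {
  inst <- test_instrument(1024)
  tr <- point_truth(seq(20, 100, length.out = 32), 0.005, nx = 32,
                    axial_extent = 120, axial_step = 2)
  lim <- psf_fwhm_um(reconstruct(
    simulate_volume(tr, inst, seed = 1, noise = FALSE)), ix = 16)
  inject <- dispersion_model(c(a2 = 50, a3 = 0))
  v <- simulate_volume(tr, inst, dispersion = inject, seed = 1, noise = FALSE)
  est <- estimate_dispersion(v, order = 3)
  expect_true(attr(est, "converged"))
  corr <- psf_fwhm_um(reconstruct(v, dispersion = est), ix = 16)
  expect_lt(corr / lim, 1.1)
  # recovered coefficients approximately negate the injection
  expect_lt(abs(est$coefficients[1] + 50), 2)
})

test_that("null dispersion volumes estimate near-zero coefficients", {
  inst <- test_instrument(1024)
  tr <- point_truth(seq(20, 100, length.out = 32), 0.005, nx = 32,
                    axial_extent = 120, axial_step = 2)
  v <- simulate_volume(tr, inst, seed = 1, noise = FALSE)
  est <- estimate_dispersion(v, order = 3)
  lim <- psf_fwhm_um(reconstruct(v), ix = 16)
  corr <- psf_fwhm_um(reconstruct(v, dispersion = est), ix = 16)
  expect_lt(corr / lim, 1.01)
})

test_that("estimation is invariant to a global depth shift of the scene", {
  # a rigid depth shift is a linear spectral phase; the recovered quadratic
  # and cubic coefficients must not change
  inst <- test_instrument(1024)
  inject <- dispersion_model(c(a2 = 20, a3 = -8))
  ests <- lapply(c(0, 20), function(off) {
    tr <- point_truth(off + seq(20, 100, length.out = 32), 0.005, nx = 32,
                      axial_extent = 140, axial_step = 2)
    v <- simulate_volume(tr, inst, dispersion = inject, seed = 1,
                         noise = FALSE)
    estimate_dispersion(v, order = 3)
  })
  expect_lt(max(abs(ests[[1]]$coefficients - ests[[2]]$coefficients)), 2)
  expect_lt(max(abs(ests[[1]]$coefficients - c(-20, 8))), 2)
})

test_that("surface detection finds a noiseless step exactly", {
  nz <- 200
  I <- array(0, dim = c(nz, 6, 5))
  I[40:nz, , ] <- 4
  tom <- tomogram(array(sqrt(I), dim = dim(I)) * (1 + 0i), 5.6e-4)
  s <- detect_surface(tom, smoothing_px = 1)
  expect_true(all(s$valid_mask))
  expect_true(all(s$surface_index == 40))
})

test_that("pure-noise volumes give an all-invalid surface", {
  set.seed(5)
  I <- array(abs(rnorm(256 * 8 * 8)), dim = c(256, 8, 8))
  tom <- tomogram(array(sqrt(I), dim = dim(I)) * (1 + 0i), 5.6e-4)
  s <- detect_surface(tom)
  expect_false(any(s$valid_mask))
})

test_that("a tilted phantom surface is recovered to within a pixel", {
  tilt <- c(0.15, 0)
  tr <- layer_truth(0.35, nx = 24, ny = 8, extent = 160, step = 2,
                    tilt = tilt, backscatter = 0.005)
  v <- simulate_volume(tr, test_instrument(1024), seed = 4,
                       noise = FALSE)
  tom <- reconstruct(v)
  s <- detect_surface(tom)
  expect_true(all(s$valid_mask))
  pitch_um <- tom$axial_pitch * 1000
  true_idx <- 1.36 * tr$surface_um / pitch_um
  # least-squares plane through the detected surface
  df <- data.frame(s = as.vector(s$surface_index),
                   x = as.vector(row(s$surface_index)),
                   y = as.vector(col(s$surface_index)))
  fit <- stats::lm(s ~ x + y, df)
  true_fit <- stats::lm(as.vector(true_idx) ~ df$x + df$y)
  expect_lt(abs(stats::coef(fit)[2] - stats::coef(true_fit)[2]), 0.15)
  # agreement within one phantom axial voxel (2 um) everywhere
  voxel_bins <- 2 * 1.36 / pitch_um
  expect_lt(max(abs(stats::fitted(fit) - stats::fitted(true_fit))), voxel_bins)
})

test_that("en-face projection means are exact", {
  nz <- 60
  tom <- tomogram(array(sqrt(2.5), dim = c(nz, 4, 4)) * (1 + 0i), 1e-3)
  s <- structure(list(surface_index = matrix(5L, 4, 4),
                      valid_mask = matrix(TRUE, 4, 4)), class = "surface_map")
  ef <- enface_projection(tom, s, 0, 30)
  expect_equal(unname(as.vector(ef)), rep(2.5, 16))

  # 3-voxel toy slab (1, 2, 3) -> mean 2
  I <- array(0, dim = c(10, 1, 1))
  I[5:7, 1, 1] <- 1:3
  s1 <- structure(list(surface_index = matrix(5L, 1, 1),
                       valid_mask = matrix(TRUE, 1, 1)), class = "surface_map")
  ef1 <- enface_projection(I, s1, 0, 3, delta_um = 1)
  expect_equal(as.vector(ef1), 2)
})

test_that("en-face projection equals an explicit per-pixel loop", {
  set.seed(8)
  I <- array(stats::runif(40 * 6 * 5), dim = c(40, 6, 5))
  sidx <- matrix(sample(3:8, 30, replace = TRUE), 6, 5)
  s <- structure(list(surface_index = sidx, valid_mask = matrix(TRUE, 6, 5)),
                 class = "surface_map")
  delta_um <- 2
  ef <- enface_projection(I, s, 4, 20, delta_um = delta_um)
  manual <- matrix(NA_real_, 6, 5)
  for (ix in 1:6) for (iy in 1:5) {
    i0 <- sidx[ix, iy] + floor(4 / delta_um)
    i1 <- sidx[ix, iy] + ceiling(20 / delta_um) - 1
    manual[ix, iy] <- mean(I[i0:i1, ix, iy])
  }
  expect_equal(unclass(ef), manual, ignore_attr = TRUE)
})

test_that("surface-referenced projection is invariant to a common depth offset", {
  set.seed(9)
  I <- array(stats::runif(60 * 4 * 4), dim = c(60, 4, 4))
  sidx <- matrix(sample(5:10, 16, replace = TRUE), 4, 4)
  s <- structure(list(surface_index = sidx, valid_mask = matrix(TRUE, 4, 4)),
                 class = "surface_map")
  off <- 7L
  I2 <- array(0, dim = c(60 + off, 4, 4))
  I2[(off + 1):(off + 60), , ] <- I
  s2 <- structure(list(surface_index = sidx + off,
                       valid_mask = matrix(TRUE, 4, 4)), class = "surface_map")
  expect_equal(enface_projection(I, s, 0, 20, delta_um = 2),
               enface_projection(I2, s2, 0, 20, delta_um = 2),
               ignore_attr = TRUE)
})

test_that("resampled FFT of a chirp-free fringe matches the direct FFT", {
  k_uniform <- seq(2 * pi / 685, 2 * pi / 425, length.out = 512)
  fringe <- cos(2 * k_uniform * 20000) * exp(-((k_uniform - mean(k_uniform)) /
    (diff(range(k_uniform)) / 4))^2)
  lambda <- 2 * pi / rev(k_uniform)
  rs <- resample_to_k(rev(fringe), lambda)
  direct <- Mod(stats::fft(fringe))[1:256]
  ours <- Mod(stats::fft(rs$values))[1:256]
  expect_lt(abs(max(ours) - max(direct)) / max(direct), 1e-3)
  expect_equal(which.max(ours), which.max(direct))
})
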