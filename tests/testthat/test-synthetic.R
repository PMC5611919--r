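# Phantom construction and the interferogram forward model.

test_that("flat single-layer phantom has a constant surface", {
  ph <- phantom_spec(lateral_shape = c(8, 6),
                     layers = list(phantom_layer(20, 0.4)))
  tr <- build_phantom(ph, 100, 2)
  expect_true(all(tr$surface_um == 20))
  expect_true(all(tr$surface_zindex == tr$surface_zindex[1, 1]))
})

test_that("two-layer phantom yields piecewise-constant attenuation with one transition", {
  ph <- phantom_spec(lateral_shape = c(4, 4),
                     layers = list(phantom_layer(10, 0.39, 0.01),
                                   phantom_layer(60, 0.35, 0.01)))
  tr <- build_phantom(ph, 120, 2)
  for (ix in 1:4) for (iy in 1:4) {
    mu_line <- tr$mu[ix, iy, ]
    vals <- unique(mu_line[mu_line > 0])
    expect_equal(sort(vals, decreasing = TRUE), c(0.39, 0.35))
    # exactly one 0.39 -> 0.35 transition
    r <- rle(mu_line[mu_line > 0])
    expect_equal(r$values, c(0.39, 0.35))
  }
})

test_that("spherical inclusion voxelization matches brute-force rasterization", {
  ctr <- c(21, 17, 40)
  rad <- 15
  ph <- phantom_spec(lateral_shape = c(20, 20), lateral_pitch = 2,
                     layers = list(phantom_layer(5, 0.3, 0.01)),
                     inclusions = list(phantom_inclusion(ctr, rad, 4)))
  step <- 2
  tr <- build_phantom(ph, 100, step)
  inc_cls <- which(vapply(tr$classes, function(c) c$kind == "inclusion", logical(1)))
  got <- sum(tr$scatterers$class %in% inc_cls)
  # oracle: triple loop over voxel centres testing Euclidean distance
  expected <- 0L
  for (ix in 1:20) for (iy in 1:20) for (iz in seq_along(tr$z_centers)) {
    x <- (ix - 0.5) * 2; y <- (iy - 0.5) * 2; z <- tr$z_centers[iz]
    if (z < 5) next  # above the layer: no scatterer to reassign
    if ((x - ctr[1])^2 + (y - ctr[2])^2 + (z - ctr[3])^2 <= rad^2) {
      expected <- expected + 1L
    }
  }
  expect_equal(got, expected)
})

test_that("invalid phantom geometry is rejected with a diagnostic", {
  expect_error(
    build_phantom(phantom_spec(layers = list(phantom_layer(150, 0.3))), 100, 2),
    "below axial_extent"
  )
  overlapping <- list(phantom_inclusion(c(20, 20, 40), 12),
                      phantom_inclusion(c(25, 20, 45), 12))
  expect_error(
    build_phantom(phantom_spec(layers = list(phantom_layer(5, 0.3)),
                               inclusions = overlapping), 100, 2),
    "overlap"
  )
})

test_that("source envelope has the stated centre and FWHM", {
  # 1025 pixels put the 555 nm centre exactly on the wavelength grid
  inst <- test_instrument(1025)
  env <- source_envelope(inst)
  px <- diff(env$wavelength[1:2])
  half <- which(env$power >= 0.5)
  expect_lt(abs(env$wavelength[min(half)] - (555 - 78)), px + 1e-9)
  expect_lt(abs(env$wavelength[max(half)] - (555 + 78)), px + 1e-9)
  # symmetric about the centre wavelength with flat quantum efficiency
  i_c <- which.min(abs(env$wavelength - 555))
  m <- min(i_c - 1, length(env$power) - i_c)
  expect_equal(env$power[i_c - seq_len(m)], env$power[i_c + seq_len(m)],
               tolerance = 1e-9)
  # rectangle-rule integral equals explicit summation
  s <- 0
  for (p in env$power) s <- s + p * px
  expect_equal(sum(env$power) * px, s)
})

test_that("quantum-efficiency weighting reshapes the envelope", {
  qe <- cbind(c(425, 500, 555, 685), c(0.4, 1, 0.9, 0.3))
  inst <- test_instrument(512, qe_profile = qe)
  env <- source_envelope(inst)
  i_c <- which.min(abs(env$wavelength - 555))
  m <- 100
  expect_false(isTRUE(all.equal(env$power[i_c - seq_len(m)],
                                env$power[i_c + seq_len(m)])))
  expect_equal(max(env$power), 1)
})

test_that("simulation is bit-identical for identical seeds", {
  tr <- layer_truth(0.35, nx = 6, ny = 6, extent = 100, step = 4)
  inst <- test_instrument(256)
  v1 <- simulate_volume(tr, inst, seed = 11)
  v2 <- simulate_volume(tr, inst, seed = 11)
  v3 <- simulate_volume(tr, inst, seed = 12)
  expect_identical(v1$counts, v2$counts)
  expect_false(identical(v1$counts, v3$counts))
})

test_that("an empty phantom reconstructs to noise only", {
  ph <- phantom_spec(lateral_shape = c(6, 6), layers = list())
  tr <- build_phantom(ph, 100, 2)
  v <- simulate_volume(tr, test_instrument(512), seed = 2)
  tom <- reconstruct(v)
  # speckle-smoothed amplitude A-scans carry no peak above the background
  A <- Mod(tom$field)[5:tom$n_depth, , ]
  sm <- apply(matrix(A, nrow = dim(A)[1]), 2,
              function(col) stats::filter(col, rep(1 / 5, 5), sides = 1))
  sm <- sm[!is.na(sm)]
  expect_lt(max(sm), mean(sm) + 5 * stats::sd(sm))
  expect_false(any(detect_surface(tom)$valid_mask))
})

test_that("a single point scatterer lands on the depth bin the NUDFT predicts", {
  inst <- test_instrument(512)
  for (z0 in c(25.3, 60.7)) {
    tr <- point_truth(z0, 0.004)
    v <- simulate_volume(tr, inst, seed = 1, noise = FALSE, quantize = FALSE)
    vol <- remove_background(v)
    tom <- reconstruct(vol)
    got_bin <- which.max(Mod(tom$field[, 1, 1]))
    # oracle: nonuniform DFT of the detected spectrum on a fine depth grid
    k <- 2 * pi / vol$wavelength
    z_grid <- seq(0, 120, by = 0.05) * 1000
    resp <- oracle_ascan(as.vector(vol$counts[, 1, 1]), k, z_grid)
    z_pk_um <- z_grid[which.max(resp)] / 1000
    expect_lt(abs(got_bin - (round(z_pk_um / (tom$axial_pitch * 1000)) + 1)), 2)
  }
})

test_that("scatterers at geometric depth z image at optical depth n z", {
  inst <- test_instrument(512)
  n_med <- 1.36
  tr <- point_truth(40, 0.004, n = n_med)
  v <- simulate_volume(tr, inst, seed = 1, noise = FALSE)
  tom <- reconstruct(v)
  got_bin <- which.max(tomogram_intensity(tom)[, 1, 1])
  expect_lt(abs(got_bin - 1 - n_med * 40 / (tom$axial_pitch * 1000)), 1)
})

test_that("reflectors at z and 2z map to bins in ratio two", {
  inst <- test_instrument(512)
  b <- sapply(c(30, 60), function(z0) {
    v <- simulate_volume(point_truth(z0, 0.004), inst, seed = 1, noise = FALSE)
    which.max(tomogram_intensity(reconstruct(v))[, 1, 1]) - 1
  })
  expect_lte(abs(b[2] - 2 * b[1]), 1)
})

test_that("sensitivity roll-off attenuates by the stated dB per mm", {
  # wide grid keeps both peaks in the shallow half of the depth range,
  # where resampling losses are negligible against the 1 dB budget
  inst <- test_instrument(8192)
  tr <- point_truth(c(100, 1100), 0.004, axial_extent = 1150, axial_step = 2)
  v <- simulate_volume(tr, inst, seed = 1, noise = FALSE, quantize = FALSE)
  tom <- reconstruct(v)
  I <- tomogram_intensity(tom)[, 1, 1]
  pitch <- tom$axial_pitch * 1000
  e1 <- sum(I[round(100 / pitch) + (-5:6)])
  e2 <- sum(I[round(1100 / pitch) + (-5:6)])
  drop_db <- 10 * log10(e1 / e2)
  expect_lt(abs(drop_db - 24), 1)
})

test_that("interference term is linear in scatterer amplitude when weak", {
  inst <- test_instrument(512)
  peaks <- sapply(c(0.005, 0.01), function(a) {
    v <- simulate_volume(point_truth(45, a), inst, seed = 1,
                         noise = FALSE, quantize = FALSE)
    max(Mod(reconstruct(v)$field[, 1, 1]))
  })
  expect_lt(abs(peaks[2] / peaks[1] - 2), 0.02)
})

test_that("bit depth outside the supported camera range is rejected", {
  expect_error(instrument_spec(bit_depth = 6), "bit_depth")
  expect_error(instrument_spec(bit_depth = 20), "bit_depth")
  expect_error(instrument_spec(source_fwhm = 0), "source_fwhm")
  expect_error(instrument_spec(n_spectral_pixels = 8), "n_spectral_pixels")
})

test_that("homogeneous-layer decay recovers the ground-truth coefficient", {
  # noiseless forward model, 100 A-lines, roll-off compensated
  tr <- layer_truth(0.5, nx = 10, ny = 10, speckle = FALSE)
  v <- simulate_volume(tr, test_instrument(2048), seed = 3, noise = FALSE)
  tom0 <- reconstruct(v)
  s <- detect_surface(tom0)
  tom <- compensate_rolloff(tom0)
  g <- global_attenuation_map(tom, s, fit_depth = 0.1,
                              delta = tom$axial_pitch / 1.36,
                              roundtrip = "double", offset_px = 5)
  expect_gt(sum(g$valid), 90)
  expect_lt(abs(mean(g$mu[g$valid]) - 0.5) / 0.5, 0.1)
})
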