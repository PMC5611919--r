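# Shared fixture builders. Everything is generated in code at test time;
# grids are kept small so the whole suite runs at desk scale.

test_instrument <- function(n_pixels = 512, reference_level = 2, ...) {
  instrument_spec(n_spectral_pixels = n_pixels,
                  reference_level = reference_level, ...)
}

quiet_noise <- list(shot_scale = 1, excess_intensity_noise_sd = 0.005,
                    read_noise_sd = 2)

# Ground truth holding hand-placed point scatterers (bypasses the layer
# rasterizer) for mirror/PSF style tests. One scatterer per entry of `zs`,
# distributed over the A-lines in order (recycled), so a single-line phantom
# holds all of them and an nx-line phantom with nx depths gets one each.
point_truth <- function(zs, amplitudes, nx = 1, ny = 1, n = 1,
                        axial_extent = 120, axial_step = 2,
                        profile = NULL) {
  ph <- phantom_spec(lateral_shape = c(nx, ny), refractive_index = n,
                     layers = list())
  tr <- build_phantom(ph, axial_extent, axial_step)
  k <- length(zs)
  lines <- (seq_len(k) - 1L) %% (nx * ny)
  tr$scatterers <- data.frame(
    ix = lines %% nx + 1L, iy = lines %/% nx + 1L,
    z = zs, amplitude = rep(amplitudes, length.out = k),
    class = 1L
  )
  tr$classes <- list(list(kind = "inclusion", profile = profile))
  tr
}

# Nonuniform discrete Fourier transform oracle: magnitude of the depth
# response of a sampled spectrum at arbitrary depths z (nm axis, k rad/nm).
oracle_ascan <- function(values, k, z_nm) {
  vapply(z_nm, function(z) Mod(sum(values * exp(-1i * 2 * k * z))), numeric(1))
}

# Amplitude-FWHM of the brightest peak of one reconstructed A-line.
psf_fwhm_um <- function(tom, ix = 1, iy = 1) {
  fwhm_of_peak_local(tom$depth_um, Mod(tom$field[, ix, iy]))
}

# local copy of the interpolated-FWHM helper (kept independent of the
# package internals so PSF checks do not reuse the code they validate)
fwhm_of_peak_local <- function(x, y) {
  i <- which.max(y)
  half <- y[i] / 2
  jl <- max(which(y[seq_len(i - 1)] <= half))
  left <- x[jl] + (x[jl + 1] - x[jl]) * (half - y[jl]) / (y[jl + 1] - y[jl])
  after <- y[seq(i + 1, length(y))]
  jr <- i + which(after <= half)[1] - 1
  right <- x[jr] + (x[jr + 1] - x[jr]) * (half - y[jr]) / (y[jr + 1] - y[jr])
  right - left
}

# Small speckled single-layer brain-like phantom.
layer_truth <- function(mu, backscatter = 0.002, nx = 24, ny = 24,
                        top = 25, extent = 250, step = 1, speckle = TRUE,
                        tilt = c(0, 0), jitter = TRUE) {
  ph <- phantom_spec(lateral_shape = c(nx, ny), lateral_pitch = 2,
                     layers = list(phantom_layer(top, mu, backscatter)),
                     surface_tilt = tilt, speckle = speckle,
                     axial_jitter = jitter)
  build_phantom(ph, extent, step)
}

with_seed_local <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), .Machine$double.eps)),
            tol)
}
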