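# Synthetic interferogram generator.
#
# Emulates a spectrometer-based visible-light OCM instrument imaging layered
# brain-like phantoms, so that every downstream processing stage can be
# exercised against known ground truth. The forward model is a
# sparse-scatterer sum, not a wave simulation: each voxel of the phantom
# contributes one discrete scatterer (or the coherent sum of several random
# sub-resolution scatterers when speckle is enabled) whose fringe
# contribution is exp(i 2 k n z). Amplitudes carry Beer-Lambert attenuation,
# wavelength-dependent backscatter, optional chromophore absorption, and the
# spectrometer's depth roll-off. Detected spectra are envelope-weighted,
# interfered with a reference field, corrupted by shot/excess/read noise and
# quantized to the camera bit depth.
#
# Attenuation convention: a phantom layer with attenuation mu (mm^-1)
# produces reconstructed *intensity* decaying as exp(-2 mu z) with geometric
# depth z, i.e. mu is the coefficient recovered by the per-pixel
# (round-trip) estimator and equals half the decay rate of a plain
# exponential fit to intensity versus depth.

#' Instrument description for the synthetic OCM
#'
#' Captures the source spectrum, spectrometer sampling, camera bit depth,
#' sensitivity roll-off and noise model of a visible-light spectral-domain
#' OCM. Defaults follow a broadband supercontinuum system: detected band
#' 425-685 nm, centre wavelength 555 nm, source FWHM 156 nm, 12-bit line
#' camera, roll-off 24 dB/mm.
#'
#' @param wavelength_min,wavelength_max Detected band edges in nm.
#' @param center_wavelength Source centre wavelength in nm.
#' @param source_fwhm Source FWHM bandwidth in nm (> 0).
#' @param n_spectral_pixels Number of spectrometer pixels (>= 16). The full
#'   instrument uses 8192; reduced grids are supported for desk-scale runs.
#' @param bit_depth Camera bit depth, within `[8, 16]`.
#' @param rolloff_db_mm Sensitivity roll-off in dB of intensity per mm of
#'   optical depth (>= 0).
#' @param reference_level Reference-arm field amplitude (relative units).
#' @param full_scale_fraction Fraction of the ADC range occupied by the peak
#'   of the reference spectrum.
#' @param noise_model List with `shot_scale` (variance of the Gaussian shot
#'   term per count), `excess_intensity_noise_sd` (relative sd of the
#'   multiplicative excess-intensity term, mimicking supercontinuum RIN) and
#'   `read_noise_sd` (additive, in counts). All >= 0.
#' @param qe_profile Relative quantum efficiency of the camera versus
#'   wavelength: `NULL` (flat), a function of wavelength (nm), or a
#'   two-column matrix/data frame of (wavelength, qe) interpolated
#'   piecewise-linearly. Normalized to peak 1.
#' @return An object of class `instrument_spec`.
#' @export
instrument_spec <- function(wavelength_min = 425, wavelength_max = 685,
                            center_wavelength = 555, source_fwhm = 156,
                            n_spectral_pixels = 8192, bit_depth = 12,
                            rolloff_db_mm = 24, reference_level = 1,
                            full_scale_fraction = 0.6,
                            noise_model = list(shot_scale = 1,
                                               excess_intensity_noise_sd = 0.02,
                                               read_noise_sd = 2),
                            qe_profile = NULL) {
  if (!(wavelength_min < center_wavelength && center_wavelength < wavelength_max)) {
    stopf("need wavelength_min < center_wavelength < wavelength_max")
  }
  assert_scalar_num(source_fwhm, "source_fwhm", min = 0, strict = TRUE)
  assert_scalar_num(rolloff_db_mm, "rolloff_db_mm", min = 0)
  assert_scalar_num(reference_level, "reference_level", min = 0)
  if (n_spectral_pixels < 16) stopf("`n_spectral_pixels` must be >= 16")
  if (bit_depth < 8 || bit_depth > 16) {
    stopf("`bit_depth` must be within [8, 16], got %s", bit_depth)
  }
  nm <- utils::modifyList(
    list(shot_scale = 1, excess_intensity_noise_sd = 0.02, read_noise_sd = 2),
    noise_model %||% list()
  )
  for (f in names(nm)) assert_scalar_num(nm[[f]], paste0("noise_model$", f), min = 0)
  qe_fun <- resolve_qe(qe_profile)
  structure(
    list(
      wavelength_min = wavelength_min, wavelength_max = wavelength_max,
      center_wavelength = center_wavelength, source_fwhm = source_fwhm,
      n_spectral_pixels = as.integer(n_spectral_pixels),
      bit_depth = as.integer(bit_depth),
      rolloff_db_mm = rolloff_db_mm,
      reference_level = reference_level,
      full_scale_fraction = full_scale_fraction,
      noise_model = nm,
      qe_profile = qe_fun
    ),
    class = "instrument_spec"
  )
}

resolve_qe <- function(qe_profile) {
  if (is.null(qe_profile)) return(NULL)
  if (is.function(qe_profile)) return(qe_profile)
  tab <- as.matrix(qe_profile)
  if (ncol(tab) != 2 || nrow(tab) < 2) {
    stopf("`qe_profile` must be a function or a 2-column (wavelength, qe) table")
  }
  f <- stats::approxfun(tab[, 1], tab[, 2], rule = 2)
  peak <- max(tab[, 2])
  function(l) f(l) / peak
}

#' Spectrometer wavelength axis of an instrument
#'
#' Pixel-to-wavelength calibration of the synthetic spectrometer: linear in
#' wavelength across the detected band.
#'
#' @param instrument An `instrument_spec`.
#' @return Wavelength in nm, one value per spectral pixel (ascending).
#' @export
instrument_wavelength <- function(instrument) {
  seq(instrument$wavelength_min, instrument$wavelength_max,
      length.out = instrument$n_spectral_pixels)
}

#' Source spectral envelope sampled on the spectrometer
#'
#' Gaussian source envelope with the instrument's centre wavelength and
#' FWHM, weighted by the camera quantum-efficiency profile, truncated to the
#' detected band and peak-normalized.
#'
#' @param instrument An `instrument_spec`.
#' @return List with `wavelength` (nm) and `power` (relative, peak 1).
#' @export
source_envelope <- function(instrument) {
  lambda <- instrument_wavelength(instrument)
  env <- exp(-4 * log(2) *
               (lambda - instrument$center_wavelength)^2 /
               instrument$source_fwhm^2)
  if (!is.null(instrument$qe_profile)) env <- env * instrument$qe_profile(lambda)
  list(wavelength = lambda, power = env / max(env))
}

#' Phantom layer description
#'
#' One horizontal layer of a layered phantom. Layers are stacked by
#' `top_depth` (micrometres from the reference plane); a layer extends until
#' the next layer's top or the bottom of the volume.
#'
#' @param top_depth Top of the layer in micrometres (>= 0).
#' @param attenuation Attenuation coefficient mu in mm^-1 (>= 0); see the
#'   convention note in [simulate_volume()].
#' @param backscatter Relative backscatter amplitude of the layer.
#' @param spectral_slope Power-law exponent of backscatter amplitude versus
#'   wavelength, `(lambda/555)^slope`; positive favours red.
#' @param absorption_peaks List of `list(center, width, strength)` Gaussian
#'   absorption bands (nm, nm, mm^-1) accumulating with depth in the layer.
#' @return A list of class `phantom_layer`.
#' @export
phantom_layer <- function(top_depth, attenuation, backscatter = 0.01,
                          spectral_slope = 0, absorption_peaks = list()) {
  assert_scalar_num(top_depth, "top_depth", min = 0)
  assert_scalar_num(attenuation, "attenuation", min = 0)
  assert_scalar_num(backscatter, "backscatter", min = 0)
  for (p in absorption_peaks) {
    if (!all(c("center", "width", "strength") %in% names(p))) {
      stopf("each absorption peak needs `center`, `width`, `strength`")
    }
  }
  structure(list(top_depth = top_depth, attenuation = attenuation,
                 backscatter = backscatter, spectral_slope = spectral_slope,
                 absorption_peaks = absorption_peaks),
            class = "phantom_layer")
}

#' Spherical inclusion description
#'
#' A hyperscattering spherical inclusion (e.g. an amyloid-plaque-like
#' object of a few tens of micrometres) embedded in the layer stack.
#'
#' @param center Numeric `(x, y, z)` centre in micrometres (lateral origin
#'   at the corner of the field, z from the reference plane).
#' @param radius Radius in micrometres (> 0).
#' @param backscatter_gain Multiplier on the local layer backscatter.
#' @param spectral_profile Wavelength response replacing the layer profile
#'   inside the inclusion: `NULL` (neutral), a function of wavelength (nm),
#'   or `"congo_red"` for a red-preferential sigmoid (near zero below
#'   ~540 nm, full response above ~580 nm) emulating Congo-red-stained
#'   amyloid.
#' @return A list of class `phantom_inclusion`.
#' @export
phantom_inclusion <- function(center, radius, backscatter_gain = 4,
                              spectral_profile = NULL) {
  if (length(center) != 3 || any(!is.finite(center))) {
    stopf("`center` must be (x, y, z) in micrometres")
  }
  assert_scalar_num(radius, "radius", min = 0, strict = TRUE)
  assert_scalar_num(backscatter_gain, "backscatter_gain", min = 0)
  prof <- spectral_profile
  if (is.character(prof)) {
    prof <- switch(prof,
      congo_red = function(l) 1 / (1 + exp(-(l - 560) / 8)),
      stopf("unknown spectral profile preset '%s'", spectral_profile)
    )
  }
  structure(list(center = as.numeric(center), radius = radius,
                 backscatter_gain = backscatter_gain,
                 spectral_profile = prof),
            class = "phantom_inclusion")
}

#' Layered phantom description
#'
#' Describes a laterally extended layered scene with optional spherical
#' inclusions, a rigid surface tilt and an optional second lateral region
#' with its own layer stack (for side-by-side tissue types such as white
#' versus grey matter).
#'
#' @param lateral_shape Integer `(nx, ny)` number of A-scans.
#' @param lateral_pitch Lateral sampling pitch in micrometres per A-scan.
#' @param layers List of [phantom_layer()] with strictly increasing
#'   `top_depth`. May be empty for an empty scene.
#' @param inclusions List of [phantom_inclusion()]; inclusions must not
#'   overlap each other.
#' @param surface_tilt Numeric `(dz/dx, dz/dy)`: rigid tilt of the specimen,
#'   applied as a per-column axial offset about the field centre.
#' @param refractive_index Group refractive index of the medium (>= 1).
#' @param lateral_regions Optional list of `list(x_range = c(lo, hi),
#'   layers = <list of phantom_layer>)` overriding the default stack over an
#'   inclusive range of x indices.
#' @param speckle If `TRUE`, each voxel hosts `scatterers_per_voxel` random
#'   sub-resolution scatterers whose coherent sum produces speckle.
#' @param scatterers_per_voxel Number of random scatterers per voxel in
#'   speckle mode (>= 2).
#' @param axial_jitter If `TRUE`, every A-line's axial origin is offset by a
#'   seeded uniform draw within one voxel (sub-micrometre surface
#'   roughness). This decorrelates the scatterer grid across A-lines, so
#'   laterally averaged depth profiles are smooth instead of showing the
#'   voxel-grid comb.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(lateral_shape = c(64, 64), lateral_pitch = 2,
                         layers = list(), inclusions = list(),
                         surface_tilt = c(0, 0), refractive_index = 1.36,
                         lateral_regions = list(), speckle = FALSE,
                         scatterers_per_voxel = 5, axial_jitter = FALSE) {
  if (length(lateral_shape) != 2 || any(lateral_shape < 1)) {
    stopf("`lateral_shape` must be (nx, ny) counts")
  }
  assert_scalar_num(lateral_pitch, "lateral_pitch", min = 0, strict = TRUE)
  if (refractive_index < 1) stopf("`refractive_index` must be >= 1")
  check_stack <- function(st, what) {
    tops <- vapply(st, function(l) l$top_depth, numeric(1))
    if (length(tops) > 1 && is.unsorted(tops, strictly = TRUE)) {
      stopf("%s `top_depth` values must be strictly increasing", what)
    }
  }
  check_stack(layers, "layer")
  for (r in lateral_regions) {
    if (!all(c("x_range", "layers") %in% names(r))) {
      stopf("each lateral region needs `x_range` and `layers`")
    }
    check_stack(r$layers, "lateral region layer")
  }
  if (speckle && scatterers_per_voxel < 2) {
    stopf("`scatterers_per_voxel` must be >= 2 in speckle mode")
  }
  structure(
    list(lateral_shape = as.integer(lateral_shape),
         lateral_pitch = lateral_pitch, layers = layers,
         inclusions = inclusions, surface_tilt = as.numeric(surface_tilt),
         refractive_index = refractive_index,
         lateral_regions = lateral_regions, speckle = isTRUE(speckle),
         scatterers_per_voxel = as.integer(scatterers_per_voxel),
         axial_jitter = isTRUE(axial_jitter)),
    class = "phantom_spec"
  )
}

# Resolve the layer stack governing column ix.
stack_for_x <- function(spec, ix) {
  for (r in spec$lateral_regions) {
    if (ix >= r$x_range[1] && ix <= r$x_range[2]) return(r$layers)
  }
  spec$layers
}

#' Voxelize a phantom into ground truth
#'
#' Rasterizes a [phantom_spec()] onto a regular voxel grid: per-voxel true
#' attenuation, the surface height map (including tilt), and a scatterer
#' table with depth-attenuated amplitudes and spectral-class assignments
#' ready for [simulate_volume()]. Voxel centres sit at
#' `(i - 1/2) * axial_step`; a voxel belongs to the deepest layer whose top
#' lies at or above its centre. Inclusion voxels multiply the local
#' backscatter by the inclusion gain and replace the spectral profile.
#'
#' @param spec A `phantom_spec`.
#' @param axial_extent Geometric depth extent of the grid in micrometres;
#'   must cover all layer tops and inclusions.
#' @param axial_step Axial voxel size in micrometres (> 0).
#' @return An object of class `ground_truth` with fields `mu`
#'   (nx x ny x nz array, mm^-1), `surface_um` and `surface_zindex`
#'   (nx x ny), `scatterers` (data frame `ix, iy, z, amplitude, class`),
#'   `classes` (spectral class descriptors), `z_centers`, `axial_step`, and
#'   the originating `spec`.
#' @export
build_phantom <- function(spec, axial_extent, axial_step) {
  if (!inherits(spec, "phantom_spec")) stopf("`spec` must be a phantom_spec")
  assert_scalar_num(axial_step, "axial_step", min = 0, strict = TRUE)
  assert_scalar_num(axial_extent, "axial_extent", min = 0, strict = TRUE)
  all_stacks <- c(list(spec$layers), lapply(spec$lateral_regions, `[[`, "layers"))
  for (st in all_stacks) {
    for (l in st) {
      if (l$top_depth >= axial_extent) {
        stopf("layer top_depth %.3g um lies below axial_extent %.3g um",
              l$top_depth, axial_extent)
      }
    }
  }
  for (inc in spec$inclusions) {
    if (inc$center[3] + inc$radius > axial_extent) {
      stopf("inclusion at z = %.3g um extends below axial_extent", inc$center[3])
    }
  }
  # reject overlapping inclusions
  n_inc <- length(spec$inclusions)
  if (n_inc > 1) {
    for (a in seq_len(n_inc - 1)) {
      for (b in seq(a + 1, n_inc)) {
        ia <- spec$inclusions[[a]]
        ib <- spec$inclusions[[b]]
        if (sqrt(sum((ia$center - ib$center)^2)) < ia$radius + ib$radius) {
          stopf("inclusions %d and %d overlap", a, b)
        }
      }
    }
  }

  nx <- spec$lateral_shape[1]
  ny <- spec$lateral_shape[2]
  nz <- ceiling(axial_extent / axial_step)
  z_centers <- (seq_len(nz) - 0.5) * axial_step

  # spectral classes: one per (stack, layer), plus one per inclusion
  classes <- list()
  class_key <- character(0)
  class_of <- function(key, descriptor) {
    hit <- match(key, class_key)
    if (!is.na(hit)) return(hit)
    classes[[length(classes) + 1L]] <<- descriptor
    class_key[length(class_key) + 1L] <<- key
    length(classes)
  }

  stacks <- list(spec$layers)
  stack_id <- rep(1L, nx)
  for (r in spec$lateral_regions) {
    stacks[[length(stacks) + 1L]] <- r$layers
    sel <- seq_len(nx) >= r$x_range[1] & seq_len(nx) <= r$x_range[2]
    stack_id[sel] <- length(stacks)
  }

  # per-stack per-z layer index, mu, cumulative attenuation path (mm),
  # amplitude and class id
  per_stack <- lapply(seq_along(stacks), function(si) {
    st <- stacks[[si]]
    if (length(st) == 0) {
      return(list(mu = rep(0, nz), amp = rep(0, nz),
                  class = rep(NA_integer_, nz), surface = NA_real_))
    }
    tops <- vapply(st, `[[`, numeric(1), "top_depth")
    layer_idx <- findInterval(z_centers, tops)     # 0 = above first layer
    mu_z <- rep(0, nz)
    amp <- rep(0, nz)
    cls <- rep(NA_integer_, nz)
    inside <- layer_idx > 0
    mu_z[inside] <- vapply(layer_idx[inside], function(i) st[[i]]$attenuation,
                           numeric(1))
    # cumulative one-way attenuation path from the surface, in mm^-1 * mm
    path <- cumsum(mu_z * (axial_step / 1000))
    for (i in seq_along(st)) {
      sel <- layer_idx == i
      if (!any(sel)) next
      above <- st[seq_len(i - 1)]
      thick <- if (i > 1) {
        tops_all <- c(tops, Inf)
        vapply(seq_len(i - 1), function(j) tops_all[j + 1] - tops_all[j],
               numeric(1))
      } else numeric(0)
      cid <- class_of(
        sprintf("stack%d_layer%d", si, i),
        list(kind = "layer", slope = st[[i]]$spectral_slope,
             absorption_peaks = st[[i]]$absorption_peaks,
             top_depth = tops[i],
             above = if (i > 1) {
               lapply(seq_len(i - 1), function(j) {
                 list(absorption_peaks = above[[j]]$absorption_peaks,
                      thickness = thick[j])
               })
             } else list())
      )
      amp[sel] <- st[[i]]$backscatter * exp(-path[sel])
      cls[sel] <- cid
    }
    list(mu = mu_z, amp = amp, class = cls, surface = tops[1])
  })

  mu <- array(0, dim = c(nx, ny, nz))
  surface_um <- matrix(NA_real_, nx, ny)
  for (ix in seq_len(nx)) {
    si <- stack_id[ix]
    mu[ix, , ] <- matrix(per_stack[[si]]$mu, ny, nz, byrow = TRUE)
    surface_um[ix, ] <- per_stack[[si]]$surface
  }
  # rigid tilt about the field centre
  x_um <- (seq_len(nx) - (nx + 1) / 2) * spec$lateral_pitch
  y_um <- (seq_len(ny) - (ny + 1) / 2) * spec$lateral_pitch
  tilt <- outer(x_um * spec$surface_tilt[1], rep(1, ny)) +
    outer(rep(1, nx), y_um * spec$surface_tilt[2])
  surface_um <- surface_um + tilt

  # scatterer table: one row per (column, occupied voxel)
  sc_ix <- integer(0); sc_iy <- integer(0); sc_z <- numeric(0)
  sc_amp <- numeric(0); sc_cls <- integer(0)
  for (si in seq_along(stacks)) {
    cols <- which(stack_id == si)
    occ <- which(per_stack[[si]]$amp > 0)
    if (!length(cols) || !length(occ)) next
    grid <- expand.grid(iz = occ, ix = cols, iy = seq_len(ny))
    sc_ix <- c(sc_ix, grid$ix)
    sc_iy <- c(sc_iy, grid$iy)
    sc_z <- c(sc_z, z_centers[grid$iz])
    sc_amp <- c(sc_amp, per_stack[[si]]$amp[grid$iz])
    sc_cls <- c(sc_cls, per_stack[[si]]$class[grid$iz])
  }
  scatterers <- data.frame(ix = sc_ix, iy = sc_iy, z = sc_z,
                           amplitude = sc_amp, class = sc_cls)

  # inclusions: reassign amplitude/class of contained voxels
  if (length(spec$inclusions)) {
    x_pos <- (seq_len(nx) - 0.5) * spec$lateral_pitch
    y_pos <- (seq_len(ny) - 0.5) * spec$lateral_pitch
    for (ii in seq_along(spec$inclusions)) {
      inc <- spec$inclusions[[ii]]
      cid <- class_of(sprintf("inclusion%d", ii),
                      list(kind = "inclusion", profile = inc$spectral_profile))
      inside <- (x_pos[scatterers$ix] - inc$center[1])^2 +
        (y_pos[scatterers$iy] - inc$center[2])^2 +
        (scatterers$z - inc$center[3])^2 <= inc$radius^2
      scatterers$amplitude[inside] <- scatterers$amplitude[inside] *
        inc$backscatter_gain
      scatterers$class[inside] <- cid
    }
  }

  surface_zindex <- matrix(
    pmin(pmax(ceiling(surface_um / axial_step + 1e-9), 1L), nz),
    nx, ny
  )
  surface_zindex[is.na(surface_um)] <- NA_integer_

  structure(
    list(mu = mu, surface_um = surface_um, surface_zindex = surface_zindex,
         scatterers = scatterers, classes = classes, z_centers = z_centers,
         axial_step = axial_step, axial_extent = axial_extent,
         tilt_um = tilt, spec = spec),
    class = "ground_truth"
  )
}

# Gaussian absorption coefficient alpha(lambda) in mm^-1 for a peak list.
absorption_alpha <- function(peaks, lambda) {
  a <- rep(0, length(lambda))
  for (p in peaks) {
    a <- a + p$strength * exp(-4 * log(2) * (lambda - p$center)^2 / p$width^2)
  }
  a
}

#' Simulate a raw spectral volume
#'
#' Runs the forward model: for every A-line the detected spectrum is
#' \deqn{I(\lambda) = E(\lambda)\,|r + \textstyle\sum_j a_j(\lambda)
#'   e^{i(2 k n z_j + \phi_d(k))}|^2,}
#' with scatterer amplitudes attenuated by the Beer-Lambert path integral
#' and the spectrometer roll-off, the dispersion phase \eqn{\phi_d} applied
#' to the sample field, noise added per the instrument noise model, and the
#' result quantized to the camera bit depth. The same
#' `(truth, instrument, dispersion, seed)` always yields a bit-identical
#' volume.
#'
#' @param truth A `ground_truth` from [build_phantom()].
#' @param instrument An `instrument_spec`.
#' @param dispersion Optional [dispersion_model()] describing the
#'   interferometer arm mismatch injected into the sample field.
#' @param seed Integer seed controlling all randomness (noise, speckle).
#' @param noise If `FALSE`, the noise model and quantization dithering are
#'   skipped (spectra are still quantized unless `quantize = FALSE`).
#' @param quantize If `FALSE`, return unquantized counts (floating point).
#' @return An object of class `spectral_volume`: integer `counts` array of
#'   dim `(n_pixels, nx, ny)`, `wavelength` calibration vector, `dims`, and
#'   `meta` (instrument, seed, gain, refractive index).
#' @export
simulate_volume <- function(truth, instrument, dispersion = NULL, seed = 1,
                            noise = TRUE, quantize = TRUE) {
  if (!inherits(truth, "ground_truth")) stopf("`truth` must be a ground_truth")
  if (!inherits(instrument, "instrument_spec")) {
    stopf("`instrument` must be an instrument_spec")
  }
  if (instrument$bit_depth < 8 || instrument$bit_depth > 16) {
    stopf("`bit_depth` must be within [8, 16]")
  }
  spec <- truth$spec
  nx <- spec$lateral_shape[1]
  ny <- spec$lateral_shape[2]
  nlat <- nx * ny
  env <- source_envelope(instrument)
  lambda <- env$wavelength
  P <- length(lambda)
  k <- 2 * pi / lambda                     # rad/nm, descending
  n_med <- spec$refractive_index
  r <- instrument$reference_level

  with_seed(seed, {
    field <- matrix(0 + 0i, P, nlat)
    sc <- truth$scatterers
    if (nrow(sc)) {
      col <- (sc$iy - 1L) * nx + sc$ix
      # roll-off amplitude factor vs optical depth (intensity dB/mm)
      roll <- 10^(-instrument$rolloff_db_mm * n_med * (sc$z / 1000) / 20)
      base_amp <- sc$amplitude * roll
      speckle_phasor <- if (spec$speckle) {
        K <- spec$scatterers_per_voxel
        ph <- matrix(stats::runif(nrow(sc) * K, 0, 2 * pi), nrow(sc), K)
        rowSums(exp(1i * ph)) / sqrt(K)
      } else rep(1 + 0i, nrow(sc))
      for (ci in seq_along(truth$classes)) {
        rows <- which(sc$class == ci)
        if (!length(rows)) next
        cl <- truth$classes[[ci]]
        zs <- sort(unique(sc$z[rows]))
        zi <- match(sc$z[rows], zs)
        # common-grid fringe matrix, phase 2 k n z (z in nm)
        M <- exp(1i * outer(2 * k * n_med, zs * 1000))
        g <- rep(1, P)
        if (identical(cl$kind, "layer")) {
          if (!identical(cl$slope, 0)) {
            g <- (lambda / instrument$center_wavelength)^cl$slope
          }
          offset <- rep(0, P)
          for (ab in cl$above) {
            offset <- offset +
              absorption_alpha(ab$absorption_peaks, lambda) *
              (ab$thickness / 1000)
          }
          g <- g * exp(-offset)
          if (length(cl$absorption_peaks)) {
            alpha <- absorption_alpha(cl$absorption_peaks, lambda)
            M <- M * exp(-outer(alpha, pmax(zs - cl$top_depth, 0) / 1000))
          }
        } else if (!is.null(cl$profile)) {
          g <- cl$profile(lambda)
        }
        # accumulate amplitudes onto the (z, column) grid
        A <- matrix(0 + 0i, length(zs), nlat)
        amp <- base_amp[rows] * speckle_phasor[rows]
        for (s in seq_along(rows)) {
          A[zi[s], col[rows[s]]] <- A[zi[s], col[rows[s]]] + amp[s]
        }
        field <- field + g * (M %*% A)
      }
      # rigid tilt (plus optional sub-voxel roughness): per-column axial
      # shift of the whole return
      shift <- as.vector(truth$tilt_um)
      if (isTRUE(spec$axial_jitter)) {
        shift <- shift + stats::runif(nlat, -0.5, 0.5) * truth$axial_step
      }
      if (any(shift != 0)) {
        roll_s <- 10^(-instrument$rolloff_db_mm * n_med * (shift / 1000) / 20)
        phase_s <- exp(1i * outer(2 * k * n_med, shift * 1000))
        field <- field * sweep(phase_s, 2, roll_s, `*`)
      }
    }
    if (!is.null(dispersion)) {
      phi <- dispersion_phase(dispersion, k)
      field <- field * exp(1i * phi)
    }
    intensity <- env$power * (Mod(r + field))^2
    full <- 2^instrument$bit_depth - 1
    gain <- instrument$full_scale_fraction * full /
      max(env$power * r^2, .Machine$double.eps)
    counts <- gain * intensity
    if (noise) {
      nm <- instrument$noise_model
      if (nm$excess_intensity_noise_sd > 0) {
        counts <- counts *
          (1 + stats::rnorm(length(counts), 0, nm$excess_intensity_noise_sd))
      }
      if (nm$shot_scale > 0) {
        counts <- counts +
          stats::rnorm(length(counts), 0, sqrt(nm$shot_scale * pmax(counts, 0)))
      }
      if (nm$read_noise_sd > 0) {
        counts <- counts + stats::rnorm(length(counts), 0, nm$read_noise_sd)
      }
    }
    if (quantize) counts <- clamp(round(counts), 0, full)
    spectral_volume(
      counts = array(counts, dim = c(P, nx, ny)),
      wavelength = lambda,
      meta = list(seed = seed, gain = gain,
                  reference = gain * env$power * r^2,
                  refractive_index = n_med,
                  bit_depth = instrument$bit_depth,
                  rolloff_db_mm = instrument$rolloff_db_mm,
                  axial_step = truth$axial_step)
    )
  })
}

#' Construct a spectral volume container
#'
#' Container for raw spectrometer data: one spectrum per A-line plus the
#' pixel-to-wavelength calibration.
#'
#' @param counts Numeric array of dim `(n_pixels, nx, ny)`.
#' @param wavelength Strictly monotone wavelength calibration (nm), length
#'   `n_pixels`.
#' @param meta Optional metadata list.
#' @return An object of class `spectral_volume`.
#' @export
spectral_volume <- function(counts, wavelength, meta = list()) {
  if (length(dim(counts)) == 2L) {
    counts <- array(counts, dim = c(dim(counts), 1L))
  }
  if (length(dim(counts)) != 3L) {
    stopf("`counts` must be a (n_pixels, nx, ny) array")
  }
  if (length(wavelength) != dim(counts)[1]) {
    stopf("`wavelength` length %d does not match n_pixels %d",
          length(wavelength), dim(counts)[1])
  }
  if (is.unsorted(wavelength, strictly = TRUE) &&
      is.unsorted(rev(wavelength), strictly = TRUE)) {
    stopf("`wavelength` calibration must be strictly monotone")
  }
  structure(
    list(counts = counts, wavelength = as.numeric(wavelength),
         dims = dim(counts), meta = meta),
    class = "spectral_volume"
  )
}

#' @export
print.spectral_volume <- function(x, ...) {
  cat(sprintf(
    "Spectral volume: %d x %d A-scans, %d spectral pixels, %.0f-%.0f nm\n",
    x$dims[2], x$dims[3], x$dims[1], min(x$wavelength), max(x$wavelength)
  ))
  invisible(x)
}
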