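# Spectral-domain reconstruction.
#
# Raw spectrometer data are sampled (nearly) uniformly in wavelength. Depth
# reconstruction requires spectra uniform in wavenumber k = 2*pi/lambda, so
# each A-line is resampled onto a uniform k grid (cubic spline), the
# reference/background spectrum is removed, a polynomial dispersion phase is
# applied, and the FFT yields the complex depth profile. The axial pixel
# pitch follows from the spanned k range: for a fringe exp(i 2 k z), depth
# bin m corresponds to z = pi * m / (P * dk).

#' Polynomial dispersion model
#'
#' Describes the unbalanced dispersion phase between interferometer arms as
#' a polynomial in normalized detuning
#' \eqn{\phi(k) = \sum_{j \ge 2} a_j u^j}, with
#' \eqn{u = (k - k_0)/k_{half}} scaled so that `u = 1` at the band edge:
#' coefficients are read directly as radians of phase at the edge of the
#' detected band. Orders up to 5 are supported; the constant and linear
#' terms only shift the image in depth and are excluded.
#'
#' @param coefficients Named or ordered numeric vector `(a2, a3, ...)`, all
#'   finite, at most 4 entries (orders 2-5).
#' @param k0 Reference wavenumber in rad/nm; `NULL` (default) uses the
#'   centre of the k grid at application time.
#' @param k_half Half-width of the k band in rad/nm; `NULL` derives it from
#'   the grid at application time.
#' @return An object of class `dispersion_model`.
#' @export
dispersion_model <- function(coefficients = c(a2 = 0), k0 = NULL,
                             k_half = NULL) {
  coefficients <- as.numeric(coefficients)
  if (length(coefficients) < 1 || length(coefficients) > 4 ||
      any(!is.finite(coefficients))) {
    stopf("`coefficients` must be 1 to 4 finite values (orders 2 to 5)")
  }
  structure(
    list(coefficients = coefficients, k0 = k0, k_half = k_half),
    class = "dispersion_model"
  )
}

#' @export
print.dispersion_model <- function(x, ...) {
  cat("Dispersion model, phase at band edge (rad):\n")
  print(stats::setNames(x$coefficients,
                        paste0("a", seq_along(x$coefficients) + 1L)))
  invisible(x)
}

# Evaluate the dispersion phase on a wavenumber grid (rad).
dispersion_phase <- function(model, k) {
  k0 <- model$k0 %||% mean(range(k))
  kh <- model$k_half %||% (diff(range(k)) / 2)
  u <- (k - k0) / kh
  phi <- 0
  for (j in seq_along(model$coefficients)) {
    phi <- phi + model$coefficients[j] * u^(j + 1L)
  }
  phi
}

#' Negate a dispersion model
#'
#' The model with all coefficients negated: applying a model and then its
#' negation is the identity.
#'
#' @param model A `dispersion_model`.
#' @return A `dispersion_model`.
#' @export
negate_dispersion <- function(model) {
  dispersion_model(-model$coefficients, model$k0, model$k_half)
}

#' Apply a dispersion phase to a uniform-k spectrum
#'
#' Multiplies the (complex) spectrum by the unit-modulus factor
#' \eqn{e^{i\phi(k)}}; the magnitude spectrum is unchanged.
#'
#' @param values Spectrum sampled on `k` (numeric or complex).
#' @param k Uniform wavenumber grid, rad/nm.
#' @param model A `dispersion_model`.
#' @return Complex spectrum of the same length.
#' @export
apply_dispersion <- function(values, k, model) {
  if (length(values) != length(k)) stopf("`values` and `k` lengths differ")
  values * exp(1i * dispersion_phase(model, k))
}

#' Resample a spectrum to a uniform wavenumber grid
#'
#' Interpolates a spectrum sampled on a monotone wavelength calibration onto
#' a uniform grid in k = 2*pi/lambda spanning the same range, using a cubic
#' spline. At existing nodes the interpolation is exact, so input already
#' uniform in k is returned unchanged.
#'
#' @param values Spectral samples.
#' @param wavelength Strictly monotone wavelength calibration in nm.
#' @param n_out Number of output samples (default: same as input).
#' @return List with `k` (ascending uniform grid, rad/nm) and `values`.
#' @export
resample_to_k <- function(values, wavelength, n_out = length(values)) {
  if (length(values) < 16) stopf("need at least 16 spectral samples")
  if (length(values) != length(wavelength)) {
    stopf("`values` and `wavelength` lengths differ")
  }
  up <- !is.unsorted(wavelength, strictly = TRUE)
  down <- !is.unsorted(rev(wavelength), strictly = TRUE)
  if (!up && !down) stopf("wavelength calibration must be strictly monotone")
  k_in <- 2 * pi / wavelength
  ord <- order(k_in)
  kg <- seq(min(k_in), max(k_in), length.out = n_out)
  out <- stats::spline(k_in[ord], values[ord], xout = kg, method = "fmm")$y
  list(k = kg, values = out)
}

#' Remove the background (reference) spectrum from a volume
#'
#' Subtracts a reference spectrum from every A-line. With
#' `background = "estimate"` the mean spectrum over all A-lines of the
#' volume is used, which cancels the reference-arm pedestal when fringe
#' phases decorrelate across the field; a measured reference spectrum can be
#' supplied instead.
#'
#' @param volume A `spectral_volume`.
#' @param background `"estimate"`, `"auto"` (use the reference spectrum
#'   recorded in the volume metadata when present, otherwise estimate), or
#'   a numeric vector of length `n_pixels`.
#' @return A `spectral_volume` with background-corrected (floating point)
#'   counts.
#' @export
remove_background <- function(volume, background = "auto") {
  if (!inherits(volume, "spectral_volume")) {
    stopf("`volume` must be a spectral_volume")
  }
  P <- volume$dims[1]
  flat <- matrix(volume$counts, nrow = P)
  if (identical(background, "auto")) {
    background <- if (!is.null(volume$meta$reference)) {
      as.numeric(volume$meta$reference)
    } else "estimate"
  }
  if (identical(background, "estimate")) {
    bg <- rowMeans(flat)
  } else {
    if (!is.numeric(background) || length(background) != P) {
      stopf("`background` must be 'estimate' or a numeric vector of length %d", P)
    }
    bg <- background
  }
  corrected <- flat - bg
  meta <- volume$meta
  meta$background_removed <- TRUE
  spectral_volume(array(corrected, dim = volume$dims), volume$wavelength, meta)
}

# Resample all A-lines of a (background-removed) volume onto the common
# uniform k grid. Returns list(k, spectra) with spectra P x nlat.
resample_volume <- function(volume) {
  P <- volume$dims[1]
  nlat <- prod(volume$dims[-1])
  flat <- matrix(volume$counts, nrow = P)
  k_in <- 2 * pi / volume$wavelength
  ord <- order(k_in)
  kx <- k_in[ord]
  kg <- seq(kx[1], kx[P], length.out = P)
  out <- matrix(0, P, nlat)
  for (j in seq_len(nlat)) {
    out[, j] <- stats::spline(kx, flat[ord, j], xout = kg, method = "fmm")$y
  }
  list(k = kg, spectra = out)
}

#' Reconstruct a tomogram from a spectral volume
#'
#' Full A-line processing chain: background removal, k-space resampling,
#' optional spectral apodization, dispersion correction, FFT (normalized by
#' `1/sqrt(P)` so energy is preserved), and retention of the positive-depth
#' half of the transform. The depth axis is optical depth.
#'
#' @param volume A `spectral_volume`.
#' @param dispersion Optional `dispersion_model` used as the correction
#'   phase (use [estimate_dispersion()] to obtain one).
#' @param background Passed to [remove_background()]; `NULL` skips background
#'   removal (for already-corrected data).
#' @param window Optional spectral apodization: a function of wavelength
#'   (nm) evaluated on the resampled grid. Default none; the source envelope
#'   already shapes the spectrum.
#' @param keep `"positive"` (default) keeps depth bins `0 .. P/2-1`;
#'   `"full"` keeps the entire transform (useful for energy checks).
#' @return An object of class `tomogram`: complex `field` array
#'   `(nz, nx, ny)`, `axial_pitch` in mm of optical depth per pixel,
#'   `depth_um`, and `meta` carried over from the volume.
#' @export
reconstruct <- function(volume, dispersion = NULL, background = "auto",
                        window = NULL, keep = c("positive", "full")) {
  keep <- match.arg(keep)
  if (!inherits(volume, "spectral_volume")) {
    stopf("`volume` must be a spectral_volume")
  }
  if (!is.null(background) && !isTRUE(volume$meta$background_removed)) {
    volume <- remove_background(volume, background)
  }
  rs <- resample_volume(volume)
  P <- length(rs$k)
  spec <- rs$spectra
  if (!is.null(window)) {
    w <- window(2 * pi / rs$k)
    spec <- spec * w
  }
  if (!is.null(dispersion)) {
    phase <- exp(1i * dispersion_phase(dispersion, rs$k))
    spec <- spec * phase
  }
  field <- stats::mvfft(spec) / sqrt(P)
  dk <- (rs$k[P] - rs$k[1]) / (P - 1)
  delta_nm <- pi / (P * dk)
  nz <- if (keep == "positive") P %/% 2L else P
  field <- field[seq_len(nz), , drop = FALSE]
  dims_lat <- volume$dims[-1]
  tomogram(
    field = array(field, dim = c(nz, dims_lat)),
    axial_pitch = delta_nm * 1e-6,
    meta = c(volume$meta, list(n_spectral = P, dk = dk, keep = keep))
  )
}

#' Tomogram container
#'
#' Depth-resolved complex reconstruction with its axial sampling.
#'
#' @param field Complex array `(nz, nx, ny)`.
#' @param axial_pitch Optical depth per pixel in mm.
#' @param meta Metadata list.
#' @return An object of class `tomogram`.
#' @export
tomogram <- function(field, axial_pitch, meta = list()) {
  if (length(dim(field)) == 2L) field <- array(field, dim = c(dim(field), 1L))
  assert_scalar_num(axial_pitch, "axial_pitch", min = 0, strict = TRUE)
  structure(
    list(field = field, axial_pitch = axial_pitch,
         n_depth = dim(field)[1],
         depth_um = (seq_len(dim(field)[1]) - 1) * axial_pitch * 1000,
         meta = meta),
    class = "tomogram"
  )
}

#' @export
print.tomogram <- function(x, ...) {
  d <- dim(x$field)
  cat(sprintf(
    "Tomogram: %d depth x %d x %d A-scans, pitch %.3g um (optical depth)\n",
    d[1], d[2], d[3], x$axial_pitch * 1000
  ))
  invisible(x)
}

#' Intensity of a tomogram
#'
#' @param tom A `tomogram`.
#' @return Numeric array `|field|^2` of the same dimensions.
#' @export
tomogram_intensity <- function(tom) {
  if (!inherits(tom, "tomogram")) stopf("`tom` must be a tomogram")
  Mod(tom$field)^2
}

#' Compensate the spectrometer sensitivity roll-off
#'
#' Multiplies the depth profile amplitude by the inverse of the exponential
#' roll-off model, `10^(rate * z / 20)` with z the optical depth in mm, so
#' that intensities at depth regain `rate` dB per mm.
#'
#' @param tom A `tomogram`.
#' @param rate_db_mm Roll-off rate in dB of intensity per mm; defaults to
#'   the rate recorded in the tomogram metadata.
#' @return A `tomogram` with compensated field.
#' @export
compensate_rolloff <- function(tom, rate_db_mm = NULL) {
  if (!inherits(tom, "tomogram")) stopf("`tom` must be a tomogram")
  rate <- rate_db_mm %||% tom$meta$rolloff_db_mm
  if (is.null(rate)) stopf("no roll-off rate supplied or recorded in metadata")
  gain <- 10^(rate * (tom$depth_um / 1000) / 20)
  tom$field <- tom$field * gain
  tom$meta$rolloff_compensated <- TRUE
  tom
}

#' Estimate dispersion coefficients from a reconstructed volume
#'
#' Searches for the polynomial dispersion correction that minimizes the
#' Shannon entropy of the normalized reconstructed intensity (a sharpness
#' objective: a focused image concentrates energy in few pixels). The search
#' is deterministic: a fixed coarse grid over the quadratic coefficient
#' seeds a Nelder-Mead refinement over all coefficients with fixed
#' tolerances.
#'
#' @param volume A `spectral_volume` containing structure (point-like or
#'   speckled reflectors).
#' @param order Polynomial order, 2 to 5 (number of coefficients =
#'   `order - 1`).
#' @param lines Indices of A-lines used for the objective (default: up to 32
#'   lines evenly spaced through the volume).
#' @param coarse Coarse grid of a2 values (rad at band edge) used to seed
#'   the simplex.
#' @param maxit Maximum Nelder-Mead iterations.
#' @return A `dispersion_model` suitable as the `dispersion` argument of
#'   [reconstruct()]; recovered coefficients approximately negate an
#'   injected mismatch. Attribute `converged` reports optimizer status, with
#'   a warning when the optimizer stopped early.
#' @export
estimate_dispersion <- function(volume, order = 3, lines = NULL,
                                coarse = seq(-60, 60, by = 6), maxit = 400) {
  if (!(order %in% 2:5)) stopf("`order` must be in 2..5")
  if (!isTRUE(volume$meta$background_removed)) {
    volume <- remove_background(volume, "auto")
  }
  nlat <- prod(volume$dims[-1])
  if (is.null(lines)) {
    lines <- unique(round(seq(1, nlat, length.out = min(32, nlat))))
  }
  sub <- matrix(matrix(volume$counts, nrow = volume$dims[1])[, lines],
                nrow = volume$dims[1])
  subvol <- spectral_volume(array(sub, dim = c(volume$dims[1], length(lines), 1L)),
                            volume$wavelength,
                            c(volume$meta, list(background_removed = TRUE)))
  rs <- resample_volume(subvol)
  P <- length(rs$k)
  half <- seq_len(P %/% 2L)
  objective <- function(a) {
    phase <- exp(1i * dispersion_phase(dispersion_model(a), rs$k))
    I <- Mod(stats::mvfft(rs$spectra * phase)[half, , drop = FALSE])^2
    p <- I / sum(I)
    -sum(p[p > 0] * log(p[p > 0]))
  }
  n_coef <- order - 1L
  grid_scores <- vapply(coarse, function(a2) objective(c(a2, rep(0, n_coef - 1L))),
                        numeric(1))
  start <- c(coarse[which.min(grid_scores)], rep(0, n_coef - 1L))
  fit <- stats::optim(start, objective, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-9))
  if (fit$convergence != 0) {
    warnf("dispersion optimizer stopped early (code %d); returning last iterate",
          fit$convergence)
  }
  out <- dispersion_model(fit$par)
  attr(out, "converged") <- fit$convergence == 0
  attr(out, "entropy") <- fit$value
  out
}

#' Detect the tissue surface in a tomogram
#'
#' The intensity of each A-line is first smoothed along depth with a
#' forward-looking running mean of `smooth_z` pixels (suppressing individual
#' speckle grains without delaying a sharp onset). The surface is then the
#' first depth (excluding the first two zero-delay bins) where the smoothed
#' intensity reaches `noise_mean + threshold_sd * noise_sd` for two
#' consecutive pixels, with the noise statistics estimated from the deepest
#' 10% of the smoothed samples. The index map is median-smoothed over a
#' square lateral window. A-lines that never cross the threshold, or whose
#' peak lies less than `min_snr_db` above the noise floor, are flagged
#' invalid — a volume of pure noise yields an all-invalid map.
#'
#' @param tom A `tomogram`.
#' @param threshold_sd Threshold in noise standard deviations (default 4).
#' @param smoothing_px Lateral median smoothing window in pixels (odd;
#'   default 5).
#' @param min_peak_fraction Lower bound on the threshold as a fraction of
#'   the volume's maximum smoothed intensity (default 0.02), which keeps the
#'   detector off weak zero-delay residuals when the noise floor is very
#'   low.
#' @param smooth_z Axial running-mean width in pixels (default 5).
#' @param min_snr_db Minimum column peak over the mean noise floor, in dB
#'   (default 10), below which a column is considered signal-free.
#' @return An object of class `surface_map`: integer `surface_index`
#'   (nx x ny, NA where invalid) and logical `valid_mask`.
#' @export
detect_surface <- function(tom, threshold_sd = 4, smoothing_px = 5,
                           min_peak_fraction = 0.02, smooth_z = 5,
                           min_snr_db = 10) {
  I <- tomogram_intensity(tom)
  dm <- dim(I)
  nz <- dm[1]
  flat <- matrix(I, nrow = nz)
  # forward-looking running mean: sm[i] = mean(I[i .. i+smooth_z-1])
  if (smooth_z > 1) {
    cs <- rbind(0, apply(flat, 2, cumsum))
    hi <- pmin(seq_len(nz) + smooth_z - 1L, nz)
    sm <- (cs[hi + 1L, , drop = FALSE] - cs[seq_len(nz), , drop = FALSE]) /
      (hi - seq_len(nz) + 1L)
  } else {
    sm <- flat
  }
  deep <- sm[seq.int(floor(nz * 0.9) + 1L, nz), , drop = FALSE]
  noise_mean <- mean(deep)
  noise_sd <- stats::sd(as.vector(deep))
  thr <- max(noise_mean + threshold_sd * noise_sd,
             min_peak_fraction * max(sm))
  first_bin <- 3L
  nlat <- ncol(flat)
  sidx <- rep(NA_integer_, nlat)
  # the SNR gate only makes sense when the deep region is genuine noise;
  # zero spread there means it holds signal (or nothing), so skip the gate
  snr_ok <- if (noise_mean <= 0 || noise_sd <= 0) {
    rep(TRUE, nlat)
  } else {
    colSums(sm >= noise_mean * 10^(min_snr_db / 10)) > 0
  }
  for (j in seq_len(nlat)) {
    if (!snr_ok[j]) next
    a <- sm[, j] >= thr
    a[seq_len(first_bin - 1L)] <- FALSE
    hits <- which(a[-nz] & a[-1])
    if (length(hits)) sidx[j] <- hits[1]
  }
  m <- matrix(as.numeric(sidx), dm[2], dm[3])
  m <- round(median_filter2(m, smoothing_px))
  valid <- !is.na(m)
  m[valid] <- clamp(m[valid], 1L, nz)
  structure(
    list(surface_index = m, valid_mask = valid,
         threshold = thr, noise_mean = noise_mean, noise_sd = noise_sd),
    class = "surface_map"
  )
}

#' Surface-referenced en-face projection
#'
#' For each A-line, summarizes the intensity over the depth slab
#' `[depth_start, depth_end)` micrometres below the detected surface.
#' Slab pixel indices follow the half-open convention: the start offset is
#' rounded down and the end offset rounded up to whole pixels. Slabs
#' reaching past the bottom of the volume are truncated (flagged via the
#' `"truncated"` attribute); invalid A-lines yield `NA`.
#'
#' @param x A `tomogram` or numeric intensity array (depth first).
#' @param surface A `surface_map`.
#' @param depth_start,depth_end Slab bounds in micrometres below the
#'   surface, `depth_end > depth_start`.
#' @param statistic Summary function applied per A-line (default `mean`).
#' @param delta_um Axial pitch in micrometres (required for plain arrays).
#' @return Matrix (nx x ny) of slab statistics.
#' @export
enface_projection <- function(x, surface, depth_start, depth_end,
                              statistic = mean, delta_um = NULL) {
  if (depth_end <= depth_start) stopf("`depth_end` must exceed `depth_start`")
  if (inherits(x, "tomogram")) {
    I <- tomogram_intensity(x)
    delta_um <- delta_um %||% (x$axial_pitch * 1000)
  } else {
    I <- x
    if (is.null(delta_um)) stopf("`delta_um` is required for a plain array")
  }
  dm <- dim(I)
  nz <- dm[1]
  flat <- matrix(I, nrow = nz)
  px0 <- floor(depth_start / delta_um)
  px1 <- ceiling(depth_end / delta_um)
  sidx <- as.vector(surface$surface_index)
  svalid <- as.vector(surface$valid_mask)
  out <- rep(NA_real_, ncol(flat))
  truncated <- FALSE
  for (j in seq_len(ncol(flat))) {
    if (!isTRUE(svalid[j])) next
    i0 <- sidx[j] + px0
    i1 <- sidx[j] + px1 - 1L
    if (i1 > nz) {
      i1 <- nz
      truncated <- TRUE
    }
    if (i1 < i0 || i0 < 1) next
    out[j] <- statistic(flat[seq.int(i0, i1), j])
  }
  res <- matrix(out, dm[2], if (length(dm) >= 3) dm[3] else 1L)
  attr(res, "truncated") <- truncated
  res
}
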