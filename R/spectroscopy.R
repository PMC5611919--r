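# Sub-band (spectroscopic) reconstruction.
#
# Multiplying the detected spectrum by a Gaussian window centred at a chosen
# wavelength before the Fourier transform yields a tomogram that only sees
# light of that band. With a constant-resolution window set (design_windows)
# every sub-band image shares one axial resolution, so sub-band intensities
# are directly comparable voxel by voxel.

#' Apply a Gaussian window set to a spectral volume
#'
#' Reconstructs one tomogram per window of a [design_windows()] set. Each
#' window is a Gaussian in wavelength evaluated on the resampled k grid
#' through the calibration map. With `equalize_energy` every windowed
#' spectrum is rescaled so the area under its windowed source profile equals
#' that of the first window (equal total spectral energy across bands), and
#' with `compensate_rolloff` each sub-band tomogram is multiplied by the
#' inverse roll-off gain versus depth.
#'
#' @param volume A `spectral_volume`.
#' @param windows A `gaussian_windows` set. Windows whose centre lies
#'   outside the detected wavelength band are dropped with a warning (an
#'   error if none remain).
#' @param dispersion Optional `dispersion_model` correction.
#' @param equalize_energy Equalize total spectral energy across windows
#'   (default `TRUE`).
#' @param compensate_rolloff `NULL` (none), a single dB/mm rate, or one rate
#'   per window for wavelength-dependent roll-off.
#' @param background Passed to [remove_background()].
#' @return An object of class `subband_volume`: list of `tomograms` (one per
#'   window, in window order), the `windows` set, and the
#'   `normalization` scale factors applied.
#' @export
apply_windows <- function(volume, windows, dispersion = NULL,
                          equalize_energy = TRUE, compensate_rolloff = NULL,
                          background = "auto") {
  if (!inherits(windows, "gaussian_windows")) {
    stopf("`windows` must come from design_windows()")
  }
  band <- range(volume$wavelength)
  inside <- windows$centers >= band[1] & windows$centers <= band[2]
  if (!all(inside)) {
    warnf("dropping window(s) centred at %s nm: outside detected band %.0f-%.0f nm",
          paste(windows$centers[!inside], collapse = ", "), band[1], band[2])
    if (!any(inside)) stopf("no window centre inside the detected band")
    windows <- design_subset(windows, which(inside))
  }
  raw_ref <- rowMeans(matrix(volume$counts, nrow = volume$dims[1]))
  if (!isTRUE(volume$meta$background_removed)) {
    volume <- remove_background(volume, background)
  }
  rs <- resample_volume(volume)
  P <- length(rs$k)
  lambda_k <- 2 * pi / rs$k
  ref_k <- resample_to_k(raw_ref, volume$wavelength)$values
  phase <- if (!is.null(dispersion)) {
    exp(1i * dispersion_phase(dispersion, rs$k))
  } else 1
  dk <- (rs$k[P] - rs$k[1]) / (P - 1)
  delta_mm <- pi / (P * dk) * 1e-6
  half <- seq_len(P %/% 2L)
  rates <- if (is.null(compensate_rolloff)) {
    rep(NA_real_, windows$n)
  } else {
    rep_len(compensate_rolloff, windows$n)
  }
  areas <- numeric(windows$n)
  tomograms <- vector("list", windows$n)
  scales <- rep(1, windows$n)
  for (i in seq_len(windows$n)) {
    w <- window_profile(windows$centers[i], windows$fwhms[i], lambda_k)
    areas[i] <- sum(pmax(ref_k, 0) * w)
  }
  for (i in seq_len(windows$n)) {
    w <- window_profile(windows$centers[i], windows$fwhms[i], lambda_k)
    if (equalize_energy && areas[i] > 0) scales[i] <- areas[1] / areas[i]
    spec <- rs$spectra * (w * scales[i]) * phase
    field <- stats::mvfft(spec)[half, , drop = FALSE] / sqrt(P)
    tom <- tomogram(
      field = array(field, dim = c(length(half), volume$dims[2], volume$dims[3])),
      axial_pitch = delta_mm,
      meta = c(volume$meta,
               list(window_center = windows$centers[i],
                    window_fwhm = windows$fwhms[i]))
    )
    if (!is.na(rates[i])) tom <- compensate_rolloff(tom, rates[i])
    tomograms[[i]] <- tom
  }
  structure(
    list(tomograms = tomograms, windows = windows, normalization = scales),
    class = "subband_volume"
  )
}

# Subset a gaussian_windows object (keeps the constant-resolution FWHMs of
# the original design rather than re-solving).
design_subset <- function(windows, idx) {
  structure(
    list(centers = windows$centers[idx], fwhms = windows$fwhms[idx],
         total_fwhm = sum(windows$fwhms[idx]), n = length(idx),
         axial_resolution = windows$axial_resolution),
    class = "gaussian_windows"
  )
}

#' @export
print.subband_volume <- function(x, ...) {
  cat(sprintf("Sub-band volume: %d window(s) at %s nm\n",
              x$windows$n, paste(round(x$windows$centers), collapse = ", ")))
  invisible(x)
}

#' Compose three sub-band tomograms into an RGB volume
#'
#' Maps the longest-wavelength window to the red channel, the middle to
#' green and the shortest to blue. Each channel is the log-compressed
#' intensity clipped to `dynamic_range` dB below the global maximum and
#' scaled to `[0, 1]`, so voxels with equal contributions in all three bands
#' appear grey/white.
#'
#' @param subbands A `subband_volume` with exactly 3 windows.
#' @param dynamic_range Displayed dynamic range in dB (default 40).
#' @return Numeric array `(nz, nx, ny, 3)` with channels ordered R, G, B.
#' @export
compose_rgb <- function(subbands, dynamic_range = 40) {
  if (!inherits(subbands, "subband_volume") || subbands$windows$n != 3L) {
    stopf("`subbands` must hold exactly 3 windows (blue, green, red)")
  }
  I <- lapply(subbands$tomograms, tomogram_intensity)
  top <- max(vapply(I, max, numeric(1)))
  if (top <= 0) stopf("all sub-band intensities are zero")
  dm <- dim(I[[1]])
  out <- array(0, dim = c(dm, 3L))
  # window order is blue -> red; channel order is R, G, B
  chan_of_window <- c(3L, 2L, 1L)
  for (w in 1:3) {
    db <- 10 * log10(I[[w]] / top)
    out[, , , chan_of_window[w]] <- clamp(1 + db / dynamic_range, 0, 1)
  }
  out
}

#' Split two non-overlapping sub-bands into independent channels
#'
#' For a two-window set whose supports (centre +/- 2 sigma) are disjoint,
#' the two sub-band images carry completely independent spectral
#' information. Overlapping supports violate that independence contract and
#' are rejected.
#'
#' @param subbands A `subband_volume` with exactly 2 windows.
#' @return List with `short` and `long` (the two tomograms in order of
#'   centre wavelength) and `report` (the support intervals and their gap in
#'   nm).
#' @export
split_channels <- function(subbands) {
  if (!inherits(subbands, "subband_volume") || subbands$windows$n != 2L) {
    stopf("`subbands` must hold exactly 2 windows")
  }
  w <- subbands$windows
  s1 <- window_support(w$centers[1], w$fwhms[1])
  s2 <- window_support(w$centers[2], w$fwhms[2])
  gap <- s2[1] - s1[2]
  if (gap <= 0) {
    stopf(paste0(
      "window supports overlap (%.1f-%.1f nm vs %.1f-%.1f nm): ",
      "the two channels would not be independent"),
      s1[1], s1[2], s2[1], s2[2])
  }
  list(short = subbands$tomograms[[1]], long = subbands$tomograms[[2]],
       report = list(support_short = s1, support_long = s2, gap_nm = gap))
}

#' Per-window spectral profiles of a region
#'
#' For every window of a sub-band volume, computes the mean and standard
#' deviation of (i) the intensity and (ii) the local attenuation coefficient
#' over the voxels of a surface-referenced region. Mean intensities (and
#' their SDs) are normalized to the maximum across windows.
#'
#' @param subbands A `subband_volume`.
#' @param surface A `surface_map`.
#' @param region A [region_spec()] (its `sample_count` is ignored: all
#'   region voxels enter the averages).
#' @param delta Axial pitch in mm used for the local attenuation (default:
#'   the sub-band tomogram pitch).
#' @return Data frame with one row per window: `window`, `center_nm`,
#'   `fwhm_nm`, `mean_intensity`, `sd_intensity` (normalized),
#'   `mean_attenuation`, `sd_attenuation` (mm^-1), `n_voxels`.
#' @export
spectral_profiles <- function(subbands, surface, region, delta = NULL) {
  if (!inherits(subbands, "subband_volume")) {
    stopf("`subbands` must be a subband_volume")
  }
  n <- subbands$windows$n
  mi <- si <- ma <- sa <- nv <- numeric(n)
  for (i in seq_len(n)) {
    tom <- subbands$tomograms[[i]]
    I <- tomogram_intensity(tom)
    d <- delta %||% tom$axial_pitch
    vals <- collect_region_values(I, surface, region, tom$axial_pitch * 1000)
    if (!length(vals)) stopf("region contains no valid voxels")
    att <- local_attenuation_volume(I, delta = d)
    mu_vals <- collect_region_values(att$mu, surface, region,
                                     tom$axial_pitch * 1000,
                                     valid = att$valid)
    mi[i] <- mean(vals)
    si[i] <- stats::sd(vals)
    ma[i] <- mean(mu_vals)
    sa[i] <- stats::sd(mu_vals)
    nv[i] <- length(vals)
  }
  top <- max(mi)
  data.frame(
    window = seq_len(n),
    center_nm = subbands$windows$centers,
    fwhm_nm = subbands$windows$fwhms,
    mean_intensity = mi / top,
    sd_intensity = si / top,
    mean_attenuation = ma,
    sd_attenuation = sa,
    n_voxels = nv
  )
}
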