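# Attenuation coefficient estimation.
#
# Two estimators are provided. The *global* estimator fits a single
# exponential decay I(z) = I0 exp(-mu z) to each A-scan over a window below
# the detected surface (Beer-Lambert behaviour of a homogeneous medium).
# The *local* estimator inverts the discrete depth-resolved model of
# Vermeer et al., assigning an attenuation coefficient to every pixel from
# the ratio of its intensity to the integrated intensity below it.
#
# Convention note: the exponential-fit model is written with a single-pass
# exponent exp(-mu z) while the per-pixel model carries the round-trip
# factor 1/(2 Delta). The two therefore differ by a factor of two on the
# same data. Both are implemented exactly as written and the `roundtrip`
# flag of `fit_global_attenuation()` converts the fitted decay rate to the
# round-trip ("double") convention when requested, so that the two
# estimators can be compared consistently.

#' Per-pixel (local) attenuation coefficient
#'
#' Computes the depth-resolved attenuation coefficient
#' \deqn{\mu_t[i] = \frac{1}{2\Delta}\,
#'   \ln\!\left(1 + \frac{I[i]}{\sum_{j=i+1}^{N} I[j]}\right)}
#' for every pixel of an A-scan intensity profile (natural logarithm). For a
#' pure geometric decay \eqn{I[i] \propto e^{-2\mu\Delta i}} with a long
#' tail this is exact: \eqn{1 + I[i]/\mathrm{tail} = e^{2\mu\Delta}}. The
#' last pixel has an empty tail and is marked invalid rather than
#' extrapolated; pixels whose tail sums to zero while \eqn{I[i] > 0} yield
#' `Inf` and are flagged invalid.
#'
#' The estimator assumes the recorded decay is fully contained in the
#' profile. When the signal is truncated (scene shorter than the decay
#' length) the estimates carry an upward truncation bias; see the package
#' vignette.
#'
#' @param intensity Non-negative intensity profile: a vector (one A-scan) or
#'   a matrix with depth along rows (one column per A-scan).
#' @param delta Axial pixel pitch \eqn{\Delta} in mm (> 0).
#' @return A list with `mu` (mm^-1, same shape as `intensity`) and a logical
#'   `valid` mask of the same shape.
#' @examples
#' local_attenuation(c(3, 1), delta = 0.5)$mu[1] # log(4)
#' @export
local_attenuation <- function(intensity, delta) {
  assert_scalar_num(delta, "delta", min = 0, strict = TRUE)
  vec <- is.null(dim(intensity))
  m <- if (vec) matrix(intensity, ncol = 1L) else as.matrix(intensity)
  if (any(!is.finite(m)) || any(m < 0)) {
    stopf("`intensity` must be finite and non-negative")
  }
  n <- nrow(m)
  if (n < 2L) stopf("need at least 2 depth pixels")
  # tail[i] = sum of I below pixel i (exclusive), accumulated from the
  # bottom up so long decays do not lose the tail to cancellation
  rcs <- apply(m[n:1, , drop = FALSE], 2L, cumsum)
  if (is.null(dim(rcs))) rcs <- matrix(rcs, ncol = ncol(m))
  tail_sum <- rbind(rcs[(n - 1):1, , drop = FALSE], rep(0, ncol(m)))
  mu <- log1p(m / tail_sum) / (2 * delta)
  valid <- is.finite(mu)
  valid[n, ] <- FALSE
  mu[n, ] <- NA_real_
  zero_over_zero <- tail_sum == 0 & m == 0
  mu[zero_over_zero] <- NA_real_
  valid[zero_over_zero] <- FALSE
  if (vec) {
    list(mu = as.vector(mu), valid = as.vector(valid))
  } else {
    list(mu = mu, valid = valid)
  }
}

#' Local attenuation volume from a tomogram
#'
#' Applies [local_attenuation()] to every A-line of an intensity volume.
#'
#' @param x A `tomogram` (see [reconstruct()]) or a numeric array with depth
#'   along the first dimension.
#' @param delta Axial pixel pitch in mm. Defaults to the tomogram's pitch;
#'   pass `delta = tom$axial_pitch / n` to work in geometric depth for a
#'   medium of group index `n`.
#' @return An object of class `attenuation_volume`: list with `mu` and
#'   `valid` arrays shaped like the input and the `delta` used.
#' @export
local_attenuation_volume <- function(x, delta = NULL) {
  if (inherits(x, "tomogram")) {
    intensity <- tomogram_intensity(x)
    delta <- delta %||% x$axial_pitch
  } else {
    intensity <- x
    if (is.null(delta)) stopf("`delta` is required for a plain array")
  }
  dm <- dim(intensity)
  flat <- matrix(intensity, nrow = dm[1])
  res <- local_attenuation(flat, delta)
  structure(
    list(
      mu = array(res$mu, dim = dm),
      valid = array(res$valid, dim = dm),
      delta = delta
    ),
    class = "attenuation_volume"
  )
}

#' Global (per A-scan) attenuation fit
#'
#' Fits the exponential decay model \eqn{I(z) = I_0 e^{-\mu_t z}} to one
#' A-scan over a window of depth `fit_depth` below the surface, with depth
#' measured from the surface pixel. The fit is seeded by a closed-form
#' log-linear regression and refined by one round of Levenberg-Marquardt
#' least squares in the linear intensity domain with fixed tolerances, so it
#' is deterministic. Fits with fewer than 8 samples, all-zero windows, or a
#' non-finite refined estimate are returned with `valid = FALSE` rather than
#' raising an error mid-volume.
#'
#' @param intensity Non-negative intensity A-scan (vector, depth-ordered).
#' @param surface_index Depth index (1-based) of the tissue surface.
#' @param fit_depth Fit window length below the surface, in mm (default
#'   0.2 mm).
#' @param delta Axial pixel pitch in mm.
#' @param roundtrip `"single"` returns the fitted decay rate of the model as
#'   written; `"double"` halves it to express the result in the round-trip
#'   convention of [local_attenuation()].
#' @param noise_floor Constant background intensity subtracted before
#'   fitting (default 0).
#' @return A list with `mu` (mm^-1), `i0`, `residual` (RMS relative
#'   residual), `n` (samples used), `fit_depth`, and `valid`.
#' @examples
#' z <- (0:199) * 1e-3
#' fit <- fit_global_attenuation(7 * exp(-0.39 * z), 1, 0.2, 1e-3)
#' round(fit$mu, 6) # 0.39
#' @export
fit_global_attenuation <- function(intensity, surface_index, fit_depth = 0.2,
                                   delta, roundtrip = c("single", "double"),
                                   noise_floor = 0) {
  roundtrip <- match.arg(roundtrip)
  assert_scalar_num(delta, "delta", min = 0, strict = TRUE)
  assert_scalar_num(fit_depth, "fit_depth", min = 0, strict = TRUE)
  invalid <- list(mu = NA_real_, i0 = NA_real_, residual = NA_real_,
                  n = 0L, fit_depth = fit_depth, valid = FALSE)
  n_tot <- length(intensity)
  if (is.na(surface_index) || surface_index < 1 || surface_index > n_tot) {
    return(invalid)
  }
  n_px <- floor(fit_depth / delta)
  idx <- seq.int(surface_index, min(n_tot, surface_index + n_px - 1L))
  y <- pmax(intensity[idx] - noise_floor, 0)
  if (length(idx) < 8L || !any(y > 0)) return(invalid)
  z <- (seq_along(idx) - 1) * delta
  # closed-form log-linear seed on the positive samples
  pos <- y > 0
  if (sum(pos) < 8L) return(invalid)
  co <- stats::lm.fit(cbind(1, z[pos]), log(y[pos]))$coefficients
  i0_seed <- unname(exp(co[1]))
  m_seed <- unname(max(-co[2], 0))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ i0 * exp(-m * z),
      start = list(i0 = i0_seed, m = m_seed),
      control = minpack.lm::nls.lm.control(maxiter = 50, ftol = 1e-10)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    i0 <- i0_seed
    m <- m_seed
  } else {
    cf <- stats::coef(fit)
    i0 <- cf[["i0"]]
    m <- cf[["m"]]
  }
  if (!is.finite(m) || !is.finite(i0)) return(invalid)
  pred <- i0 * exp(-m * z)
  resid <- sqrt(mean((y - pred)^2)) / max(mean(y), .Machine$double.eps)
  mu <- if (roundtrip == "double") m / 2 else m
  list(mu = unname(mu), i0 = unname(i0), residual = resid,
       n = length(idx), fit_depth = fit_depth, valid = TRUE)
}

#' Global attenuation map over a volume
#'
#' Runs [fit_global_attenuation()] on every A-line of an intensity volume
#' beneath a detected surface and returns lateral maps of the fitted
#' parameters.
#'
#' @param x A `tomogram` or numeric array (depth first).
#' @param surface A `surface_map` from [detect_surface()].
#' @param fit_depth,delta,roundtrip,noise_floor Passed to
#'   [fit_global_attenuation()].
#' @param offset_px Pixels skipped below the detected surface before the
#'   fit window starts, avoiding the specular entry peak (default 0).
#' @return List of matrices `mu`, `i0`, `residual` and logical `valid`, one
#'   entry per A-line.
#' @export
global_attenuation_map <- function(x, surface, fit_depth = 0.2, delta = NULL,
                                   roundtrip = c("single", "double"),
                                   noise_floor = 0, offset_px = 0) {
  roundtrip <- match.arg(roundtrip)
  if (inherits(x, "tomogram")) {
    intensity <- tomogram_intensity(x)
    delta <- delta %||% x$axial_pitch
  } else {
    intensity <- x
    if (is.null(delta)) stopf("`delta` is required for a plain array")
  }
  dm <- dim(intensity)
  nx <- dm[2]
  ny <- if (length(dm) >= 3) dm[3] else 1L
  mu <- i0 <- resid <- matrix(NA_real_, nx, ny)
  valid <- matrix(FALSE, nx, ny)
  flat <- matrix(intensity, nrow = dm[1])
  sidx <- surface$surface_index
  svalid <- surface$valid_mask
  for (j in seq_len(nx * ny)) {
    if (!svalid[j]) next
    f <- fit_global_attenuation(flat[, j], sidx[j] + offset_px, fit_depth,
                                delta, roundtrip, noise_floor)
    mu[j] <- f$mu
    i0[j] <- f$i0
    resid[j] <- f$residual
    valid[j] <- f$valid
  }
  list(mu = mu, i0 = i0, residual = resid, valid = valid)
}

#' Region-averaged global attenuation fit
#'
#' Estimates one attenuation coefficient for a lateral region by averaging
#' surface-aligned A-scan intensities (incoherent speckle averaging) and
#' fitting the exponential decay model to the mean profile. Each column's
#' segment is roll-off-corrected at its own absolute optical depth before
#' averaging, so the fitted decay reflects tissue attenuation only. This is
#' far less noisy than averaging per-A-line fits when speckle dominates.
#'
#' @param tom An *uncompensated* `tomogram` (roll-off correction is applied
#'   internally at absolute depth).
#' @param surface A `surface_map`.
#' @param region Optional [region_spec()] restricting the lateral extent
#'   (its depth slab and sample count are ignored); `NULL` uses all valid
#'   A-lines.
#' @param fit_depth Fit window below the surface in mm of geometric depth
#'   (default 0.2).
#' @param offset_px Pixels skipped below the detected surface before the
#'   window starts, avoiding the specular entry peak (default 5).
#' @param rolloff_db_mm Roll-off rate; defaults to the tomogram metadata.
#' @param group_index Group refractive index converting optical to
#'   geometric depth (default: metadata value, else 1.36).
#' @param roundtrip Passed to [fit_global_attenuation()]; default
#'   `"double"` so the result is comparable with [local_attenuation()].
#' @return As [fit_global_attenuation()], plus `n_lines` averaged.
#' @export
fit_region_attenuation <- function(tom, surface, region = NULL,
                                   fit_depth = 0.2, offset_px = 5,
                                   rolloff_db_mm = NULL, group_index = NULL,
                                   roundtrip = c("double", "single")) {
  roundtrip <- match.arg(roundtrip)
  if (!inherits(tom, "tomogram")) stopf("`tom` must be a tomogram")
  rate <- rolloff_db_mm %||% tom$meta$rolloff_db_mm %||% 0
  n_med <- group_index %||% tom$meta$refractive_index %||% 1.36
  I <- tomogram_intensity(tom)
  dm <- dim(I)
  nz <- dm[1]
  flat <- matrix(I, nrow = nz)
  delta_geom <- tom$axial_pitch / n_med
  n_fit <- floor(fit_depth / delta_geom)
  gain <- 10^(rate * (tom$depth_um / 1000) / 10)
  sidx <- as.vector(surface$surface_index) + as.integer(offset_px)
  ok <- as.vector(surface$valid_mask) & !is.na(sidx) &
    (sidx + n_fit - 1L <= nz) & sidx >= 1L
  if (!is.null(region)) {
    keep <- matrix(FALSE, dm[2], if (length(dm) >= 3) dm[3] else 1L)
    xs <- max(1L, region$x_range[1]):min(nrow(keep), region$x_range[2])
    ys <- max(1L, region$y_range[1]):min(ncol(keep), region$y_range[2])
    keep[xs, ys] <- TRUE
    ok <- ok & as.vector(keep)
  }
  cols <- which(ok)
  if (length(cols) < 1L) {
    return(list(mu = NA_real_, i0 = NA_real_, residual = NA_real_, n = 0L,
                fit_depth = fit_depth, valid = FALSE, n_lines = 0L))
  }
  seg <- vapply(cols, function(j) {
    sel <- seq.int(sidx[j], sidx[j] + n_fit - 1L)
    flat[sel, j] * gain[sel]
  }, numeric(n_fit))
  prof <- rowMeans(seg)
  out <- fit_global_attenuation(prof, 1L, fit_depth, delta_geom, roundtrip)
  out$n_lines <- length(cols)
  out
}

#' En-face mean of local attenuation over a surface-referenced slab
#'
#' For each A-line, averages the valid local attenuation coefficients in the
#' depth slab `[depth_start, depth_end)` micrometres below the detected
#' surface. Slab indices follow the half-open pixel convention (floor of the
#' start offset, ceiling of the end). A-lines with no valid surface or no
#' valid attenuation pixel in the slab are `NA`.
#'
#' @param att An `attenuation_volume` from [local_attenuation_volume()].
#' @param surface A `surface_map`.
#' @param depth_start,depth_end Slab bounds below the surface in
#'   micrometres, `depth_end > depth_start`.
#' @return Matrix (nx x ny) of mean attenuation in mm^-1.
#' @export
attenuation_enface <- function(att, surface, depth_start, depth_end) {
  if (!inherits(att, "attenuation_volume")) {
    stopf("`att` must be an attenuation_volume")
  }
  if (depth_end <= depth_start) stopf("`depth_end` must exceed `depth_start`")
  dm <- dim(att$mu)
  nz <- dm[1]
  nlat <- prod(dm[-1])
  delta_um <- att$delta * 1000
  px0 <- floor(depth_start / delta_um)
  px1 <- ceiling(depth_end / delta_um)
  out <- rep(NA_real_, nlat)
  mu_flat <- matrix(att$mu, nrow = nz)
  valid_flat <- matrix(att$valid, nrow = nz)
  sidx <- as.vector(surface$surface_index)
  svalid <- as.vector(surface$valid_mask)
  for (j in seq_len(nlat)) {
    if (!isTRUE(svalid[j])) next
    i0 <- sidx[j] + px0
    i1 <- min(sidx[j] + px1 - 1L, nz)
    if (i1 < i0) next
    sel <- seq.int(i0, i1)
    ok <- valid_flat[sel, j]
    if (!any(ok)) next
    out[j] <- mean(mu_flat[sel, j][ok])
  }
  matrix(out, dm[2], if (length(dm) >= 3) dm[3] else 1L)
}
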