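# Region-level statistics: sampling voxel values from surface-referenced
# regions, intensity-versus-attenuation clustering summaries, pairwise
# t-tests with Bonferroni correction, and clearing time-course tracking.

#' Region specification
#'
#' A lateral rectangle combined with a surface-referenced depth slab, plus
#' the number of voxel samples requested from it.
#'
#' @param label Region label, e.g. `"WM"`, `"GM"`, `"plaque"` or any custom
#'   string.
#' @param x_range,y_range Inclusive A-scan index ranges `(lo, hi)`.
#' @param depth_range Depth slab below the surface in micrometres,
#'   `(start, end)` with `end > start` (half-open in pixels after
#'   conversion).
#' @param sample_count Number of voxel samples requested (>= 1); when the
#'   region holds fewer voxels, all are used.
#' @return An object of class `region_spec`.
#' @export
region_spec <- function(label, x_range, y_range, depth_range,
                        sample_count = 200) {
  if (length(x_range) != 2 || length(y_range) != 2 || length(depth_range) != 2) {
    stopf("`x_range`, `y_range`, `depth_range` must each be (lo, hi)")
  }
  if (depth_range[2] <= depth_range[1]) {
    stopf("`depth_range` end must exceed start")
  }
  if (sample_count < 1) stopf("`sample_count` must be >= 1")
  structure(
    list(label = label, x_range = as.integer(x_range),
         y_range = as.integer(y_range), depth_range = as.numeric(depth_range),
         sample_count = as.integer(sample_count)),
    class = "region_spec"
  )
}

# All voxel values of `arr` (depth-first array) inside the region's
# surface-referenced slab; `valid` optionally masks voxels.
collect_region_values <- function(arr, surface, region, delta_um,
                                  valid = NULL) {
  dm <- dim(arr)
  nz <- dm[1]
  nx <- dm[2]
  ny <- if (length(dm) >= 3) dm[3] else 1L
  xs <- max(1L, region$x_range[1]):min(nx, region$x_range[2])
  ys <- max(1L, region$y_range[1]):min(ny, region$y_range[2])
  px0 <- floor(region$depth_range[1] / delta_um)
  px1 <- ceiling(region$depth_range[2] / delta_um)
  out <- vector("list", length(xs) * length(ys))
  idx <- 0L
  for (iy in ys) {
    for (ix in xs) {
      idx <- idx + 1L
      if (!isTRUE(surface$valid_mask[ix, iy])) next
      s <- surface$surface_index[ix, iy]
      i0 <- s + px0
      i1 <- min(s + px1 - 1L, nz)
      if (i1 < i0 || i0 < 1) next
      sel <- seq.int(i0, i1)
      v <- arr[cbind(sel, ix, iy)]
      if (!is.null(valid)) v <- v[valid[cbind(sel, ix, iy)]]
      out[[idx]] <- v
    }
  }
  unlist(out) %||% numeric(0)
}

#' Sample voxel values from a region
#'
#' Collects all voxel values of the surface-referenced slab described by
#' `region` and, when more are available than `sample_count`, draws a seeded
#' uniform subsample without replacement. The same seed always returns the
#' identical sample.
#'
#' @param x A `tomogram` (its intensity is sampled), an
#'   `attenuation_volume` (its valid local coefficients are sampled), or a
#'   numeric depth-first array.
#' @param surface A `surface_map`.
#' @param region A [region_spec()].
#' @param seed Integer seed for the subsample.
#' @param delta_um Axial pitch in micrometres (required for plain arrays).
#' @param units Unit string recorded in the result.
#' @return An object of class `sample_set`: `values`, `label`, `units`,
#'   `n`.
#' @export
extract_region <- function(x, surface, region, seed = 1, delta_um = NULL,
                           units = NULL) {
  if (inherits(x, "tomogram")) {
    arr <- tomogram_intensity(x)
    delta_um <- delta_um %||% (x$axial_pitch * 1000)
    units <- units %||% "intensity"
    valid <- NULL
  } else if (inherits(x, "attenuation_volume")) {
    arr <- x$mu
    delta_um <- delta_um %||% (x$delta * 1000)
    units <- units %||% "mm^-1"
    valid <- x$valid
  } else {
    arr <- x
    if (is.null(delta_um)) stopf("`delta_um` is required for a plain array")
    units <- units %||% "value"
    valid <- NULL
  }
  vals <- collect_region_values(arr, surface, region, delta_um, valid)
  vals <- vals[is.finite(vals)]
  if (!length(vals)) stopf("region '%s' contains no valid voxels", region$label)
  if (length(vals) > region$sample_count) {
    vals <- with_seed(seed, vals[sample.int(length(vals), region$sample_count)])
  }
  structure(
    list(values = vals, label = region$label, units = units,
         n = length(vals)),
    class = "sample_set"
  )
}

#' Pair intensity and attenuation samples into a scatter dataset
#'
#' Index-aligns intensity and attenuation sample sets drawn from the same
#' region(s) and summarizes each group by its centroid. With two or more
#' groups, a separation summary (distance between centroids divided by the
#' pooled per-axis SD) is included.
#'
#' @param intensity A `sample_set` or list of sample sets (one per group).
#' @param attenuation Matching `sample_set` or list; lengths must agree
#'   pairwise.
#' @return List with `points` (data frame `group, intensity, attenuation`),
#'   `centroids` (one row per group) and, for >= 2 groups, `separation`.
#' @export
pair_intensity_attenuation <- function(intensity, attenuation) {
  as_list <- function(x) if (inherits(x, "sample_set")) list(x) else x
  ints <- as_list(intensity)
  atts <- as_list(attenuation)
  if (length(ints) != length(atts)) stopf("group counts differ")
  pts <- list()
  for (g in seq_along(ints)) {
    a <- ints[[g]]
    b <- atts[[g]]
    if (length(a$values) != length(b$values)) {
      stopf("group '%s': %d intensity vs %d attenuation samples",
            a$label, length(a$values), length(b$values))
    }
    pts[[g]] <- data.frame(group = a$label, intensity = a$values,
                           attenuation = b$values)
  }
  points <- do.call(rbind, pts)
  centroids <- do.call(rbind, lapply(pts, function(d) {
    data.frame(group = d$group[1], intensity = mean(d$intensity),
               attenuation = mean(d$attenuation),
               sd_intensity = stats::sd(d$intensity),
               sd_attenuation = stats::sd(d$attenuation))
  }))
  out <- list(points = points, centroids = centroids)
  if (nrow(centroids) >= 2) {
    pool_i <- sqrt(mean(centroids$sd_intensity^2))
    pool_a <- sqrt(mean(centroids$sd_attenuation^2))
    pairs <- utils::combn(nrow(centroids), 2)
    sep <- apply(pairs, 2, function(p) {
      sqrt(((centroids$intensity[p[1]] - centroids$intensity[p[2]]) / pool_i)^2 +
             ((centroids$attenuation[p[1]] - centroids$attenuation[p[2]]) / pool_a)^2)
    })
    out$separation <- data.frame(
      group1 = centroids$group[pairs[1, ]],
      group2 = centroids$group[pairs[2, ]],
      centroid_distance_pooled_sd = sep
    )
  }
  out
}

#' Pairwise two-sample t-tests with Bonferroni correction
#'
#' Runs a two-sample t-test for every unordered pair of groups (Welch by
#' default; pooled-variance optional) and applies the Bonferroni correction
#' `p_adj = min(1, m p)` with `m` the number of pairs. A pair of identical
#' zero-variance samples yields `p = 1` (not significant) rather than an
#' error.
#'
#' @param samples Named list of `sample_set` objects or numeric vectors
#'   (>= 2 groups, each with >= 2 values).
#' @param alpha Significance level applied to the adjusted p values
#'   (default 0.05).
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @param transform `"none"` or `"db"` (compare intensities on the decibel
#'   scale; requires positive values).
#' @return Data frame with one row per pair: `group1`, `group2`,
#'   `statistic`, `df`, `p_value`, `p_adjusted`, `significant`.
#' @export
compare_groups <- function(samples, alpha = 0.05, var_equal = FALSE,
                           transform = c("none", "db")) {
  transform <- match.arg(transform)
  vals <- lapply(samples, function(s) {
    v <- if (inherits(s, "sample_set")) s$values else as.numeric(s)
    if (transform == "db") {
      if (any(v <= 0)) stopf("dB transform requires positive values")
      v <- to_db(v)
    }
    v
  })
  labs <- names(samples)
  if (is.null(labs)) {
    labs <- vapply(seq_along(samples), function(i) {
      s <- samples[[i]]
      if (inherits(s, "sample_set")) s$label else paste0("group", i)
    }, character(1))
  }
  if (length(vals) < 2) stopf("need at least 2 groups")
  if (any(vapply(vals, length, integer(1)) < 2)) {
    stopf("every group needs at least 2 values")
  }
  pairs <- utils::combn(length(vals), 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(j) {
    a <- vals[[pairs[1, j]]]
    b <- vals[[pairs[2, j]]]
    tt <- tryCatch(
      stats::t.test(a, b, var.equal = var_equal),
      error = function(e) NULL
    )
    if (is.null(tt)) {
      # degenerate zero-variance case
      if (isTRUE(all.equal(mean(a), mean(b)))) {
        stat <- 0; df <- length(a) + length(b) - 2; p <- 1
      } else {
        stat <- Inf; df <- length(a) + length(b) - 2; p <- 0
      }
    } else {
      stat <- unname(tt$statistic); df <- unname(tt$parameter); p <- tt$p.value
    }
    data.frame(group1 = labs[pairs[1, j]], group2 = labs[pairs[2, j]],
               statistic = stat, df = df, p_value = p,
               p_adjusted = min(1, m * p))
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p_adjusted < alpha
  out
}

#' Clearing time-course of region amplitude
#'
#' Tracks the mean OCM amplitude (square root of intensity) in a
#' surface-referenced region across a time-ordered series of volumes, e.g.
#' during optical clearing. All means and SDs are normalized by the mean of
#' the first time point, and a least-squares trend line is fitted through
#' the normalized means. Time points whose region holds no valid surface
#' are dropped with a warning.
#'
#' @param tomograms Time-ordered list of `tomogram` objects.
#' @param surfaces List of matching `surface_map` objects.
#' @param roi A [region_spec()] shared by all time points.
#' @param times Strictly increasing acquisition times in minutes.
#' @return List with `points` (data frame `time, mean_amplitude, sd`,
#'   normalized) and `trend` (named intercept/slope of the fitted line, per
#'   minute).
#' @export
clearing_timecourse <- function(tomograms, surfaces, roi, times) {
  n <- length(tomograms)
  if (n < 2) stopf("need at least 2 time points")
  if (length(surfaces) != n || length(times) != n) {
    stopf("`tomograms`, `surfaces` and `times` lengths must agree")
  }
  if (any(times < 0) || is.unsorted(times, strictly = TRUE)) {
    stopf("`times` must be nonnegative and strictly increasing")
  }
  mean_amp <- sd_amp <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    tom <- tomograms[[i]]
    amp <- sqrt(collect_region_values(tomogram_intensity(tom), surfaces[[i]],
                                      roi, tom$axial_pitch * 1000))
    if (!length(amp)) {
      warnf("time point %g min has no valid surface in the ROI; dropped", times[i])
      next
    }
    mean_amp[i] <- mean(amp)
    sd_amp[i] <- stats::sd(amp)
  }
  keep <- !is.na(mean_amp)
  if (!keep[1]) stopf("the first (pre-clearing) time point must be valid")
  ref <- mean_amp[1]
  pts <- data.frame(
    time = times[keep],
    mean_amplitude = mean_amp[keep] / ref,
    sd = sd_amp[keep] / ref
  )
  fit <- stats::lm(mean_amplitude ~ time, data = pts)
  list(points = pts,
       trend = c(intercept = unname(stats::coef(fit)[1]),
                 slope = unname(stats::coef(fit)[2])))
}
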