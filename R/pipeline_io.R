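# Configuration, file formats and pipeline orchestration.
#
# Raw spectral volumes travel as little-endian unsigned 16-bit binary in
# A-scan-major order (spectral pixel fastest) with a JSON sidecar holding
# dimensions, wavelength calibration and provenance. Derived images are
# written as 32-bit float TIFF, tables as CSV, manifests and window sets as
# JSON. All randomness flows from the seeds in the configuration.

config_schema <- list(
  top = c("seed", "output", "instrument", "phantom", "windows", "dispersion",
          "reconstruction", "slabs", "attenuation", "regions", "stats"),
  instrument = c("wavelength_min", "wavelength_max", "center_wavelength",
                 "source_fwhm", "n_spectral_pixels", "bit_depth",
                 "rolloff_db_mm", "reference_level", "full_scale_fraction",
                 "noise_model"),
  phantom = c("lateral_shape", "lateral_pitch", "axial_extent", "axial_step",
              "layers", "inclusions", "surface_tilt", "refractive_index",
              "lateral_regions", "speckle", "scatterers_per_voxel"),
  windows = c("total_fwhm", "centers"),
  dispersion = c("inject", "estimate", "order"),
  reconstruction = c("threshold_sd", "smoothing_px"),
  slabs = c("enface", "attenuation"),
  attenuation = c("fit_depth_um", "roundtrip", "compensate_rolloff",
                  "geometric_depth"),
  stats = c("enabled", "alpha", "transform"),
  region = c("label", "x_range", "y_range", "depth_range", "sample_count")
)

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad)) {
    stopf("unknown key(s) in %s: %s (allowed: %s)", where,
          paste(bad, collapse = ", "), paste(allowed, collapse = ", "))
  }
}

#' Load and validate a pipeline configuration
#'
#' Reads a JSON or YAML configuration (by file extension), rejects unknown
#' keys with a message naming the offending key, fills defaults (units:
#' wavelengths nm, depths/slabs micrometres, fit depth micrometres), and
#' validates ordering rules such as strictly increasing window centres.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return An object of class `pipeline_config` (a validated named list).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stopf("config file '%s' does not exist", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  validate_config(raw)
}

#' Validate a configuration list
#'
#' @param raw Named list with the structure produced by [load_config()].
#' @return An object of class `pipeline_config`.
#' @export
validate_config <- function(raw) {
  check_keys(raw, config_schema$top, "config")
  if (is.null(raw$seed)) stopf("missing required key `seed`")
  assert_scalar_num(raw$seed, "seed")

  for (sec in c("instrument", "phantom", "windows", "dispersion",
                "reconstruction", "slabs", "attenuation", "stats")) {
    if (!is.null(raw[[sec]])) check_keys(raw[[sec]], config_schema[[sec]], sec)
  }
  for (i in seq_along(raw$regions)) {
    check_keys(raw$regions[[i]], config_schema$region,
               sprintf("regions[%d]", i))
  }

  cfg <- raw
  cfg$output <- cfg$output %||% "specoct-out"
  cfg$instrument <- utils::modifyList(
    list(n_spectral_pixels = 1024), as.list(cfg$instrument %||% list()))
  cfg$phantom <- utils::modifyList(
    list(lateral_shape = c(32L, 32L), lateral_pitch = 2, axial_extent = 120,
         axial_step = 3,
         layers = list(list(top_depth = 5, attenuation = 0.35,
                            backscatter = 0.05))),
    as.list(cfg$phantom %||% list()))
  cfg$windows <- utils::modifyList(
    list(total_fwhm = 156, centers = c(520, 560, 600)),
    as.list(cfg$windows %||% list()))
  if (is.unsorted(cfg$windows$centers, strictly = TRUE)) {
    stopf("`windows$centers` must be strictly increasing (got %s)",
          paste(cfg$windows$centers, collapse = ", "))
  }
  cfg$dispersion <- utils::modifyList(
    list(inject = list(), estimate = FALSE, order = 3),
    as.list(cfg$dispersion %||% list()))
  cfg$reconstruction <- utils::modifyList(
    list(threshold_sd = 4, smoothing_px = 5),
    as.list(cfg$reconstruction %||% list()))
  cfg$slabs <- utils::modifyList(
    list(enface = c(0, 100), attenuation = c(0, 100)),
    as.list(cfg$slabs %||% list()))
  cfg$attenuation <- utils::modifyList(
    list(fit_depth_um = 200, roundtrip = "double", compensate_rolloff = TRUE,
         geometric_depth = TRUE),
    as.list(cfg$attenuation %||% list()))
  cfg$stats <- utils::modifyList(
    list(enabled = TRUE, alpha = 0.05, transform = "db"),
    as.list(cfg$stats %||% list()))
  cfg$regions <- cfg$regions %||% list()
  structure(cfg, class = "pipeline_config")
}

#' Serialize a configuration to YAML
#'
#' @param config A `pipeline_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Write a raw spectral volume
#'
#' Writes `<prefix>.bin` (little-endian unsigned 16-bit, A-scan-major:
#' spectral pixel fastest, then x, then y) and `<prefix>.json` (dimensions,
#' linear wavelength calibration, metadata).
#'
#' @param volume A `spectral_volume` with integer counts in `[0, 65535]`.
#' @param prefix Output path prefix.
#' @return The two file paths, invisibly.
#' @export
write_spectral_volume <- function(volume, prefix) {
  counts <- as.integer(round(volume$counts))
  if (any(counts < 0 | counts > 65535)) {
    stopf("counts outside the unsigned 16-bit range")
  }
  signed <- ifelse(counts >= 32768L, counts - 65536L, counts)
  bin <- paste0(prefix, ".bin")
  side <- paste0(prefix, ".json")
  con <- file(bin, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(signed, con, size = 2L, endian = "little")
  meta <- volume$meta
  meta$gain <- unname(meta$gain)
  jsonlite::write_json(
    list(nx = volume$dims[2], ny = volume$dims[3], n_pixels = volume$dims[1],
         wavelength_min = min(volume$wavelength),
         wavelength_max = max(volume$wavelength),
         byte_order = "little", sample_format = "uint16",
         meta = meta),
    side, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(c(bin, side))
}

#' Read a raw spectral volume
#'
#' Counterpart of [write_spectral_volume()]. The payload size must match
#' the sidecar dimensions exactly; truncated or oversized files are rejected
#' with a byte-count diagnostic.
#'
#' @param prefix Path prefix (the function reads `<prefix>.bin` and
#'   `<prefix>.json`).
#' @return A `spectral_volume` identical to the one written.
#' @export
read_spectral_volume <- function(prefix) {
  bin <- paste0(prefix, ".bin")
  side <- paste0(prefix, ".json")
  if (!file.exists(bin) || !file.exists(side)) {
    stopf("missing '%s' or '%s'", bin, side)
  }
  hdr <- jsonlite::read_json(side, simplifyVector = TRUE)
  n <- hdr$nx * hdr$ny * hdr$n_pixels
  expected <- 2 * n
  actual <- file.size(bin)
  if (actual != expected) {
    stopf("payload size mismatch: header implies %d bytes, file has %d bytes",
          expected, actual)
  }
  con <- file(bin, "rb")
  on.exit(close(con), add = TRUE)
  counts <- readBin(con, "integer", n = n, size = 2L, signed = FALSE,
                    endian = "little")
  lambda <- seq(hdr$wavelength_min, hdr$wavelength_max,
                length.out = hdr$n_pixels)
  spectral_volume(array(counts, dim = c(hdr$n_pixels, hdr$nx, hdr$ny)),
                  lambda, as.list(hdr$meta))
}

# Write a numeric matrix/array as 32-bit float TIFF with a JSON sidecar
# recording the affine scale used to map data into [0, 1] (the tiff writer
# stores normalized samples).
write_float_tiff <- function(x, path) {
  lo <- min(x, na.rm = TRUE)
  hi <- max(x, na.rm = TRUE)
  rng <- if (hi > lo) hi - lo else 1
  norm <- (x - lo) / rng
  norm[is.na(norm)] <- 0
  if (length(dim(x)) == 3L) {
    pages <- lapply(seq_len(dim(x)[3]), function(i) t(norm[, , i]))
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  } else {
    tiff::writeTIFF(t(norm), path, bits.per.sample = 32L)
  }
  jsonlite::write_json(list(offset = lo, scale = rng),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

md5_of <- function(paths) unname(tools::md5sum(paths))

# Hash of the scientific configuration; the output location is incidental
# and excluded so identical analyses share a hash wherever they are written.
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$output <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  unname(tools::md5sum(tmp))
}

build_from_config <- function(cfg) {
  inst_args <- cfg$instrument
  nm <- inst_args$noise_model
  if (!is.null(nm)) inst_args$noise_model <- as.list(nm)
  instrument <- do.call(instrument_spec, inst_args)
  ph <- cfg$phantom
  layers <- lapply(ph$layers, function(l) do.call(phantom_layer, as.list(l)))
  inclusions <- lapply(ph$inclusions %||% list(), function(l) {
    do.call(phantom_inclusion, as.list(l))
  })
  regions <- lapply(ph$lateral_regions %||% list(), function(r) {
    list(x_range = r$x_range,
         layers = lapply(r$layers, function(l) do.call(phantom_layer, as.list(l))))
  })
  spec <- phantom_spec(
    lateral_shape = ph$lateral_shape, lateral_pitch = ph$lateral_pitch,
    layers = layers, inclusions = inclusions,
    surface_tilt = ph$surface_tilt %||% c(0, 0),
    refractive_index = ph$refractive_index %||% 1.36,
    lateral_regions = regions, speckle = isTRUE(ph$speckle),
    scatterers_per_voxel = ph$scatterers_per_voxel %||% 5L
  )
  truth <- build_phantom(spec, ph$axial_extent, ph$axial_step)
  inject <- NULL
  if (length(cfg$dispersion$inject)) {
    inject <- dispersion_model(unlist(cfg$dispersion$inject))
  }
  list(instrument = instrument, truth = truth, inject = inject)
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes the stages in order: simulate, reconstruct, spectroscopy,
#' attenuation, statistics (the last only when enabled). Every stage writes
#' its artifacts under the output directory and records their MD5 checksums
#' in the run manifest; re-running an identical configuration reproduces
#' identical checksums because all randomness is seeded from the
#' configuration. A stage failure aborts the run with the stage named.
#'
#' @param config A `pipeline_config` (from [load_config()] /
#'   [validate_config()]) or a path to a configuration file.
#' @param out_dir Output directory; defaults to the configuration's
#'   `output` entry.
#' @return An object of class `run_manifest`: `config_hash`, `package_version`,
#'   per-stage file checksums, and the completion timestamp. Also written as
#'   `manifest.json` in the output directory.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- load_config(config)
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  out <- out_dir %||% config$output
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  run_stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
    stages[[name]] <<- list(files = res, md5 = md5_of(res))
    res
  }

  built <- build_from_config(config)
  env <- new.env()

  run_stage("simulate", function() {
    env$volume <- simulate_volume(built$truth, built$instrument,
                                  dispersion = built$inject,
                                  seed = config$seed)
    f1 <- write_spectral_volume(env$volume, file.path(out, "raw"))
    f2 <- write_float_tiff(aperm(built$truth$mu, c(3, 1, 2)),
                           file.path(out, "truth_mu.tif"))
    f3 <- file.path(out, "truth_scatterers.csv")
    utils::write.csv(built$truth$scatterers, f3, row.names = FALSE)
    c(f1, f2, paste0(f2, ".json"), f3)
  })

  run_stage("reconstruct", function() {
    model <- if (isTRUE(config$dispersion$estimate)) {
      estimate_dispersion(env$volume, order = config$dispersion$order)
    } else if (!is.null(built$inject)) {
      negate_dispersion(built$inject)
    } else NULL
    env$dispersion <- model
    env$tom <- reconstruct(env$volume, dispersion = model)
    env$surface <- detect_surface(env$tom,
                                  config$reconstruction$threshold_sd,
                                  config$reconstruction$smoothing_px)
    slab <- config$slabs$enface
    ef <- enface_projection(env$tom, env$surface, slab[1], slab[2])
    f1 <- write_float_tiff(ef, file.path(out, "enface_intensity.tif"))
    surf <- env$surface$surface_index
    surf[is.na(surf)] <- 0
    tiff::writeTIFF(t(surf) / 65535, file.path(out, "surface.tif"),
                    bits.per.sample = 16L)
    f2 <- file.path(out, "surface.tif")
    c(f1, paste0(f1, ".json"), f2)
  })

  run_stage("spectroscopy", function() {
    wset <- design_windows(config$windows$total_fwhm, config$windows$centers)
    rate <- if (isTRUE(config$attenuation$compensate_rolloff)) {
      built$instrument$rolloff_db_mm
    } else NULL
    env$subbands <- apply_windows(env$volume, wset,
                                  dispersion = env$dispersion,
                                  compensate_rolloff = rate)
    f0 <- file.path(out, "windows.json")
    jsonlite::write_json(
      list(centers = wset$centers, fwhms = wset$fwhms,
           total_fwhm = wset$total_fwhm,
           axial_resolution_um = wset$axial_resolution),
      f0, auto_unbox = TRUE, digits = NA
    )
    slab <- config$slabs$enface
    files <- f0
    for (i in seq_len(wset$n)) {
      ef <- enface_projection(env$subbands$tomograms[[i]], env$surface,
                              slab[1], slab[2])
      f <- write_float_tiff(ef, file.path(out, sprintf("enface_band%d.tif", i)))
      files <- c(files, f, paste0(f, ".json"))
    }
    if (wset$n == 3L) {
      rgb <- compose_rgb(env$subbands)
      chans <- lapply(1:3, function(c3) {
        matrix(enface_projection(rgb[, , , c3], env$surface, slab[1], slab[2],
                                 delta_um = env$subbands$tomograms[[1]]$axial_pitch * 1000),
               nrow = dim(rgb)[2])
      })
      img <- array(0, dim = c(dim(chans[[1]])[2], dim(chans[[1]])[1], 3))
      for (c3 in 1:3) {
        m <- chans[[c3]]
        m[is.na(m)] <- 0
        img[, , c3] <- t(m)
      }
      f <- file.path(out, "enface_rgb.png")
      png::writePNG(clamp(img, 0, 1), f)
      files <- c(files, f)
    }
    files
  })

  run_stage("attenuation", function() {
    tom <- if (isTRUE(config$attenuation$compensate_rolloff)) {
      compensate_rolloff(env$tom)
    } else env$tom
    n_med <- built$truth$spec$refractive_index
    delta <- if (isTRUE(config$attenuation$geometric_depth)) {
      tom$axial_pitch / n_med
    } else tom$axial_pitch
    env$att <- local_attenuation_volume(tomogram_intensity(tom), delta = delta)
    slab <- config$slabs$attenuation
    ef <- attenuation_enface(env$att, env$surface, slab[1], slab[2])
    f1 <- write_float_tiff(ef, file.path(out, "enface_attenuation.tif"))
    gmap <- global_attenuation_map(
      tom, env$surface, fit_depth = config$attenuation$fit_depth_um / 1000,
      delta = delta, roundtrip = config$attenuation$roundtrip
    )
    f2 <- file.path(out, "global_attenuation.csv")
    nx <- nrow(gmap$mu)
    df <- data.frame(
      x = rep(seq_len(nx), times = ncol(gmap$mu)),
      y = rep(seq_len(ncol(gmap$mu)), each = nx),
      mu = as.vector(gmap$mu), i0 = as.vector(gmap$i0),
      residual = as.vector(gmap$residual), valid = as.vector(gmap$valid)
    )
    utils::write.csv(df, f2, row.names = FALSE)
    c(f1, paste0(f1, ".json"), f2)
  })

  if (isTRUE(config$stats$enabled) && length(config$regions) >= 1) {
    run_stage("stats", function() {
      n_med <- built$truth$spec$refractive_index
      files <- character(0)
      int_sets <- list()
      att_sets <- list()
      for (i in seq_along(config$regions)) {
        rg <- do.call(region_spec, as.list(config$regions[[i]]))
        int_sets[[rg$label]] <- extract_region(env$tom, env$surface, rg,
                                               seed = config$seed + i)
        att_sets[[rg$label]] <- extract_region(env$att, env$surface, rg,
                                               seed = config$seed + i)
      }
      f1 <- file.path(out, "region_samples.csv")
      df <- do.call(rbind, lapply(names(int_sets), function(lb) {
        data.frame(label = lb,
                   intensity = int_sets[[lb]]$values[
                     seq_len(min(int_sets[[lb]]$n, att_sets[[lb]]$n))],
                   attenuation = att_sets[[lb]]$values[
                     seq_len(min(int_sets[[lb]]$n, att_sets[[lb]]$n))])
      }))
      utils::write.csv(df, f1, row.names = FALSE)
      files <- c(files, f1)
      if (length(int_sets) >= 2) {
        tests_int <- compare_groups(int_sets, alpha = config$stats$alpha,
                                    transform = config$stats$transform)
        tests_att <- compare_groups(att_sets, alpha = config$stats$alpha)
        f2 <- file.path(out, "tests_intensity.csv")
        f3 <- file.path(out, "tests_attenuation.csv")
        utils::write.csv(tests_int, f2, row.names = FALSE)
        utils::write.csv(tests_att, f3, row.names = FALSE)
        files <- c(files, f2, f3)
      }
      files
    })
  }

  manifest <- structure(
    list(config_hash = config_hash(config),
         package_version = as.character(utils::packageVersion("specoct")),
         stages = stages,
         timestamp = format(Sys.time(), tz = "UTC")),
    class = "run_manifest"
  )
  jsonlite::write_json(unclass(manifest), file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("Pipeline run %s (%d stage(s) complete)\n",
              substr(x$config_hash, 1, 8), length(x$stages)))
  for (nm in names(x$stages)) {
    cat(sprintf("  %-14s %d file(s)\n", nm, length(x$stages[[nm]]$files)))
  }
  invisible(x)
}
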