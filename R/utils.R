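# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global random number generator seeded at `seed` and
#' restores the previous RNG state afterwards, so seeded operations do not
#' perturb the caller's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

assert_scalar_num <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stopf("`%s` must be a single finite number", name)
  }
  if (strict && x <= min) stopf("`%s` must be > %g", name, min)
  if (!strict && x < min) stopf("`%s` must be >= %g", name, min)
  invisible(x)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Decibel conversions for intensity data
#'
#' `to_db()` converts linear intensity to decibels (10 log10); `from_db()`
#' inverts it. Zero or negative intensities map to `-Inf` dB.
#'
#' @param x Intensity values (linear) or dB values.
#' @param ref Reference intensity for 0 dB (default 1).
#' @return Numeric vector of the same length.
#' @export
to_db <- function(x, ref = 1) 10 * log10(x / ref)

#' @rdname to_db
#' @export
from_db <- function(x, ref = 1) ref * 10^(x / 10)

# FWHM of a sampled peak by linear interpolation at the half-maximum
# crossings; x must be sorted ascending. Returns NA when the peak is not
# fully resolved inside the axis.
fwhm_of_peak <- function(x, y) {
  i <- which.max(y)
  half <- y[i] / 2
  left <- NA_real_
  right <- NA_real_
  if (i > 1) {
    j <- max(which(y[seq_len(i - 1)] <= half))
    if (length(j) && is.finite(j)) {
      left <- x[j] + (x[j + 1] - x[j]) * (half - y[j]) / (y[j + 1] - y[j])
    }
  }
  if (i < length(y)) {
    after <- y[seq(i + 1, length(y))]
    j <- which(after <= half)
    if (length(j)) {
      j <- i + j[1] - 1
      right <- x[j] + (x[j + 1] - x[j]) * (half - y[j]) / (y[j + 1] - y[j])
    }
  }
  right - left
}

# Running 2-D median filter with odd square window; NA entries are ignored.
median_filter2 <- function(m, size) {
  if (size <= 1) return(m)
  h <- floor(size / 2)
  nr <- nrow(m)
  nc <- ncol(m)
  out <- m
  for (j in seq_len(nc)) {
    jj <- max(1, j - h):min(nc, j + h)
    for (i in seq_len(nr)) {
      ii <- max(1, i - h):min(nr, i + h)
      v <- m[ii, jj]
      v <- v[!is.na(v)]
      if (length(v)) out[i, j] <- stats::median(v)
    }
  }
  out
}
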