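#' Locate the reactant ion peak of a spectrum
#'
#' The reactant ion peak (RIP) is the global intensity maximum of an IMS
#' spectrum. Its drift time is refined to sub-sample precision by fitting a
#' parabola through the apex sample and its two neighbours; when the apex
#' falls on the first or last axis point the raw sample position is
#' returned and flagged (`attr(,"boundary")`). Set `refine = FALSE` for the
#' plain argmax.
#'
#' @param spectrum a [drift_spectrum()].
#' @param refine logical; apply 3-point parabolic apex interpolation.
#' @return RIP drift time in milliseconds, with attribute `boundary`.
#' @export
find_rip <- function(spectrum, refine = TRUE) {
  stopifnot(inherits(spectrum, "drift_spectrum"))
  y <- spectrum$intensity
  x <- spectrum$drift_time_ms
  if (length(y) == 0) stopf("empty spectrum")
  if (all(y == 0)) stopf("all-zero spectrum: no reactant ion peak found")
  i <- which.max(y)
  boundary <- i == 1L || i == length(y)
  td <- x[i]
  if (refine && !boundary) {
    y0 <- y[i - 1]; y1 <- y[i]; y2 <- y[i + 1]
    denom <- y0 - 2 * y1 + y2
    if (denom < 0) { # proper concave apex
      delta <- 0.5 * (y0 - y2) / denom
      # local axis spacing (axis may be non-uniform)
      step <- if (delta >= 0) x[i + 1] - x[i] else x[i] - x[i - 1]
      td <- x[i] + delta * step
    }
  }
  structure(td, boundary = boundary)
}

#' Normalize a spectrum to relative drift time
#'
#' Divides the drift-time axis by the RIP drift time, so the RIP apex sits
#' at relative drift time 1 and instrumental factors (tube length, voltage,
#' temperature, pressure) cancel. Intensities are unchanged.
#'
#' @param spectrum a [drift_spectrum()].
#' @param rip_drift_time_ms RIP drift time in ms; located with [find_rip()]
#'   when omitted.
#' @return An object of class `normalized_spectrum`: list with `rel_axis`,
#'   `intensity`, `rip_drift_time_ms`, `timestamp_h`.
#' @export
normalize_spectrum <- function(spectrum, rip_drift_time_ms = find_rip(spectrum)) {
  stopifnot(inherits(spectrum, "drift_spectrum"))
  rip <- as.numeric(rip_drift_time_ms)
  if (!is.finite(rip) || rip <= 0) stopf("RIP drift time must be > 0")
  structure(list(
    rel_axis = spectrum$drift_time_ms / rip,
    intensity = spectrum$intensity,
    rip_drift_time_ms = rip,
    timestamp_h = spectrum$timestamp_h
  ), class = "normalized_spectrum")
}

#' @export
print.normalized_spectrum <- function(x, ...) {
  cat(sprintf("<normalized_spectrum> t = %.2f h, %d points, trel %.3f-%.3f (RIP %.3f ms)\n",
              x$timestamp_h, length(x$intensity), min(x$rel_axis),
              max(x$rel_axis), x$rip_drift_time_ms))
  invisible(x)
}

#' Estimate background noise and the limit of detection
#'
#' The background standard deviation is measured in a peak-free window of
#' the relative-drift-time axis (default 2.2--2.9, beyond all configured
#' peaks): the windowed trace is linearly detrended and the robust spread
#' of the residuals taken as the median absolute deviation scaled by 1.4826
#' (consistent for Gaussian noise and insensitive to a stray peak). The
#' limit of detection is defined as three times that background noise. The
#' window median is also returned as the local baseline level.
#'
#' @param nspec a [normalize_spectrum()] output.
#' @param window `c(trel_lo, trel_hi)` noise-estimation window; must lie
#'   after the RIP and contain at least `min_points` samples.
#' @param min_points minimum samples required in the window.
#' @return Object of class `noise_estimate`: `sigma`, `lod` (= 3 sigma),
#'   `baseline`, `window`, `n_points`.
#' @export
estimate_noise <- function(nspec, window = c(2.2, 2.9), min_points = 20) {
  stopifnot(inherits(nspec, "normalized_spectrum"))
  if (length(window) != 2 || window[1] >= window[2]) {
    stopf("window must be c(lo, hi) with lo < hi")
  }
  if (window[1] <= 1.05) {
    stopf("noise window [%g, %g] overlaps the reactant ion peak region (trel <= 1.05)",
          window[1], window[2])
  }
  idx <- which(nspec$rel_axis >= window[1] & nspec$rel_axis <= window[2])
  if (length(idx) < min_points) {
    stopf("noise window [%g, %g] contains %d samples (< %d) on this axis",
          window[1], window[2], length(idx), min_points)
  }
  x <- nspec$rel_axis[idx]
  y <- nspec$intensity[idx]
  fit <- lm.fit(cbind(1, x - mean(x)), y)
  res <- fit$residuals
  sigma <- mad(res)
  structure(list(
    sigma = sigma, lod = 3 * sigma,
    baseline = median(y), window = window, n_points = length(idx)
  ), class = "noise_estimate")
}

#' @export
print.noise_estimate <- function(x, ...) {
  cat(sprintf("<noise_estimate> sigma = %.4g, LOD = %.4g, baseline = %.4g (trel %.2f-%.2f, n = %d)\n",
              x$sigma, x$lod, x$baseline, x$window[1], x$window[2], x$n_points))
  invisible(x)
}

#' Default common relative-drift-time grid
#'
#' @param n number of grid points (default 1150, comfortably above the
#'   1000-point density of the instrument axis between 0.7 and 3).
#' @param range relative-drift-time span.
#' @return Numeric vector of grid points.
#' @export
default_rel_grid <- function(n = 1150, range = c(0.7, 3)) {
  seq(range[1], range[2], length.out = n)
}

#' Interpolate normalized spectra onto a common relative-drift-time grid
#'
#' Linear interpolation of each spectrum onto the shared grid. Grid points
#' outside a spectrum's axis range are set to 0 (blank regions carry no
#' signal) with a warning. Rows keep the time order of the input.
#'
#' @param nspecs list of [normalize_spectrum()] outputs.
#' @param grid common relative-drift-time grid (strictly increasing).
#' @return Numeric matrix (spectra x grid points) with attributes `grid`
#'   and `timestamps`.
#' @seealso [state_matrix()] for the RIP-masked view used by the state
#'   model.
#' @export
to_common_axis <- function(nspecs, grid = default_rel_grid()) {
  stopifnot(is.list(nspecs))
  if (length(grid) > 1 && any(diff(grid) <= 0)) {
    stopf("grid must be strictly increasing")
  }
  out_of_range <- FALSE
  rows <- lapply(nspecs, function(ns) {
    stopifnot(inherits(ns, "normalized_spectrum"))
    v <- approx(ns$rel_axis, ns$intensity, xout = grid)$y
    if (anyNA(v)) {
      out_of_range <<- TRUE
      v[is.na(v)] <- 0
    }
    v
  })
  if (out_of_range) {
    warning("grid points outside a spectrum's axis range were filled with 0")
  }
  mat <- if (length(rows)) do.call(rbind, rows) else
    matrix(numeric(0), nrow = 0, ncol = length(grid))
  attr(mat, "grid") <- grid
  attr(mat, "timestamps") <- vapply(nspecs, function(ns) ns$timestamp_h, numeric(1))
  mat
}

#' Mask the common-axis matrix to points after the reactant ion peak
#'
#' The state model uses all grid points after the RIP; this helper drops
#' columns at relative drift time at or below `rip_exclusion` (default 1.05,
#' just beyond the RIP tail).
#'
#' @param mat matrix from [to_common_axis()].
#' @param rip_exclusion relative-drift-time cutoff.
#' @return The column-subset matrix, `grid`/`timestamps` attributes updated.
#' @export
state_matrix <- function(mat, rip_exclusion = 1.05) {
  grid <- attr(mat, "grid")
  if (is.null(grid)) stopf("matrix lacks a `grid` attribute; use to_common_axis()")
  keep <- grid > rip_exclusion
  out <- mat[, keep, drop = FALSE]
  attr(out, "grid") <- grid[keep]
  attr(out, "timestamps") <- attr(mat, "timestamps")
  out
}

#' Normalize and grid a whole spectrum series
#'
#' Convenience wrapper running [find_rip()], [normalize_spectrum()],
#' [estimate_noise()] and [to_common_axis()] over a series.
#'
#' @param series a [spectrum_series()].
#' @param grid common relative-drift-time grid.
#' @param noise_window noise-estimation window passed to [estimate_noise()].
#' @return List: `matrix` (spectra x grid), `grid`, `timestamps`,
#'   `normalized` (list of normalized spectra), `noise` (list of
#'   per-spectrum noise estimates), `rip_ms` (per-spectrum RIP drift time).
#' @export
preprocess_series <- function(series, grid = default_rel_grid(),
                              noise_window = c(2.2, 2.9)) {
  stopifnot(inherits(series, "spectrum_series"))
  nspecs <- lapply(series$spectra, function(s) normalize_spectrum(s))
  noise <- lapply(nspecs, estimate_noise, window = noise_window)
  mat <- to_common_axis(nspecs, grid)
  list(matrix = mat, grid = attr(mat, "grid"),
       timestamps = attr(mat, "timestamps"),
       normalized = nspecs, noise = noise,
       rip_ms = vapply(nspecs, function(n) n$rip_drift_time_ms, numeric(1)))
}
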