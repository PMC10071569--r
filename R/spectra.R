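#' A single drift-time IMS spectrum
#'
#' One intensity trace over a strictly increasing drift-time axis, tagged
#' with the acquisition time (hours from inoculation) and the instrument it
#' was recorded on.
#'
#' @param drift_time_ms numeric vector, drift-time axis in milliseconds,
#'   strictly increasing.
#' @param intensity numeric vector of intensities (arbitrary units), same
#'   length as the axis.
#' @param timestamp_h acquisition time in hours from inoculation.
#' @param instrument an [instrument_config()].
#' @param label optional free-text label.
#' @return An object of class `drift_spectrum`.
#' @export
drift_spectrum <- function(drift_time_ms, intensity, timestamp_h = 0,
                           instrument = instrument_config(), label = NULL) {
  if (length(drift_time_ms) != length(intensity)) {
    stopf("axis and intensity lengths differ (%d vs %d)",
          length(drift_time_ms), length(intensity))
  }
  if (length(drift_time_ms) > 1 && any(diff(drift_time_ms) <= 0)) {
    stopf("drift-time axis must be strictly increasing")
  }
  if (anyNA(drift_time_ms) || anyNA(intensity)) {
    stopf("NA values in axis or intensity")
  }
  check_number(timestamp_h, "timestamp_h")
  stopifnot(inherits(instrument, "instrument_config"))
  structure(list(
    drift_time_ms = as.numeric(drift_time_ms),
    intensity = as.numeric(intensity),
    timestamp_h = as.numeric(timestamp_h),
    instrument = instrument,
    label = label
  ), class = "drift_spectrum")
}

#' @export
print.drift_spectrum <- function(x, ...) {
  cat(sprintf("<drift_spectrum> t = %.2f h, %d points, axis %.3f-%.3f ms, max %.3g\n",
              x$timestamp_h, length(x$intensity),
              min(x$drift_time_ms), max(x$drift_time_ms), max(x$intensity)))
  invisible(x)
}

#' A time-ordered series of drift spectra
#'
#' @param spectra list of [drift_spectrum()] objects with non-decreasing
#'   timestamps.
#' @param common_axis logical: do all spectra share one drift-time axis?
#'   Determined automatically when `NULL`.
#' @return An object of class `spectrum_series`.
#' @export
spectrum_series <- function(spectra, common_axis = NULL) {
  stopifnot(is.list(spectra))
  for (s in spectra) stopifnot(inherits(s, "drift_spectrum"))
  ts <- vapply(spectra, function(s) s$timestamp_h, numeric(1))
  if (length(ts) > 1 && any(diff(ts) < 0)) {
    stopf("spectrum timestamps must be non-decreasing")
  }
  if (is.null(common_axis)) {
    common_axis <- length(spectra) <= 1 ||
      all(vapply(spectra[-1], function(s) {
        identical(s$drift_time_ms, spectra[[1]]$drift_time_ms)
      }, logical(1)))
  }
  structure(list(spectra = spectra, common_axis = common_axis),
            class = "spectrum_series")
}

#' @export
length.spectrum_series <- function(x) length(x$spectra)

#' @export
print.spectrum_series <- function(x, ...) {
  n <- length(x$spectra)
  if (n == 0) {
    cat("<spectrum_series> empty\n")
  } else {
    ts <- vapply(x$spectra, function(s) s$timestamp_h, numeric(1))
    cat(sprintf("<spectrum_series> %d spectra, t = %.2f-%.2f h, common axis: %s\n",
                n, min(ts), max(ts), x$common_axis))
  }
  invisible(x)
}

series_timestamps <- function(series) {
  vapply(series$spectra, function(s) s$timestamp_h, numeric(1))
}

#' Write / read a spectrum series (CSV matrix + JSON metadata sidecar)
#'
#' The on-disk format is a directory containing `spectra.csv` — a matrix
#' whose first row is the drift-time axis (ms) and whose subsequent rows are
#' one spectrum each, first column the timestamp in hours — and
#' `instrument.json` holding the instrument metadata and per-spectrum
#' labels. The round trip preserves all numeric fields to IEEE double
#' precision (values are serialized with 17 significant digits).
#'
#' `write_series()` requires a common axis across spectra; an empty series
#' writes a header-only file and reads back empty.
#'
#' @param series a [spectrum_series()] on a common drift-time axis.
#' @param path directory to create/fill (write) or read from.
#' @return `write_series()` returns `path` invisibly; `read_series()`
#'   returns a [spectrum_series()].
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "spectrum_series"))
  n <- length(series$spectra)
  if (n > 0 && !series$common_axis) {
    stopf("write_series requires spectra on a common drift-time axis")
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(path, "spectra.csv")
  if (n == 0) {
    writeLines("timestamp_h", csv)
    inst <- instrument_config()
    labels <- character(0)
  } else {
    axis <- series$spectra[[1]]$drift_time_ms
    mat <- t(vapply(series$spectra, function(s) s$intensity, numeric(length(axis))))
    ts <- series_timestamps(series)
    out <- rbind(c(NA_real_, axis), cbind(ts, mat))
    dt <- data.table::as.data.table(out)
    data.table::setnames(dt, c("timestamp_h", sprintf("p%04d", seq_along(axis))))
    data.table::fwrite(dt, csv, na = "", scipen = 999)
    inst <- series$spectra[[1]]$instrument
    labels <- vapply(series$spectra, function(s) {
      if (is.null(s$label)) "" else as.character(s$label)
    }, character(1))
  }
  meta <- list(
    format = "driftwatch-series",
    version = 1L,
    n_spectra = n,
    instrument = unclass(inst),
    labels = labels
  )
  jsonlite::write_json(meta, file.path(path, "instrument.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  csv <- file.path(path, "spectra.csv")
  metaf <- file.path(path, "instrument.json")
  if (!file.exists(csv)) stopf("series file not found: %s", csv)
  if (!file.exists(metaf)) stopf("metadata sidecar not found: %s", metaf)
  meta <- jsonlite::read_json(metaf, simplifyVector = TRUE)
  if (!identical(meta$format, "driftwatch-series")) {
    stopf("%s: not a driftwatch series (format field = %s)",
          metaf, deparse(meta$format))
  }
  inst <- do.call(instrument_config, meta$instrument[
    setdiff(names(meta$instrument), "field_V_per_m")
  ])
  dt <- data.table::fread(csv, header = TRUE)
  if (nrow(dt) == 0) return(spectrum_series(list()))
  m <- as.matrix(dt)
  axis <- as.numeric(m[1, -1])
  if (anyNA(axis)) stopf("%s: malformed axis row (row 1): NA values", csv)
  if (length(axis) > 1 && any(diff(axis) <= 0)) {
    bad <- which(diff(axis) <= 0)[1]
    stopf("%s: drift-time axis not strictly increasing at column %d", csv, bad + 1L)
  }
  body <- m[-1, , drop = FALSE]
  labels <- meta$labels
  spectra <- lapply(seq_len(nrow(body)), function(i) {
    row <- as.numeric(body[i, ])
    if (anyNA(row)) {
      stopf("%s: NA intensity/timestamp in spectrum row %d (file line %d)",
            csv, i, i + 2L)
    }
    lab <- if (length(labels) >= i && nzchar(labels[i])) labels[i] else NULL
    drift_spectrum(axis, row[-1], timestamp_h = row[1],
                   instrument = inst, label = lab)
  })
  spectrum_series(spectra, common_axis = TRUE)
}
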