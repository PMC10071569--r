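#' Default principal-component sign anchors
#'
#' PCA loadings are defined only up to sign; to make the state model fully
#' deterministic and its scores interpretable, each component is anchored
#' to a labelled peak: PC1 so the growth-marker peak d contributes
#' positively (scores rise with cell concentration), PC2 so the
#' death-marker peak g contributes positively (scores rise as the culture
#' declines), PC3 so the over-illumination marker peak f contributes
#' negatively (scores fall below the shading threshold under intense
#' light). PC4 keeps a neutral convention (largest-magnitude loading
#' element positive).
#'
#' @return List of anchors, each `list(pc, label, sign)`.
#' @export
default_sign_anchors <- function() {
  list(list(pc = 1L, label = "d", sign = 1),
       list(pc = 2L, label = "g", sign = 1),
       list(pc = 3L, label = "f", sign = -1))
}

#' Fit the standard-scaled four-component PCA state model
#'
#' Every grid column (relative drift times after the reactant ion peak) is
#' centered and scaled to unit variance, and the top principal-component
#' loadings of the scaled training matrix are extracted by singular value
#' decomposition. The few thousand intensity values per spectrum are thereby
#' reduced to four state coordinates. Zero-variance columns are scaled by 1
#' (not dropped) and recorded. Loading signs are fixed by the per-peak
#' contribution anchors (see [default_sign_anchors()]), so two fits of the
#' same matrix return identical loadings, not merely identical up to sign.
#'
#' @param mat training matrix (spectra x grid) from [state_matrix()];
#'   needs a `grid` attribute and at least `n_components + 1` rows.
#' @param peaks a [peak_defs()] table (used to locate anchor peaks).
#' @param n_components number of components retained (default 4).
#' @param anchors sign anchors; see [default_sign_anchors()].
#' @return Object of class `state_model`: `grid`, `center`, `scale`,
#'   `loadings` (grid x components), `explained_variance_ratio`,
#'   `sign_anchors`, `peaks`, `zero_variance_cols`, `n_train`.
#' @export
fit_state_model <- function(mat, peaks = default_peak_defs(),
                            n_components = 4,
                            anchors = default_sign_anchors()) {
  grid <- attr(mat, "grid")
  if (is.null(grid)) stopf("training matrix lacks a `grid` attribute")
  n <- nrow(mat)
  if (n <= n_components) {
    stopf("need more spectra (%d) than components (%d)", n, n_components)
  }
  if (n < 5) stopf("need at least 5 training spectra")
  if (anyNA(mat)) stopf("NA values in training matrix")
  mu <- colMeans(mat)
  s <- apply(mat, 2, sd)
  zero_var <- which(s == 0)
  s[zero_var] <- 1
  Xs <- sweep(sweep(mat, 2, mu), 2, s, "/")
  sv <- svd(Xs, nu = 0, nv = n_components)
  loadings <- sv$v
  evr <- (sv$d^2 / sum(sv$d^2))[seq_len(n_components)]
  # sign anchoring: flip each component so the anchored peak's aggregate
  # contribution (loading x training mean intensity, summed over +-3 sigma
  # of the peak center) has the required sign
  for (k in seq_len(n_components)) {
    anc <- Filter(function(a) a$pc == k, anchors)
    flipped <- FALSE
    if (length(anc)) {
      a <- anc[[1]]
      row <- match(a$label, peaks$label)
      if (!is.na(row)) {
        idx <- which(abs(grid - peaks$center[row]) <= 3 * peaks$width_sigma[row])
        agg <- sum(loadings[idx, k] * mu[idx])
        if (agg != 0) {
          if (sign(agg) != sign(a$sign)) loadings[, k] <- -loadings[, k]
          flipped <- TRUE
        }
      }
    }
    if (!flipped) { # neutral deterministic convention
      j <- which.max(abs(loadings[, k]))
      if (loadings[j, k] < 0) loadings[, k] <- -loadings[, k]
    }
  }
  structure(list(
    grid = grid, center = mu, scale = s, loadings = loadings,
    explained_variance_ratio = evr, sign_anchors = anchors,
    peaks = peaks, zero_variance_cols = zero_var, n_train = n
  ), class = "state_model")
}

#' @export
print.state_model <- function(x, ...) {
  cat(sprintf("<state_model> %d grid points, %d components, fitted on %d spectra\n",
              length(x$grid), ncol(x$loadings), x$n_train))
  cat(sprintf("  explained variance: %s\n",
              paste(sprintf("PC%d %.1f%%", seq_along(x$explained_variance_ratio),
                            100 * x$explained_variance_ratio), collapse = ", ")))
  invisible(x)
}

#' Project spectra onto the state model
#'
#' Centers and scales new spectra with the training statistics and projects
#' them on the anchored loadings, yielding one score per component per
#' spectrum. Deterministic; the training-set scores have diagonal
#' covariance.
#'
#' @param mat matrix (spectra x grid) on the model grid, or a single
#'   numeric vector of grid intensities.
#' @param model a [fit_state_model()] result.
#' @return Numeric matrix (spectra x components) with columns `PC1`... and,
#'   when present on the input, a `timestamps` attribute.
#' @export
transform_scores <- function(mat, model) {
  stopifnot(inherits(model, "state_model"))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1)
  grid <- attr(mat, "grid")
  if (!is.null(grid) && !isTRUE(all.equal(grid, model$grid))) {
    stopf("grid mismatch: input grid differs from the model grid (%d vs %d points)",
          length(grid), length(model$grid))
  }
  if (ncol(mat) != length(model$grid)) {
    stopf("grid mismatch: input has %d columns, model expects %d",
          ncol(mat), length(model$grid))
  }
  Xs <- sweep(sweep(mat, 2, model$center), 2, model$scale, "/")
  scores <- Xs %*% model$loadings
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  ts <- attr(mat, "timestamps")
  if (!is.null(ts)) attr(scores, "timestamps") <- ts
  scores
}

#' Per-peak contributions to the principal-component scores
#'
#' Multiplies each loading vector elementwise with the mean spectrum
#' intensity at every grid point and aggregates the products over a
#' +-3 sigma window around each labelled peak center, quantifying how much
#' each peak drives each component's score.
#'
#' @param model a [fit_state_model()] result.
#' @param peaks a [peak_defs()] table; defaults to the model's own.
#' @param mean_intensities mean intensity per grid point; defaults to the
#'   training column means.
#' @return List: `pointwise` (grid x components matrix of loading x mean
#'   intensity) and `per_peak` (labels x components aggregate matrix).
#' @export
peak_contributions <- function(model, peaks = model$peaks,
                               mean_intensities = model$center) {
  stopifnot(inherits(model, "state_model"))
  if (length(mean_intensities) != length(model$grid)) {
    stopf("grid mismatch: mean_intensities has %d values, model grid %d",
          length(mean_intensities), length(model$grid))
  }
  pw <- model$loadings * mean_intensities
  colnames(pw) <- paste0("PC", seq_len(ncol(pw)))
  per_peak <- t(vapply(seq_len(nrow(peaks)), function(k) {
    idx <- which(abs(model$grid - peaks$center[k]) <= 3 * peaks$width_sigma[k])
    colSums(pw[idx, , drop = FALSE])
  }, numeric(ncol(pw))))
  rownames(per_peak) <- peaks$label
  list(pointwise = pw, per_peak = per_peak)
}
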