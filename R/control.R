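#' Thresholds of the process-control rule engine
#'
#' Score trends are trailing-window least-squares slopes in score units per
#' hour. The shading threshold (PC3 < -5) is the published rule; every
#' other default is a tunable calibrated once on the default simulator and
#' documented in the methods vignette.
#'
#' @param pc1_rise_min minimum PC1 slope (per hour) that counts as growth.
#' @param pc1_plateau_band the PC1 plateau test: the trailing slope of the
#'   running maximum of PC1, over `plateau_window` spectra, must fall below
#'   this value (per hour) for PC1 to count as at its maximum. The running
#'   maximum rather than PC1 itself is used so the nightly dips of the
#'   growth peaks do not read as a plateau.
#' @param pc2_rise_min PC2 slope (per hour) above which the culture counts
#'   as declining.
#' @param pc2_negative_limit PC2 level below which the system state is
#'   unknown (user must check the system).
#' @param pc3_shade_limit PC3 level below which the culture must be shaded
#'   (default -5); must be negative.
#' @param window number of consecutive spectra in the trend window (>= 2);
#'   default 12 spectra = 2 h at the 10-min acquisition interval.
#' @param plateau_window spectra in the PC1 running-maximum trend window;
#'   default 36 spectra = 6 h.
#' @param pc1_max_margin PC1 may be this far below its running maximum and
#'   still count as "at maximum".
#' @param pc1_total_rise_min total PC1 rise that must have been observed
#'   before a plateau is read as maximum cell concentration.
#' @param cde_drop_min slope (intensity units per hour) of the mean
#'   growth-peak (c--e) apex series below which a day/night dip is read.
#' @return List of class `control_thresholds`.
#' @export
control_thresholds <- function(pc1_rise_min = 0.2,
                               pc1_plateau_band = 0.15,
                               pc2_rise_min = 0.25,
                               pc2_negative_limit = -20,
                               pc3_shade_limit = -5,
                               window = 12,
                               plateau_window = 36,
                               pc1_max_margin = 5,
                               pc1_total_rise_min = 10,
                               cde_drop_min = -2) {
  if (window < 2) stopf("window must be >= 2 spectra")
  if (plateau_window < 2) stopf("plateau_window must be >= 2 spectra")
  if (pc3_shade_limit >= 0) stopf("pc3_shade_limit must be negative")
  structure(list(
    pc1_rise_min = pc1_rise_min, pc1_plateau_band = pc1_plateau_band,
    pc2_rise_min = pc2_rise_min, pc2_negative_limit = pc2_negative_limit,
    pc3_shade_limit = pc3_shade_limit, window = as.integer(window),
    plateau_window = as.integer(plateau_window),
    pc1_max_margin = pc1_max_margin,
    pc1_total_rise_min = pc1_total_rise_min,
    cde_drop_min = cde_drop_min
  ), class = "control_thresholds")
}

#' Map a PC-score trajectory to process-control recommendations
#'
#' Applies the rule set, one recommendation per time point, with
#' safety-first precedence `SHADE > CHECK_SYSTEM >
#' HARVEST_OR_CHECK_CONTAMINATION > HARVEST_OR_FEED > DAY_NIGHT_DIP >
#' CONTINUE`:
#'
#' * `SHADE` — PC3 below the shading limit (over-illumination);
#' * `CHECK_SYSTEM` — PC2 strongly negative (unknown system status);
#' * `HARVEST_OR_CHECK_CONTAMINATION` — PC2 rising while PC1 has fallen
#'   from its running maximum: both markers of a decreasing cell
#'   concentration;
#' * `HARVEST_OR_FEED` — PC1 has risen, now sits near its running maximum
#'   with a flat running-maximum trend while PC2 is not rising (maximum
#'   cell concentration);
#' * `DAY_NIGHT_DIP` — the growth-linked peaks c--e drop with no novel peak
#'   present (normal dark-phase behaviour, no action needed);
#' * `CONTINUE` — otherwise (in particular while PC1 rises and PC2 stays
#'   flat, i.e. undisturbed growth).
#'
#' When a peak table is supplied, the two harvest rules additionally
#' require the death-marker peak g to be above the limit of detection at
#' that time: g appears at stationary onset and its presence above the LOD
#' marks that the culture has reached maximum cell concentration, so
#' transient PC trends before that point (light/dark transitions in
#' particular) are not misread as a harvest condition.
#'
#' The classification at time *i* uses only data up to *i* (trailing
#' trends, running maxima), so batch evaluation and one-spectrum-at-a-time
#' streaming give identical results. The first `window - 1` points carry
#' the status `INSUFFICIENT_DATA`.
#'
#' @param scores matrix from [transform_scores()] (needs >= 3 columns and a
#'   `timestamps` attribute, or pass `timestamps`).
#' @param thresholds a [control_thresholds()].
#' @param peak_table optional [extract_time_series()] result; enables the
#'   day/night-dip rule via the c--e apex series.
#' @param novel optional logical vector per time point
#'   ([novel_peak_flags()]); novel peaks veto the day/night-dip reading.
#' @param timestamps hours per score row (defaults to the attribute).
#' @return `data.frame` of class `recommendations`: `time_h`, `action`,
#'   `triggering_rule`, and the score snapshot columns `PC1`...
#' @export
classify_scores <- function(scores, thresholds = control_thresholds(),
                            peak_table = NULL, novel = NULL,
                            timestamps = attr(scores, "timestamps")) {
  stopifnot(inherits(thresholds, "control_thresholds"))
  if (is.null(dim(scores)) || ncol(scores) < 3) {
    stopf("scores must be a matrix with at least 3 components")
  }
  n <- nrow(scores)
  if (n == 0) stopf("empty score trajectory")
  if (is.null(timestamps)) timestamps <- seq_len(n)
  if (length(timestamps) != n) stopf("timestamps length does not match scores")
  w <- thresholds$window
  pc1 <- scores[, 1]; pc2 <- scores[, 2]; pc3 <- scores[, 3]
  s1 <- trailing_slope(timestamps, pc1, w)
  s2 <- trailing_slope(timestamps, pc2, w)
  run_max1 <- cummax(pc1)
  plateau_slope <- trailing_slope(timestamps, run_max1,
                                  thresholds$plateau_window)
  growth_seen <- (run_max1 - pc1[1]) >= thresholds$pc1_total_rise_min
  g_present <- rep(TRUE, n)
  if (!is.null(peak_table) && "g" %in% peak_table$label) {
    gt <- peak_table[peak_table$label == "g", , drop = FALSE]
    flag <- !gt$below_lod[match(round(timestamps, 9), round(gt$time_h, 9))]
    g_present <- ifelse(is.na(flag), TRUE, flag)
  }
  cde_slope <- rep(NA_real_, n)
  if (!is.null(peak_table)) {
    cde <- peak_table[peak_table$label %in% c("c", "d", "e"), , drop = FALSE]
    if (nrow(cde) > 0) {
      agg <- tapply(cde$apex_intensity, cde$time_h, mean)
      cde_t <- as.numeric(names(agg))
      cde_y <- as.numeric(agg)
      sl <- trailing_slope(cde_t, cde_y, w)
      cde_slope <- sl[match(round(timestamps, 9), round(cde_t, 9))]
    }
  }
  if (is.null(novel)) novel <- rep(FALSE, n)
  action <- character(n)
  rule <- character(n)
  for (i in seq_len(n)) {
    if (i < w) {
      action[i] <- "INSUFFICIENT_DATA"
      rule[i] <- sprintf("fewer than %d spectra in trend window", w)
    } else if (pc3[i] < thresholds$pc3_shade_limit) {
      action[i] <- "SHADE"
      rule[i] <- sprintf("PC3 = %.2f < %.2f (over-illumination)",
                         pc3[i], thresholds$pc3_shade_limit)
    } else if (pc2[i] < thresholds$pc2_negative_limit) {
      action[i] <- "CHECK_SYSTEM"
      rule[i] <- sprintf("PC2 = %.2f < %.2f (unknown system status)",
                         pc2[i], thresholds$pc2_negative_limit)
    } else if (g_present[i] && s2[i] > thresholds$pc2_rise_min &&
               pc1[i] < run_max1[i] - thresholds$pc1_max_margin) {
      action[i] <- "HARVEST_OR_CHECK_CONTAMINATION"
      rule[i] <- sprintf("PC2 slope %.2f/h > %.2f/h (cell concentration decreasing)",
                         s2[i], thresholds$pc2_rise_min)
    } else if (g_present[i] && growth_seen[i] &&
               pc1[i] >= run_max1[i] - thresholds$pc1_max_margin &&
               !is.na(plateau_slope[i]) &&
               plateau_slope[i] <= thresholds$pc1_plateau_band &&
               s2[i] <= thresholds$pc2_rise_min) {
      action[i] <- "HARVEST_OR_FEED"
      rule[i] <- "PC1 at maximum, PC2 constant (maximum cell concentration)"
    } else if (!is.na(cde_slope[i]) && cde_slope[i] < thresholds$cde_drop_min &&
               !isTRUE(novel[i])) {
      action[i] <- "DAY_NIGHT_DIP"
      rule[i] <- "growth peaks c-e dropping, no novel peaks (day/night cycle)"
    } else {
      action[i] <- "CONTINUE"
      rule[i] <- if (s1[i] > thresholds$pc1_rise_min &&
                     abs(s2[i]) <= thresholds$pc2_rise_min) {
        "PC1 rising, PC2 constant (culture growing)"
      } else {
        "no rule fired"
      }
    }
  }
  out <- data.frame(time_h = timestamps, action = action,
                    triggering_rule = rule, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(scores))
  rownames(out) <- NULL
  class(out) <- c("recommendations", "data.frame")
  out
}

#' Convert OD750 to biomass dry weight
#'
#' The linear calibration \eqn{c_x [g/L] = 0.86 \cdot OD_{750}}.
#'
#' @param od750 optical density at 750 nm (>= 0, vectorized).
#' @return Dry weight in grams per litre.
#' @export
od_to_dryweight <- function(od750) {
  if (any(od750 < 0, na.rm = TRUE)) stopf("od750 must be >= 0")
  0.86 * od750
}

#' Linear correlation of a peak-intensity series with OD750
#'
#' Interpolates the peak time series to the offline OD sampling times,
#' restricts to the growth phase (times up to the OD maximum) and fits the
#' ordinary least-squares line intensity ~ OD750.
#'
#' @param peak_series `data.frame` with `time_h` and `intensity`.
#' @param od_samples `data.frame` from [sample_offline_od()] (`time_h`,
#'   `od750_mean`).
#' @param growth_only restrict to timestamps at or before the OD maximum.
#' @return List: `slope`, `intercept`, `r_squared`, `n`.
#' @export
correlate_peak_with_od <- function(peak_series, od_samples,
                                   growth_only = TRUE) {
  stopifnot(all(c("time_h", "intensity") %in% names(peak_series)),
            all(c("time_h", "od750_mean") %in% names(od_samples)))
  od <- od_samples
  if (growth_only) {
    t_max <- od$time_h[which.max(od$od750_mean)]
    od <- od[od$time_h <= t_max, , drop = FALSE]
  }
  span <- range(peak_series$time_h)
  od <- od[od$time_h >= span[1] & od$time_h <= span[2], , drop = FALSE]
  if (nrow(od) < 3) stopf("need >= 3 OD samples within the peak-series time span")
  y <- approx(peak_series$time_h, peak_series$intensity, xout = od$time_h)$y
  if (sd(y) == 0 || sd(od$od750_mean) == 0) {
    stopf("degenerate (constant) series: R^2 undefined")
  }
  fit <- lm(y ~ od$od750_mean)
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = r2, n = nrow(od))
}

#' Significance of peak-intensity changes between cultivation phases
#'
#' For each labelled peak, tests whether the intensities inside a phase
#' window differ from those at the start of the experiment with a
#' two-sample two-sided t test (Welch, unequal variances).
#'
#' @param peak_table a [extract_time_series()] result.
#' @param baseline_window `c(t0, t1)` hours defining the start-of-run
#'   reference window.
#' @param phase_window `c(t0, t1)` hours defining the phase under test.
#' @param value one of `"apex_intensity"`, `"fitted_amplitude"`.
#' @return `data.frame`: `label`, `t_statistic`, `p_value`,
#'   `mean_baseline`, `mean_phase`.
#' @export
growth_phase_significance <- function(peak_table, baseline_window,
                                      phase_window,
                                      value = c("apex_intensity",
                                                "fitted_amplitude")) {
  value <- match.arg(value)
  labs <- unique(peak_table$label)
  rows <- lapply(labs, function(lb) {
    sub <- peak_table[peak_table$label == lb, , drop = FALSE]
    b <- sub[[value]][sub$time_h >= baseline_window[1] &
                      sub$time_h <= baseline_window[2]]
    p <- sub[[value]][sub$time_h >= phase_window[1] &
                      sub$time_h <= phase_window[2]]
    if (length(b) < 2 || length(p) < 2) {
      stopf("peak %s: each window needs >= 2 points (got %d and %d)",
            lb, length(b), length(p))
    }
    if (var(b) == 0 && var(p) == 0) {
      if (mean(b) == mean(p)) {
        return(data.frame(label = lb, t_statistic = 0, p_value = 1,
                          mean_baseline = mean(b), mean_phase = mean(p)))
      }
      stopf("peak %s: zero variance in both windows with unequal means", lb)
    }
    tt <- t.test(p, b, var.equal = FALSE)
    data.frame(label = lb, t_statistic = unname(tt$statistic),
               p_value = tt$p.value, mean_baseline = mean(b),
               mean_phase = mean(p), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
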