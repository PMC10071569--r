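#' Default peak definitions for a species
#'
#' The seven characteristic headspace VOC peaks of a *Limnospira platensis*
#' (Spirulina) culture, labelled `a`--`g`, lie between relative drift times
#' 1.2 and 1.6; *Chlorella vulgaris* emits a distinct pattern whose major
#' peaks all sit below 1.2. Centers are placed evenly in those ranges (the
#' instrument literature reports the ranges, not numeric centers) and widths
#' default to 0.015 relative-drift-time units; both are configurable.
#'
#' @param species `"spirulina"` or `"chlorella"`.
#' @param width_sigma Gaussian sigma of every peak, in relative drift time.
#' @return A `data.frame` with columns `label`, `center`, `width_sigma`
#'   (class `peak_defs`).
#' @export
default_peak_defs <- function(species = c("spirulina", "chlorella"),
                              width_sigma = 0.015) {
  species <- match.arg(species)
  if (species == "spirulina") {
    peak_defs(labels = letters[1:7],
              centers = seq(1.2, 1.6, length.out = 7),
              width_sigma = width_sigma)
  } else {
    peak_defs(labels = paste0("p", 1:5),
              centers = seq(0.92, 1.15, length.out = 5),
              width_sigma = width_sigma)
  }
}

#' Construct a set of labelled peak definitions
#'
#' @param labels character vector of unique peak labels.
#' @param centers peak centers in relative drift time, unique.
#' @param width_sigma Gaussian sigma per peak (recycled), > 0.
#' @return `data.frame` of class `peak_defs`.
#' @export
peak_defs <- function(labels, centers, width_sigma = 0.015) {
  if (length(labels) != length(centers)) stopf("labels and centers differ in length")
  if (anyDuplicated(labels)) stopf("duplicate peak labels")
  if (anyDuplicated(centers)) stopf("duplicate peak centers")
  ws <- rep_len(width_sigma, length(labels))
  if (any(ws <= 0)) stopf("width_sigma must be > 0")
  structure(
    data.frame(label = as.character(labels), center = as.numeric(centers),
               width_sigma = ws, stringsAsFactors = FALSE),
    class = c("peak_defs", "data.frame")
  )
}

#' Configuration of a simulated microalgae cultivation
#'
#' Encodes the culture-level ground truth the spectrum simulator renders:
#' logistic growth in OD750 from the inoculation density to a carrying
#' capacity, a short stationary phase, exponential decline after the death
#' onset, a daily illumination schedule and optional illumination step
#' changes (e.g. the 60% -> 200% over-illumination experiment).
#'
#' @param initial_od inoculation OD750 (default 0.11).
#' @param growth_rate specific logistic growth rate, per hour.
#' @param carrying_capacity_od OD750 carrying capacity.
#' @param death_onset_day day at which cell death begins.
#' @param death_rate first-order decline rate after death onset, per hour.
#' @param light_schedule list of `c(on_hour, off_hour)` pairs per day;
#'   default one 16 h-on / 8 h-off block.
#' @param illumination_level illumination as a fraction of the reference
#'   level (1.0 = the standard cultures).
#' @param illumination_steps optional `data.frame(time_h, level)` of step
#'   changes applied at the given times.
#' @param illumination_saturation growth saturates above this illumination
#'   multiple: the effective growth rate is
#'   `growth_rate * min(illumination, illumination_saturation)`.
#' @param stationary_od_fraction OD fraction of the carrying capacity at
#'   which the culture is labelled stationary.
#' @param dark_attenuation multiplicative attenuation of the growth-linked
#'   emission peaks (c, d, e) while the light is off.
#' @param f_threshold illumination level above which the over-illumination
#'   marker peak `f` is emitted.
#' @param g_rise_scale decline-fraction scale of the death-marker peak g:
#'   its amplitude follows `1 - exp(-(1 - OD/K)/g_rise_scale)` from
#'   stationary onset, i.e. it rises sharply once maximum cell
#'   concentration is reached and keeps rising as the culture declines.
#' @param species `"spirulina"` or `"chlorella"`.
#' @param duration_days simulated cultivation length in days.
#' @param sample_interval_min spectrum sampling interval in minutes
#'   (default 10, one spectrum per stored instrument acquisition).
#' @param seed integer seed for all measurement noise.
#' @return A list of class `cultivation_config`.
#' @export
cultivation_config <- function(initial_od = 0.11,
                               growth_rate = 0.042,
                               carrying_capacity_od = 1.0,
                               death_onset_day = 5.5,
                               death_rate = 0.01,
                               light_schedule = list(c(0, 16)),
                               illumination_level = 1.0,
                               illumination_steps = NULL,
                               illumination_saturation = 1.5,
                               stationary_od_fraction = 0.95,
                               dark_attenuation = 0.4,
                               f_threshold = 1.5,
                               g_rise_scale = 0.15,
                               species = c("spirulina", "chlorella"),
                               duration_days = 8,
                               sample_interval_min = 10,
                               seed = 1L) {
  species <- match.arg(species)
  check_number(initial_od, "initial_od", positive = TRUE)
  check_number(growth_rate, "growth_rate", nonneg = TRUE)
  check_number(carrying_capacity_od, "carrying_capacity_od", positive = TRUE)
  if (carrying_capacity_od <= initial_od) {
    stopf("carrying_capacity_od (%g) must exceed initial_od (%g)",
          carrying_capacity_od, initial_od)
  }
  check_number(death_onset_day, "death_onset_day", nonneg = TRUE)
  check_number(death_rate, "death_rate", nonneg = TRUE)
  check_number(illumination_level, "illumination_level", nonneg = TRUE)
  check_number(duration_days, "duration_days", nonneg = TRUE)
  check_number(sample_interval_min, "sample_interval_min")
  if (sample_interval_min <= 0) stopf("sample_interval_min must be > 0")
  check_number(dark_attenuation, "dark_attenuation", nonneg = TRUE)
  stopifnot(is.list(light_schedule))
  for (blk in light_schedule) {
    if (length(blk) != 2 || any(blk < 0) || any(blk > 24) || blk[1] >= blk[2]) {
      stopf("light_schedule entries must be c(on_hour, off_hour) with 0 <= on < off <= 24")
    }
  }
  if (!is.null(illumination_steps)) {
    stopifnot(is.data.frame(illumination_steps),
              all(c("time_h", "level") %in% names(illumination_steps)))
    if (any(illumination_steps$level < 0)) stopf("illumination step levels must be >= 0")
  }
  structure(list(
    initial_od = initial_od, growth_rate = growth_rate,
    carrying_capacity_od = carrying_capacity_od,
    death_onset_day = death_onset_day, death_rate = death_rate,
    light_schedule = light_schedule,
    illumination_level = illumination_level,
    illumination_steps = illumination_steps,
    illumination_saturation = illumination_saturation,
    stationary_od_fraction = stationary_od_fraction,
    dark_attenuation = dark_attenuation,
    f_threshold = f_threshold,
    g_rise_scale = g_rise_scale,
    species = species, duration_days = duration_days,
    sample_interval_min = sample_interval_min,
    seed = as.integer(seed)
  ), class = "cultivation_config")
}

light_is_on <- function(time_h, schedule) {
  h <- time_h %% 24
  on <- rep(FALSE, length(h))
  for (blk in schedule) on <- on | (h >= blk[1] & h < blk[2])
  on
}

illumination_at <- function(time_h, config) {
  lev <- rep(config$illumination_level, length(time_h))
  steps <- config$illumination_steps
  if (!is.null(steps) && nrow(steps) > 0) {
    steps <- steps[order(steps$time_h), , drop = FALSE]
    for (i in seq_len(nrow(steps))) {
      lev[time_h >= steps$time_h[i]] <- steps$level[i]
    }
  }
  lev
}

#' Simulate the deterministic state trajectory of a cultivation
#'
#' Integrates logistic growth in OD750 on the spectrum sampling grid
#' (piecewise-exact logistic update within each step, so results do not
#' depend on integrator step-size error), followed by first-order
#' exponential decline after the death onset. The trajectory is fully
#' deterministic: measurement noise is applied only when spectra or offline
#' OD samples are rendered from it.
#'
#' @param config a [cultivation_config()].
#' @return A `data.frame` with one row per sampling time: `time_h`,
#'   `od750`, `illumination`, `light_on`, `phase` (one of `lag_growth`,
#'   `stationary`, `death`).
#' @export
simulate_cultivation <- function(config) {
  stopifnot(inherits(config, "cultivation_config"))
  dt_h <- config$sample_interval_min / 60
  n <- floor(config$duration_days * 24 * 60 / config$sample_interval_min)
  if (n == 0) {
    return(data.frame(time_h = numeric(0), od750 = numeric(0),
                      illumination = numeric(0), light_on = logical(0),
                      phase = character(0), stringsAsFactors = FALSE))
  }
  time_h <- (seq_len(n) - 1) * dt_h
  illum <- illumination_at(time_h, config)
  light_on <- light_is_on(time_h, config$light_schedule)
  onset_h <- config$death_onset_day * 24
  K <- config$carrying_capacity_od
  od <- numeric(n)
  od[1] <- config$initial_od
  for (i in seq_len(n - 1)) {
    if (time_h[i + 1] <= onset_h) {
      r <- config$growth_rate * min(illum[i], config$illumination_saturation)
      if (r > 0) {
        e <- exp(r * dt_h)
        od[i + 1] <- K * od[i] * e / (K + od[i] * (e - 1))
      } else {
        od[i + 1] <- od[i]
      }
    } else {
      od[i + 1] <- od[i] * exp(-config$death_rate * dt_h)
    }
  }
  phase <- ifelse(time_h > onset_h, "death",
                  ifelse(od >= config$stationary_od_fraction * K,
                         "stationary", "lag_growth"))
  # growth cannot resume once stationary is reached (OD is monotone pre-onset)
  data.frame(time_h = time_h, od750 = od, illumination = illum,
             light_on = light_on, phase = phase, stringsAsFactors = FALSE)
}

default_emission_scales <- function(species) {
  if (species == "spirulina") {
    c(a = 15, b = 20, c = 80, d = 120, e = 90, f = 60, g = 150)
  } else {
    c(p1 = 60, p2 = 90, p3 = 110, p4 = 70, p5 = 50)
  }
}

#' VOC emission amplitudes for one cultivation state
#'
#' Maps a culture state to the headspace signal amplitudes the spectrometer
#' would see. For Spirulina: the growth-linked peaks c, d, e scale with
#' OD750 and are attenuated by `dark_attenuation` when the light is off;
#' g appears at stationary onset and rises as the culture declines; f is
#' emitted only above the over-illumination threshold; a and b are low,
#' medium-associated constants. The reactant ion peak (`RIP`) dominates every
#' profile and a small `pre_RIP` artifact (5% of the RIP) is always present.
#'
#' @param state one row of the trajectory from [simulate_cultivation()]
#'   (or any list with `od750`, `illumination`, `light_on`, `phase`).
#' @param config the [cultivation_config()].
#' @param scales named vector of peak emission scales; defaults depend on
#'   species.
#' @param rip_amplitude amplitude of the reactant ion peak.
#' @return Named numeric vector of non-negative amplitudes over the species
#'   peak labels plus `RIP` and `pre_RIP`.
#' @export
emission_profile <- function(state, config,
                             scales = default_emission_scales(config$species),
                             rip_amplitude = 1000) {
  stopifnot(inherits(config, "cultivation_config"))
  if (!config$species %in% c("spirulina", "chlorella")) {
    stopf("unknown species: %s", config$species)
  }
  od <- state$od750
  if (is.na(od) || od < 0) stopf("invalid state: od750 = %s", format(od))
  K <- config$carrying_capacity_od
  light_f <- if (isTRUE(state$light_on)) 1 else config$dark_attenuation
  amps <- scales * 0
  if (config$species == "spirulina") {
    amps["a"] <- scales["a"]
    amps["b"] <- scales["b"]
    amps[c("c", "d", "e")] <- scales[c("c", "d", "e")] * (od / K) * light_f
    if (state$phase %in% c("stationary", "death")) {
      progress <- max(0, 1 - od / K)
      amps["g"] <- scales["g"] * (1 - exp(-progress / config$g_rise_scale))
    }
    excess <- state$illumination - config$f_threshold
    if (excess > 0) amps["f"] <- scales["f"] * min(1, excess / 0.5)
  } else {
    amps[] <- scales * (od / K) * light_f
  }
  out <- c(amps, RIP = rip_amplitude, pre_RIP = 0.05 * rip_amplitude)
  pmax(out, 0)
}

#' Render an IMS drift spectrum from an emission profile
#'
#' The spectrum is a sum of Gaussian peaks on a drift-time axis: the
#' reactant ion peak at the drift time implied by its reduced mobility, a
#' small pre-RIP artifact, and the labelled peaks at their fixed relative
#' drift times converted to absolute drift time, all on a constant baseline
#' with additive i.i.d. Gaussian noise. Negative rendered intensities are
#' clipped at zero. The default axis carries well over 1000 samples between
#' relative drift times 0.7 and 3.
#'
#' @param profile named amplitude vector from [emission_profile()] (must
#'   contain `RIP`; `pre_RIP` optional).
#' @param peaks a [peak_defs()] table giving center (relative drift time)
#'   and width for every labelled peak in `profile`.
#' @param instrument an [instrument_config()].
#' @param noise_sd standard deviation of the additive baseline noise.
#' @param seed optional seed; `NULL` draws from the current RNG stream.
#' @param timestamp_h acquisition time stored in the spectrum.
#' @param n_points number of axis samples.
#' @param trel_range relative-drift-time span of the axis.
#' @param rip_k0 reduced mobility of the reactant ion peak (cm^2/V/s);
#'   2.1 is representative of the positive-mode protonated water cluster.
#' @param rip_sigma_trel,pre_rip_center,pre_rip_sigma shape parameters of
#'   the RIP and the pre-RIP artifact, in relative drift time.
#' @param baseline constant detector offset added to the trace.
#' @return A [drift_spectrum()].
#' @export
render_spectrum <- function(profile, peaks = default_peak_defs(),
                            instrument = instrument_config(),
                            noise_sd = 1, seed = NULL, timestamp_h = 0,
                            n_points = 1200, trel_range = c(0.65, 3.1),
                            rip_k0 = 2.1, rip_sigma_trel = 0.01,
                            pre_rip_center = 0.9, pre_rip_sigma = 0.01,
                            baseline = 10) {
  check_number(noise_sd, "noise_sd", nonneg = TRUE)
  stopifnot(inherits(peaks, "peak_defs"))
  labelled <- setdiff(names(profile), c("RIP", "pre_RIP"))
  missing <- setdiff(labelled, peaks$label)
  if (length(missing)) {
    stopf("no peak definition for label(s): %s", paste(missing, collapse = ", "))
  }
  if (!"RIP" %in% names(profile)) stopf("profile must contain an RIP amplitude")
  td_rip <- drift_time(rip_k0, instrument)
  axis_ms <- seq(trel_range[1], trel_range[2], length.out = n_points) * td_rip
  centers <- c(1, pre_rip_center, peaks$center[match(labelled, peaks$label)])
  sigmas <- c(rip_sigma_trel, pre_rip_sigma,
              peaks$width_sigma[match(labelled, peaks$label)])
  amps <- c(profile[["RIP"]],
            if ("pre_RIP" %in% names(profile)) profile[["pre_RIP"]] else 0,
            unname(profile[labelled]))
  if (any(centers < trel_range[1] | centers > trel_range[2])) {
    stopf("peak center outside the rendered axis range [%g, %g]",
          trel_range[1], trel_range[2])
  }
  y <- rep(baseline, n_points)
  for (k in seq_along(centers)) {
    if (amps[k] == 0) next
    mu <- centers[k] * td_rip
    s <- sigmas[k] * td_rip
    y <- y + amps[k] * exp(-(axis_ms - mu)^2 / (2 * s^2))
  }
  if (noise_sd > 0) {
    noise <- with_seed(seed, rnorm(n_points, 0, noise_sd))
    y <- y + noise
  }
  drift_spectrum(axis_ms, pmax(y, 0), timestamp_h = timestamp_h,
                 instrument = instrument)
}

#' Simulate a full cultivation spectrum series with ground truth
#'
#' Runs [simulate_cultivation()], derives the emission profile at every
#' sampling time (one spectrum per acquisition interval, default 10 min)
#' and renders the seeded noisy spectra. The deterministic ground truth
#' (trajectory and true per-peak amplitudes) is returned alongside the
#' series for parameter-recovery testing.
#'
#' @param config a [cultivation_config()].
#' @param peaks a [peak_defs()] table for the configured species.
#' @param instrument an [instrument_config()].
#' @param noise_sd baseline noise standard deviation.
#' @param ... further arguments passed to [render_spectrum()].
#' @return A list: `series` ([spectrum_series()]), `truth` (trajectory
#'   `data.frame`), `emissions` (matrix time x peak label of true
#'   amplitudes).
#' @export
simulate_series <- function(config,
                            peaks = default_peak_defs(config$species),
                            instrument = instrument_config(),
                            noise_sd = 1, ...) {
  stopifnot(inherits(config, "cultivation_config"))
  traj <- simulate_cultivation(config)
  n <- nrow(traj)
  if (n == 0) {
    return(list(series = spectrum_series(list()), truth = traj,
                emissions = matrix(numeric(0), nrow = 0, ncol = 0)))
  }
  profiles <- lapply(seq_len(n), function(i) {
    emission_profile(traj[i, ], config)
  })
  emis <- do.call(rbind, profiles)
  rownames(emis) <- NULL
  spectra <- with_seed(config$seed, {
    lapply(seq_len(n), function(i) {
      render_spectrum(profiles[[i]], peaks = peaks, instrument = instrument,
                      noise_sd = noise_sd, seed = NULL,
                      timestamp_h = traj$time_h[i], ...)
    })
  })
  list(series = spectrum_series(spectra, common_axis = TRUE),
       truth = traj, emissions = emis)
}

#' Sample sparse offline OD750 measurements from a trajectory
#'
#' Emulates the offline photometric protocol: a handful of samplings per
#' day, each measured as several replicate reads with multiplicative noise
#' (coefficient of variation `cv`); the replicate mean and standard
#' deviation are returned per sampling time.
#'
#' Default training cultivations for the state model
#'
#' The state model is meant to be trained once on a designated set of
#' cultivations spanning the states it must recognize: standard cultures
#' contribute the growth, stationary and death patterns, and one culture
#' run under the 60% -> 200% illumination-step protocol contributes the
#' over-illumination pattern (peak f) that the third component and the
#' shading rule rely on.
#'
#' @param seed master seed; each culture uses an offset of it.
#' @param n_standard number of standard reference cultures.
#' @param sample_interval_min spectrum sampling interval (minutes).
#' @param duration_days cultivation length in days.
#' @return List of [cultivation_config()] objects (the last one is the
#'   illumination-step culture).
#' @export
training_configs <- function(seed = 1L, n_standard = 2,
                             sample_interval_min = 10,
                             duration_days = 8) {
  cfgs <- lapply(seq_len(n_standard), function(i) {
    cultivation_config(seed = seed + i - 1L,
                       sample_interval_min = sample_interval_min,
                       duration_days = duration_days)
  })
  step <- cultivation_config(
    seed = seed + n_standard,
    illumination_level = 0.6,
    illumination_steps = data.frame(time_h = 24, level = 2.0),
    sample_interval_min = sample_interval_min,
    duration_days = duration_days
  )
  c(cfgs, list(step))
}

#' Simulate and preprocess a training matrix for the state model
#'
#' Simulates each configured cultivation, preprocesses it (RIP
#' normalization, common grid) and stacks the RIP-masked state matrices
#' row-wise.
#'
#' @param configs list of [cultivation_config()], e.g. [training_configs()].
#' @param grid common relative-drift-time grid.
#' @param rip_exclusion relative-drift-time cutoff masking the RIP region.
#' @param noise_sd baseline noise passed to the renderer.
#' @param ... further arguments to [simulate_series()].
#' @return The stacked state matrix (with `grid` and `timestamps`
#'   attributes) plus attributes `culture` (index per row) and `phase`
#'   (true phase label per row).
#' @export
simulate_training_matrix <- function(configs, grid = default_rel_grid(),
                                     rip_exclusion = 1.05, noise_sd = 1,
                                     ...) {
  mats <- list(); cult <- integer(0); phase <- character(0)
  for (i in seq_along(configs)) {
    sim <- simulate_series(configs[[i]], noise_sd = noise_sd, ...)
    pre <- preprocess_series(sim$series, grid = grid)
    m <- state_matrix(pre$matrix, rip_exclusion)
    mats[[i]] <- m
    cult <- c(cult, rep(i, nrow(m)))
    phase <- c(phase, sim$truth$phase)
  }
  out <- do.call(rbind, mats)
  attr(out, "grid") <- attr(mats[[1]], "grid")
  attr(out, "timestamps") <- unlist(lapply(mats, attr, "timestamps"))
  attr(out, "culture") <- cult
  attr(out, "phase") <- phase
  out
}

#' Samplings are placed within the daily working window `daily_hours`
#' (default 1--15 h, inside the illuminated phase of the default 16 h-on
#' schedule): offline photometry is a manual operation performed while the
#' culture is lit.
#'
#' @param trajectory trajectory `data.frame` from [simulate_cultivation()].
#' @param per_day samplings per day (>= 1).
#' @param replicates replicate reads per sampling (>= 1; default 6).
#' @param cv replicate coefficient of variation (fraction, >= 0).
#' @param daily_hours `c(first, last)` hour-of-day of the first and last
#'   sampling each day.
#' @param seed optional RNG seed.
#' @return `data.frame` with `time_h`, `od750_mean`, `od750_sd`.
#' @export
sample_offline_od <- function(trajectory, per_day = 5, replicates = 6,
                              cv = 0.02, daily_hours = c(1, 15),
                              seed = NULL) {
  if (per_day < 1) stopf("per_day must be >= 1")
  if (replicates < 1) stopf("replicates must be >= 1")
  check_number(cv, "cv", nonneg = TRUE)
  if (nrow(trajectory) == 0) {
    return(data.frame(time_h = numeric(0), od750_mean = numeric(0),
                      od750_sd = numeric(0)))
  }
  t_max <- max(trajectory$time_h)
  days <- seq_len(max(1, ceiling((t_max + 1e-9) / 24))) - 1
  hours <- if (per_day == 1) mean(daily_hours) else
    seq(daily_hours[1], daily_hours[2], length.out = per_day)
  times <- as.vector(outer(hours, days * 24, "+"))
  times <- sort(times[times <= t_max])
  od_true <- approx(trajectory$time_h, trajectory$od750, xout = times,
                    rule = 2)$y
  with_seed(seed, {
    draws <- lapply(od_true, function(od) {
      pmax(0, od * (1 + cv * rnorm(replicates)))
    })
    data.frame(
      time_h = times,
      od750_mean = vapply(draws, mean, numeric(1)),
      od750_sd = vapply(draws, sd, numeric(1))
    )
  })
}
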