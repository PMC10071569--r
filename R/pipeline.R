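#' Full pipeline run configuration
#'
#' A single nested configuration covering simulation, preprocessing, state
#' model and control thresholds, round-trippable through YAML. Unknown
#' keys are rejected rather than silently ignored, so typos in a config
#' file surface immediately. Every default equals the corresponding
#' function default ([cultivation_config()], [estimate_noise()],
#' [fit_state_model()], [control_thresholds()], ...).
#'
#' @param simulation named list overriding [cultivation_config()] arguments
#'   plus `noise_sd` (baseline noise) and `n_points`/`trel_range` of the
#'   rendered axis.
#' @param preprocessing named list: `noise_window` (2 values),
#'   `rip_exclusion`, `grid_n`, `grid_range` (2 values).
#' @param model named list: `n_components`.
#' @param control named list overriding [control_thresholds()] arguments.
#' @param seed integer master seed for the run.
#' @return Nested list of class `run_config`.
#' @export
run_config <- function(simulation = list(), preprocessing = list(),
                       model = list(), control = list(), seed = 1L) {
  defaults <- list(
    simulation = c(
      formals_defaults(cultivation_config),
      list(noise_sd = 1, n_points = 1200L, trel_range = c(0.65, 3.1))
    ),
    preprocessing = list(noise_window = c(2.2, 2.9), rip_exclusion = 1.05,
                         grid_n = 1150L, grid_range = c(0.7, 3)),
    model = list(n_components = 4L),
    control = formals_defaults(control_thresholds),
    seed = 1L
  )
  sections <- list(simulation = simulation, preprocessing = preprocessing,
                   model = model, control = control)
  out <- defaults
  for (sec in names(sections)) {
    given <- sections[[sec]]
    if (length(given)) {
      unknown <- setdiff(names(given), names(defaults[[sec]]))
      if (length(unknown)) {
        stopf("unknown %s config key(s): %s", sec,
              paste(unknown, collapse = ", "))
      }
      out[[sec]] <- modifyList(defaults[[sec]], given)
    }
  }
  out$seed <- as.integer(seed)
  # validate by constructing the underlying objects
  invisible(config_objects(structure(out, class = "run_config")))
  structure(out, class = "run_config")
}

# default values of a function's formals, evaluated; language defaults
# (match.arg choices etc.) collapse to their first element
formals_defaults <- function(fn) {
  fm <- formals(fn)
  out <- list()
  for (nm in names(fm)) {
    v <- fm[[nm]]
    if (is.call(v) || is.name(v)) v <- eval(v, envir = environment(fn))
    if (is.list(v) && !is.data.frame(v)) {
      out[[nm]] <- v
    } else if (length(v) > 1) {
      out[[nm]] <- v[1]
    } else {
      out[nm] <- list(v)
    }
  }
  out
}

# instantiate the typed objects a run_config describes
config_objects <- function(config) {
  stopifnot(inherits(config, "run_config"))
  sim <- config$simulation
  cc_args <- sim[intersect(names(sim), names(formals(cultivation_config)))]
  cc_args$seed <- config$seed
  cc <- do.call(cultivation_config, cc_args)
  list(
    cultivation = cc,
    peaks = default_peak_defs(cc$species),
    instrument = instrument_config(),
    thresholds = do.call(control_thresholds, config$control),
    grid = default_rel_grid(config$preprocessing$grid_n,
                            unlist(config$preprocessing$grid_range)),
    noise_window = unlist(config$preprocessing$noise_window),
    rip_exclusion = config$preprocessing$rip_exclusion,
    noise_sd = sim$noise_sd,
    render_args = list(n_points = sim$n_points,
                       trel_range = unlist(sim$trel_range)),
    n_components = config$model$n_components
  )
}

#' Read / write a run configuration (YAML)
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return `read_run_config()` returns a validated [run_config()];
#'   `write_run_config()` returns `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), c("simulation", "preprocessing", "model",
                                   "control", "seed"))
  if (length(unknown)) {
    stopf("unknown config section(s): %s", paste(unknown, collapse = ", "))
  }
  raw$simulation$light_schedule <- lapply(raw$simulation$light_schedule, unlist)
  if (!is.null(raw$simulation$illumination_steps)) {
    raw$simulation$illumination_steps <-
      as.data.frame(raw$simulation$illumination_steps)
  }
  run_config(simulation = raw$simulation, preprocessing = raw$preprocessing,
             model = raw$model, control = raw$control, seed = raw$seed)
}

# cheap deterministic content hash for report headers (not cryptographic)
config_hash <- function(txt) {
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

report_header <- function(config, extra = character(0)) {
  cfg_yaml <- yaml::as.yaml(unclass(config), precision = 15L)
  c(sprintf("# driftwatch %s | R %s.%s",
            as.character(utils::packageVersion("driftwatch")),
            R.version$major, R.version$minor),
    sprintf("# seed: %d | config hash: %s", config$seed, config_hash(cfg_yaml)),
    extra)
}

#' Simulate a cultivation and write the series to disk
#'
#' Renders the configured cultivation and writes, under `out_dir`: the
#' spectrum series (`series/` in the CSV + JSON sidecar format), the
#' offline OD sample table (`od_samples.csv`), the deterministic
#' ground-truth trajectory (`truth.csv`) and a `run_info.txt` header
#' recording seed and config hash.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if missing).
#' @param od_per_day,od_replicates,od_cv offline OD sampling protocol.
#' @return Invisibly, a list of the written paths plus the simulation
#'   output.
#' @export
cmd_simulate <- function(config, out_dir, od_per_day = 5,
                         od_replicates = 6, od_cv = 0.02) {
  obj <- config_objects(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- do.call(simulate_series,
                 c(list(config = obj$cultivation, peaks = obj$peaks,
                        instrument = obj$instrument, noise_sd = obj$noise_sd),
                   obj$render_args))
  series_dir <- file.path(out_dir, "series")
  write_series(sim$series, series_dir)
  od <- sample_offline_od(sim$truth, per_day = od_per_day,
                          replicates = od_replicates, cv = od_cv,
                          seed = config$seed + 1L)
  utils::write.csv(od, file.path(out_dir, "od_samples.csv"), row.names = FALSE)
  utils::write.csv(sim$truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
  writeLines(report_header(config,
                           sprintf("# %d spectra written", length(sim$series))),
             file.path(out_dir, "run_info.txt"))
  invisible(list(series_dir = series_dir,
                 od_path = file.path(out_dir, "od_samples.csv"),
                 truth_path = file.path(out_dir, "truth.csv"),
                 simulation = sim))
}

#' Serialize / load a fitted state model (JSON)
#'
#' @param model a [fit_state_model()] result.
#' @param path JSON file path.
#' @return `read_state_model()` returns a `state_model`.
#' @export
write_state_model <- function(model, path) {
  stopifnot(inherits(model, "state_model"))
  obj <- unclass(model)
  obj$loadings <- as.data.frame(obj$loadings)
  obj$peaks <- as.data.frame(unclass(obj$peaks))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_state_model
#' @export
read_state_model <- function(path) {
  if (!file.exists(path)) stopf("state model file not found: %s", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$loadings <- as.matrix(obj$loadings)
  dimnames(obj$loadings) <- NULL
  obj$peaks <- structure(as.data.frame(obj$peaks),
                         class = c("peak_defs", "data.frame"))
  obj$zero_variance_cols <- as.integer(obj$zero_variance_cols)
  structure(obj, class = "state_model")
}

#' Analyze a spectrum series end to end
#'
#' Reads a stored series, preprocesses it (RIP normalization, noise
#' estimation, common-axis interpolation), extracts the per-peak time
#' series, fits (or loads) the four-component state model, scores every
#' spectrum and runs the control rule engine. CSV outputs (`peak_table.csv`,
#' `scores.csv`, `recommendations.csv`, `contributions.csv`) and a header
#' report are written to `out_dir`; diagnostic plots are written when
#' `plots = TRUE` and ggplot2 is installed.
#'
#' @param series_path directory written by [write_series()].
#' @param out_dir output directory.
#' @param config a [run_config()].
#' @param model optional frozen [fit_state_model()] result or path to one
#'   (JSON); when `NULL` the model is fitted on this series and written to
#'   `state_model.json`.
#' @param plots write PNG diagnostic plots.
#' @return Invisibly: list with `pre`, `peak_table`, `model`, `scores`,
#'   `recommendations`, `contributions`.
#' @export
cmd_analyze <- function(series_path, out_dir, config = run_config(),
                        model = NULL, plots = FALSE) {
  obj <- config_objects(config)
  series <- read_series(series_path)
  if (length(series) == 0) stopf("empty series at %s", series_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pre <- preprocess_series(series, grid = obj$grid,
                           noise_window = obj$noise_window)
  peak_table <- extract_time_series(pre, obj$peaks,
                                    rip_exclusion = obj$rip_exclusion)
  novel <- novel_peak_flags(pre, obj$peaks, rip_exclusion = obj$rip_exclusion)
  smat <- state_matrix(pre$matrix, obj$rip_exclusion)
  if (is.character(model)) model <- read_state_model(model)
  if (is.null(model)) {
    model <- fit_state_model(smat, peaks = obj$peaks,
                             n_components = obj$n_components)
    write_state_model(model, file.path(out_dir, "state_model.json"))
  } else if (!isTRUE(all.equal(model$grid, attr(smat, "grid")))) {
    stopf("grid mismatch: frozen model grid (%d points) differs from this series' grid (%d points)",
          length(model$grid), length(attr(smat, "grid")))
  }
  scores <- transform_scores(smat, model)
  recs <- classify_scores(scores, obj$thresholds, peak_table = peak_table,
                          novel = novel)
  contrib <- peak_contributions(model)
  utils::write.csv(peak_table, file.path(out_dir, "peak_table.csv"),
                   row.names = FALSE)
  utils::write.csv(
    data.frame(time_h = attr(scores, "timestamps"), scores, novel_peak = novel),
    file.path(out_dir, "scores.csv"), row.names = FALSE)
  utils::write.csv(recs, file.path(out_dir, "recommendations.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(label = rownames(contrib$per_peak),
                              contrib$per_peak),
                   file.path(out_dir, "contributions.csv"), row.names = FALSE)
  writeLines(report_header(config, c(
    sprintf("# %d spectra analyzed", length(series)),
    sprintf("# explained variance: %s",
            paste(sprintf("%.3f", model$explained_variance_ratio),
                  collapse = ", ")),
    sprintf("# final recommendation: %s", utils::tail(recs$action, 1))
  )), file.path(out_dir, "report.txt"))
  if (plots) write_diagnostic_plots(pre, peak_table, scores, contrib, out_dir)
  invisible(list(pre = pre, peak_table = peak_table, model = model,
                 scores = scores, recommendations = recs,
                 contributions = contrib))
}

#' Stream a series through a frozen state model
#'
#' Processes spectra strictly one at a time (as an online monitor attached
#' to the instrument would), emitting one recommendation per new spectrum.
#' All statistics used by the rule engine are causal, so the emitted
#' sequence is identical to batch [cmd_analyze()] on the same data with
#' the same frozen model. Spectra that fail preprocessing are logged and
#' skipped; the stream continues.
#'
#' @param series_path directory written by [write_series()], or a
#'   [spectrum_series()].
#' @param model a frozen [fit_state_model()] result or a path to one;
#'   mandatory (no implicit refit).
#' @param config a [run_config()].
#' @param quiet suppress per-spectrum console output.
#' @return `data.frame` of class `recommendations` (one row per processed
#'   spectrum; the first `window - 1` rows have status
#'   `INSUFFICIENT_DATA`).
#' @export
cmd_monitor <- function(series_path, model, config = run_config(),
                        quiet = TRUE) {
  obj <- config_objects(config)
  if (is.character(model)) model <- read_state_model(model)
  if (is.null(model)) stopf("cmd_monitor requires a frozen state model")
  series <- if (inherits(series_path, "spectrum_series")) series_path
            else read_series(series_path)
  scores <- NULL
  ts <- numeric(0)
  peak_rows <- list()
  novel <- logical(0)
  out <- NULL
  for (i in seq_along(series$spectra)) {
    row <- tryCatch({
      ns <- normalize_spectrum(series$spectra[[i]])
      noise <- estimate_noise(ns, window = obj$noise_window)
      m1 <- to_common_axis(list(ns), obj$grid)
      pre1 <- list(matrix = m1, grid = attr(m1, "grid"),
                   timestamps = ns$timestamp_h, normalized = list(ns),
                   noise = list(noise))
      pt <- extract_time_series(pre1, obj$peaks,
                                rip_exclusion = obj$rip_exclusion)
      nv <- novel_peak_flags(pre1, obj$peaks,
                             rip_exclusion = obj$rip_exclusion)
      sm <- state_matrix(m1, obj$rip_exclusion)
      sc <- transform_scores(sm, model)
      list(score = sc, t = ns$timestamp_h, pt = pt, novel = nv)
    }, error = function(e) {
      warning(sprintf("spectrum %d skipped: %s", i, conditionMessage(e)))
      NULL
    })
    if (is.null(row)) next
    scores <- rbind(scores, row$score)
    ts <- c(ts, row$t)
    peak_rows[[length(peak_rows) + 1L]] <- row$pt
    novel <- c(novel, row$novel)
    attr(scores, "timestamps") <- ts
    recs <- classify_scores(scores, obj$thresholds,
                            peak_table = do.call(rbind, peak_rows),
                            novel = novel)
    latest <- recs[nrow(recs), , drop = FALSE]
    if (!quiet) {
      message(sprintf("t = %6.2f h  %-30s %s", latest$time_h,
                      latest$action, latest$triggering_rule))
    }
    out <- recs
  }
  if (is.null(out)) stopf("no spectra could be processed")
  out
}

# PNG diagnostics via ggplot2 (optional; failures are warnings, the
# analysis itself never depends on a graphics device being available)
write_diagnostic_plots <- function(pre, peak_table, scores, contrib, out_dir) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    warning("ggplot2 not installed; skipping plots")
    return(invisible(NULL))
  }
  tryCatch({
    gg <- ggplot2::ggplot
    aes <- ggplot2::aes
    # waterfall of a spectrum subset
    idx <- unique(round(seq(1, nrow(pre$matrix), length.out = 8)))
    wf <- do.call(rbind, lapply(idx, function(i) {
      data.frame(trel = pre$grid, intensity = pre$matrix[i, ],
                 time_h = pre$timestamps[i])
    }))
    p1 <- gg(wf, aes(trel, intensity, group = time_h,
                     colour = factor(round(time_h, 1)))) +
      ggplot2::geom_line(linewidth = 0.3) +
      ggplot2::labs(x = "relative drift time", y = "intensity (a.u.)",
                    colour = "t (h)")
    ggplot2::ggsave(file.path(out_dir, "spectra_waterfall.png"), p1,
                    width = 7, height = 4, dpi = 120)
    p2 <- gg(peak_table, aes(time_h, apex_intensity, colour = label)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "time (h)", y = "apex intensity (a.u.)")
    ggplot2::ggsave(file.path(out_dir, "peak_series.png"), p2,
                    width = 7, height = 4, dpi = 120)
    sc <- data.frame(time_h = attr(scores, "timestamps"), scores)
    sc_long <- do.call(rbind, lapply(colnames(scores), function(pc) {
      data.frame(time_h = sc$time_h, pc = pc, score = sc[[pc]])
    }))
    p3 <- gg(sc_long, aes(time_h, score, colour = pc)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "time (h)", y = "PC score")
    ggplot2::ggsave(file.path(out_dir, "score_trajectories.png"), p3,
                    width = 7, height = 4, dpi = 120)
    cb <- data.frame(label = rownames(contrib$per_peak), contrib$per_peak)
    cb_long <- do.call(rbind, lapply(colnames(contrib$per_peak), function(pc) {
      data.frame(label = cb$label, pc = pc, contribution = cb[[pc]])
    }))
    p4 <- gg(cb_long, aes(label, contribution, fill = pc)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::labs(x = "peak", y = "contribution to PC score")
    ggplot2::ggsave(file.path(out_dir, "contribution_bars.png"), p4,
                    width = 7, height = 4, dpi = 120)
  }, error = function(e) warning(sprintf("plotting failed: %s",
                                         conditionMessage(e))))
  invisible(NULL)
}
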