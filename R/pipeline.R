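#' Run configuration
#'
#' Bundles every knob of a reproducible analysis run: input paths, the
#' differentiation configuration, the unit class analyzed, thresholds, the
#' state-length grid, and the seed. Serializable to and from a single YAML
#' file; every run writes the resolved configuration beside its outputs.
#'
#' @param spikes,units,epochs,speed Paths to the input CSV tables (the
#'   latter two optional).
#' @param out_dir Output directory for run artifacts.
#' @param W,S,f,taper,min_units Differentiation parameters, see
#'   [nd_config()].
#' @param unit_class `"RS"` or `"FS"`: which unit class enters ensembles.
#' @param width_threshold,snr_threshold Unit-classification thresholds.
#' @param run_speed_threshold Running/stationary split, cm/s.
#' @param alpha False-discovery-rate level for comparisons.
#' @param S_grid State-length grid for timescale surveys (seconds).
#' @param seed Integer seed used by every stochastic step.
#' @return A list of class `run_config`.
#' @export
run_config <- function(spikes = NULL, units = NULL, epochs = NULL,
                       speed = NULL, out_dir = "specdiff_run",
                       W = 3, S = 0.3, f = 200, taper = "none",
                       min_units = 10, unit_class = "RS",
                       width_threshold = 0.4, snr_threshold = 2.5,
                       run_speed_threshold = 2, alpha = 0.01,
                       S_grid = NULL, seed = 1) {
  cfg <- list(
    spikes = spikes, units = units, epochs = epochs, speed = speed,
    out_dir = out_dir, W = W, S = S, f = f, taper = taper,
    min_units = min_units, unit_class = unit_class,
    width_threshold = width_threshold, snr_threshold = snr_threshold,
    run_speed_threshold = run_speed_threshold, alpha = alpha,
    S_grid = S_grid, seed = seed
  )
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg[names(cfg) %in% names(formals(run_config))])
}

#' @rdname run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config)[!vapply(config, is.null, logical(1))], path)
  invisible(path)
}

config_hash <- function(config) {
  rlang::hash(unclass(config))
}

log_stage <- function(...) {
  message(sprintf("[specdiff %s] ", format(Sys.time(), "%H:%M:%S")), sprintf(...))
}

load_session <- function(config) {
  stopifnot(!is.null(config$spikes), !is.null(config$units))
  for (p in c(config$spikes, config$units, config$epochs, config$speed)) {
    if (!is.null(p) && !file.exists(p)) stop("missing input file: ", p)
  }
  spikes <- read_spikes_csv(config$spikes)
  units <- read_units_csv(config$units)
  units$unit_class <- classify_units(units, config$width_threshold,
                                     config$snr_threshold)
  epochs <- if (!is.null(config$epochs)) read_epochs_csv(config$epochs)
  if (!is.null(epochs) && is.null(epochs$category) && !is.null(epochs$stimulus)) {
    epochs <- assign_categories(epochs)
  }
  speed <- if (!is.null(config$speed)) read_speed_csv(config$speed)
  list(st = spike_table(spikes, units), epochs = epochs, speed = speed)
}

run_summary <- function(config, extra = list()) {
  c(list(
    package_version = as.character(utils::packageVersion("specdiff")),
    config = unclass(config)[!vapply(config, is.null, logical(1))],
    config_hash = config_hash(config)
  ), extra)
}

#' Pipeline stages
#'
#' Orchestration over the module functions. Each stage reads the inputs
#' named in the configuration, computes its products per ensemble (units
#' of the configured class grouped by area; areas below the minimum
#' ensemble size are skipped with a logged message), writes CSV outputs
#' plus a JSON run summary (package version, resolved config, config hash,
#' bound-check status) into `config$out_dir`, and returns its results
#' invisibly. `run_simulate` generates a synthetic change-detection
#' session and writes it in the same CSV formats the other stages read;
#' `run_all` chains simulate, nd, timescales, and compare.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list of the stage's main tables.
#' @export
run_nd <- function(config) {
  log_stage("nd: loading inputs")
  ses <- load_session(config)
  cfg <- nd_config(W = config$W, S = config$S, f = config$f,
                   taper = config$taper, min_units = config$min_units)
  keep <- ses$st$units$unit_id[ses$st$units$unit_class == config$unit_class]
  areas <- split(keep, ses$st$units$area[match(keep, ses$st$units$unit_id)])
  out <- list()
  for (a in names(areas)) {
    if (length(areas[[a]]) < config$min_units) {
      log_stage("nd: area %s has %d < %d units, skipped (10-unit rule)",
                a, length(areas[[a]]), config$min_units)
      next
    }
    rm_ <- build_rate_matrix(ses$st, f = config$f, unit_ids = areas[[a]])
    nd <- nd_timeseries(rm_, epochs = ses$epochs, cfg = cfg)
    nd$area <- a
    out[[a]] <- nd
    log_stage("nd: area %s done (%d windows)", a, nrow(nd))
  }
  nd_all <- dplyr::bind_rows(out)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_csv_stable(nd_all, file.path(config$out_dir, "nd_windows.csv"))
  bound_ok <- all(nd_all$nd <= bound_normalized(pmax(nd_all$amplitude_max, 1e-12),
                                                config$f) + 1e-9)
  summ <- run_summary(config, list(
    n_units_analyzed = length(keep),
    areas = names(out),
    n_windows = nrow(nd_all),
    bound_check_passed = bound_ok
  ))
  jsonlite::write_json(summ, file.path(config$out_dir, "nd_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  write_run_config(config, file.path(config$out_dir, "config.yaml"))
  invisible(list(nd = nd_all, summary = summ))
}

#' @rdname run_nd
#' @export
run_timescales <- function(config) {
  log_stage("timescales: loading inputs")
  ses <- load_session(config)
  cfg <- nd_config(W = config$W, S = config$S, f = config$f,
                   taper = config$taper, min_units = config$min_units)
  S_grid <- config$S_grid %||% state_length_grid(f = config$f,
                                                 S_max = config$W / 2)
  keep <- ses$st$units$unit_id[ses$st$units$unit_class == config$unit_class]
  areas <- split(keep, ses$st$units$area[match(keep, ses$st$units$unit_id)])
  curves <- list()
  fits <- list()
  for (a in names(areas)) {
    if (length(areas[[a]]) < config$min_units) {
      log_stage("timescales: area %s has %d < %d units, skipped",
                a, length(areas[[a]]), config$min_units)
      next
    }
    rm_ <- build_rate_matrix(ses$st, f = config$f, unit_ids = areas[[a]])
    curve <- nd_vs_state_length(rm_, cfg = cfg, S_grid = S_grid)
    opt <- detect_optimal_timescale(curve)
    curve$ensemble_id <- a
    curves[[a]] <- curve
    fit <- tryCatch({
      ac <- autocorrelation(colMeans(rm_), max_lag = 2, f = config$f)
      f_ <- fit_characteristic_timescale(ac)
      list(ensemble_id = a, a = f_$a, c = f_$c, t1 = f_$t1, t2 = f_$t2,
           residual = f_$residual, at_boundary = f_$at_boundary,
           classification = opt$classification, S_opt = opt$S_opt)
    }, error = function(e) {
      log_stage("timescales: area %s AC fit failed: %s", a, conditionMessage(e))
      NULL
    })
    fits[[a]] <- fit
    log_stage("timescales: area %s done", a)
  }
  curves_all <- dplyr::bind_rows(curves)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_csv_stable(curves_all, file.path(config$out_dir, "nd_curves.csv"))
  jsonlite::write_json(run_summary(config, list(fits = fits)),
                       file.path(config$out_dir, "timescales_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(curves = curves_all, fits = fits))
}

#' @rdname run_nd
#' @export
run_compare <- function(config) {
  log_stage("compare: loading nd windows")
  nd_path <- file.path(config$out_dir, "nd_windows.csv")
  if (!file.exists(nd_path)) stop("run_nd output not found: ", nd_path)
  nd <- tibble::as_tibble(utils::read.csv(nd_path))
  nd <- nd[!is.na(nd$category) & nd$category != "", ]
  out <- list()
  for (a in unique(nd$area)) {
    sub <- nd[nd$area == a, ]
    if (length(unique(sub$category)) < 2) next
    cmp <- compare_groups(sub$nd, sub$category, alpha = config$alpha)
    cmp$area <- a
    out[[a]] <- cmp
  }
  cmp_all <- dplyr::bind_rows(out)
  write_csv_stable(cmp_all, file.path(config$out_dir, "nd_contrasts.csv"))
  jsonlite::write_json(
    run_summary(config, list(n_contrasts = nrow(cmp_all))),
    file.path(config$out_dir, "compare_summary.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(list(contrasts = cmp_all))
}

#' @rdname run_nd
#' @param spec A [synthetic_session_spec()]; its seed is replaced by the
#'   config seed.
#' @export
run_simulate <- function(config, spec = synthetic_session_spec()) {
  spec$seed <- config$seed
  log_stage("simulate: generating session (seed %d)", config$seed)
  ses <- gen_change_detection_session(spec, f = config$f)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    spikes = file.path(config$out_dir, "spikes.csv"),
    units = file.path(config$out_dir, "units.csv"),
    trials = file.path(config$out_dir, "trials.csv"),
    speed = file.path(config$out_dir, "speed.csv")
  )
  write_csv_stable(ses$spike_table$spikes, paths$spikes)
  write_csv_stable(ses$spike_table$units, paths$units)
  write_csv_stable(ses$trials, paths$trials)
  write_csv_stable(ses$speed, paths$speed)
  log_stage("simulate: wrote %d spikes for %d units",
            nrow(ses$spike_table$spikes), nrow(ses$spike_table$units))
  invisible(c(paths, list(session = ses)))
}

#' @rdname run_nd
#' @export
run_all <- function(config, spec = synthetic_session_spec()) {
  sim <- run_simulate(config, spec)
  config$spikes <- sim$spikes
  config$units <- sim$units
  config$speed <- sim$speed
  nd <- run_nd(config)
  ts <- run_timescales(config)
  cmp <- tryCatch(run_compare(config), error = function(e) {
    log_stage("compare skipped: %s", conditionMessage(e))
    NULL
  })
  invisible(list(simulate = sim[names(sim) != "session"], nd = nd,
                 timescales = ts, compare = cmp))
}
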