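#' Run the analysis pipeline from a structured config
#'
#' Executes the requested stages in dependency order from a single flat
#' configuration (JSON or YAML file, or an equivalent named list) and
#' writes a manifest recording inputs, parameters, seeds and the MD5
#' hash of every output, sufficient to rerun any stage.
#'
#' Recognised stages (`stages` key, character vector):
#' \describe{
#'   \item{`simulate_walks`}{seeded Levy-walk cohort; writes
#'     `tracks_vehicle.csv` / `tracks_treated.csv`.}
#'   \item{`tracks`}{load, speed-filter and summarise tracks; writes
#'     `kinematics_<condition>.csv`.}
#'   \item{`stable_fit`}{pooled step-length stable fit with bootstrap;
#'     writes `stable_fits.csv`.}
#'   \item{`scan`}{rank-sum scan of treated vs vehicle cumulative
#'     distances; writes `rank_sum_scan.csv`.}
#'   \item{`simulate_fccs`}{synthetic FCCS measurement table; writes
#'     `fccs_measurements.csv`.}
#'   \item{`fccs`}{QC + concentrations + RCC + Kd fit from a measurement
#'     table; writes `fccs_processed.csv` and `kd_fit.csv`.}
#'   \item{`simulate_speeds`}{synthetic growth-speed events; writes
#'     `growth_speeds.csv`.}
#'   \item{`tertiles`}{vehicle-anchored tertile analysis; writes
#'     `tertiles.csv`.}
#' }
#'
#' Config keys (all optional unless a stage needs them): `out_dir`,
#' `seed`, `frame_interval`, `min_speed`, `n_cells`, `n_frames`,
#' `shift_time`, `alpha` (scan threshold), `bootstrap_subsets`,
#' `bootstrap_size`, `kd_true`, `fccs_n_cells`, `effective_volume`,
#' `ci_level`, `tracks_vehicle`, `tracks_treated` (input CSVs when
#' `simulate_walks` is not run), `fccs_table`, `speeds_table`,
#' `reference_condition`.
#'
#' @param config path to a JSON/YAML config file, or a named list.
#' @return The manifest, invisibly (also written to
#'   `<out_dir>/manifest.json`).
#' @export
run_pipeline <- function(config) {
  cfg <- .load_config(config)
  .validate_config(cfg)
  out_dir <- cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  log_info <- function(...) message("[cellwalk] ", sprintf(...))
  stages <- cfg$stages

  tracks <- NULL
  if ("simulate_walks" %in% stages) {
    wcfg <- walk_sim_config(
      params_vehicle = .params_from_cfg(cfg$stable_vehicle,
                                        stable_params(1.5, 0, 0.9, 2.6)),
      params_treated = .params_from_cfg(cfg$stable_treated,
                                        stable_params(1.5, 0, 0.7, 2.1)),
      n_cells = cfg$n_cells %||% 100,
      n_frames = cfg$n_frames %||% 145,
      frame_interval = cfg$frame_interval %||% 10,
      shift_time = cfg$shift_time %||% 1,
      seed = cfg$seed %||% 1)
    tracks <- simulate_levy_walk_cohort(wcfg)
    for (cond in names(tracks))
      outputs <- c(outputs, write_tracks(
        tracks[[cond]], file.path(out_dir,
                                  sprintf("tracks_%s.csv", cond))))
    log_info("simulate_walks: %d + %d tracks", length(tracks$vehicle),
             length(tracks$treated))
  }

  if (is.null(tracks) &&
      any(c("tracks", "stable_fit", "scan") %in% stages)) {
    fi <- cfg$frame_interval %||% 10
    tracks <- list(
      vehicle = load_tracks(cfg$tracks_vehicle, fi),
      treated = load_tracks(cfg$tracks_treated, fi))
  }

  filtered <- NULL
  if (!is.null(tracks)) {
    fcfg <- track_filter_config(min_mean_speed = cfg$min_speed %||% 2.5)
    filtered <- lapply(tracks, function(tr) filter_tracks(tr, fcfg))
  }

  if ("tracks" %in% stages) {
    for (cond in names(filtered)) {
      fl <- filtered[[cond]]
      summ <- summarise_tracks(fl$kept)
      path <- file.path(out_dir, sprintf("kinematics_%s.csv", cond))
      utils::write.csv(summ, path, row.names = FALSE)
      outputs <- c(outputs, path)
      log_info("tracks [%s]: %d kept, %d rejected by speed filter", cond,
               length(fl$kept), length(fl$rejected))
    }
  }

  if ("stable_fit" %in% stages) {
    rows <- lapply(names(filtered), function(cond) {
      steps <- unlist(lapply(filtered[[cond]]$kept,
                             function(tr) step_lengths(tr)$steps))
      boot <- bootstrap_alpha_stable(
        steps,
        n_subsets = cfg$bootstrap_subsets %||% 100,
        subset_size = cfg$bootstrap_size %||% 15000,
        seed = cfg$seed %||% 1)
      data.frame(condition = cond, n_steps = length(steps),
                 alpha = boot$mean[["alpha"]], beta = boot$mean[["beta"]],
                 gamma = boot$mean[["gamma"]], delta = boot$mean[["delta"]],
                 alpha_sd = boot$sd[["alpha"]], beta_sd = boot$sd[["beta"]],
                 gamma_sd = boot$sd[["gamma"]], delta_sd = boot$sd[["delta"]],
                 n_subsets = boot$n_subsets, subset_size = boot$subset_size,
                 seed = boot$seed)
    })
    path <- file.path(out_dir, "stable_fits.csv")
    utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
    outputs <- c(outputs, path)
    log_info("stable_fit: fitted %d condition(s)", length(rows))
  }

  if ("scan" %in% stages) {
    scan <- rank_sum_scan(
      cumulative_distance_matrix(filtered$treated$kept, "treated"),
      cumulative_distance_matrix(filtered$vehicle$kept, "vehicle"),
      alpha = cfg$alpha %||% 0.0001)
    path <- file.path(out_dir, "rank_sum_scan.csv")
    utils::write.csv(scan$table, path, row.names = FALSE)
    outputs <- c(outputs, path)
    log_info("scan: earliest significant time = %s min",
             format(scan$earliest_significant_time))
  }

  fccs_tab <- NULL
  if ("simulate_fccs" %in% stages) {
    scfg <- fccs_sim_config(kd_true = cfg$kd_true %||% 100,
                            n_cells = cfg$fccs_n_cells %||% 30,
                            seed = cfg$seed %||% 1)
    fccs_tab <- simulate_fccs_experiment(scfg)$table
    path <- file.path(out_dir, "fccs_measurements.csv")
    utils::write.csv(fccs_tab, path, row.names = FALSE)
    outputs <- c(outputs, path)
    log_info("simulate_fccs: %d cells", nrow(fccs_tab))
  }

  if ("fccs" %in% stages) {
    if (is.null(fccs_tab))
      fccs_tab <- utils::read.csv(cfg$fccs_table,
                                  stringsAsFactors = FALSE)
    proc <- process_fccs_table(
      fccs_tab, effective_volume = cfg$effective_volume %||% 0.57e-15)
    path <- file.path(out_dir, "fccs_processed.csv")
    utils::write.csv(proc, path, row.names = FALSE)
    outputs <- c(outputs, path)
    kd <- fit_kd(proc[proc$qc_pass, ], ci_level = cfg$ci_level %||% 0.95)
    path2 <- file.path(out_dir, "kd_fit.csv")
    utils::write.csv(
      data.frame(kd_nM = kd$kd, ci_level = kd$ci[["level"]],
                 ci_lower = kd$ci[["lower"]], ci_upper = kd$ci[["upper"]],
                 n_used = kd$n_used, n_excluded = length(kd$excluded)),
      path2, row.names = FALSE)
    outputs <- c(outputs, path2)
    log_info("fccs: %d/%d measurements pass QC; Kd = %.3g nM",
             sum(proc$qc_pass), nrow(proc), kd$kd)
  }

  speeds <- NULL
  if ("simulate_speeds" %in% stages) {
    speeds <- simulate_growth_speeds(seed = cfg$seed %||% 1)
    path <- file.path(out_dir, "growth_speeds.csv")
    utils::write.csv(speeds, path, row.names = FALSE)
    outputs <- c(outputs, path)
    log_info("simulate_speeds: %d events", nrow(speeds))
  }

  if ("tertiles" %in% stages) {
    if (is.null(speeds))
      speeds <- utils::read.csv(cfg$speeds_table, stringsAsFactors = FALSE)
    ts <- tertile_analysis(speeds,
                           cfg$reference_condition %||% "vehicle")
    path <- file.path(out_dir, "tertiles.csv")
    utils::write.csv(ts$table, path, row.names = FALSE)
    outputs <- c(outputs, path)
    log_info("tertiles: edges %.3g / %.3g um/min", ts$edges[1],
             ts$edges[2])
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("cellwalk")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = cfg,
    outputs = lapply(outputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  log_info("wrote manifest with %d output(s)", length(outputs))
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.load_config <- function(config) {
  if (is.list(config)) return(config)
  stopifnot(is.character(config), length(config) == 1L)
  if (!file.exists(config))
    stop("config file not found: ", config, call. = FALSE)
  if (grepl("\\.ya?ml$", config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package",
           call. = FALSE)
    yaml::read_yaml(config)
  } else {
    jsonlite::read_json(config, simplifyVector = TRUE)
  }
}

.validate_config <- function(cfg) {
  problems <- character(0)
  if (is.null(cfg$stages) || length(cfg$stages) == 0)
    problems <- c(problems, "`stages` must name at least one stage")
  known <- c("simulate_walks", "tracks", "stable_fit", "scan",
             "simulate_fccs", "fccs", "simulate_speeds", "tertiles")
  bad <- setdiff(cfg$stages, known)
  if (length(bad) > 0)
    problems <- c(problems, paste0("unknown stage(s): ",
                                   paste(bad, collapse = ", ")))
  if (is.null(cfg$out_dir))
    problems <- c(problems, "`out_dir` is required")
  if (!is.null(cfg$seed) && cfg$seed != as.integer(cfg$seed))
    problems <- c(problems, "`seed` must be an integer")
  if (!is.null(cfg$alpha) && (cfg$alpha <= 0 || cfg$alpha >= 1))
    problems <- c(problems, "`alpha` must lie in (0, 1)")
  if (!is.null(cfg$min_speed) && cfg$min_speed < 0)
    problems <- c(problems, "`min_speed` must be >= 0")
  for (key in c("tracks_vehicle", "tracks_treated", "fccs_table",
                "speeds_table"))
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]]))
      problems <- c(problems, paste0("`", key, "` input does not exist: ",
                                     cfg[[key]]))
  if (length(problems) > 0)
    stop("invalid pipeline config:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  invisible(TRUE)
}

.params_from_cfg <- function(x, default) {
  if (is.null(x)) return(default)
  stable_params(x$alpha, x$beta %||% 0, x$gamma, x$delta)
}
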