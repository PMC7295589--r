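#' Walk-cohort simulation configuration
#'
#' Describes a two-condition single-cell migration experiment: step
#' lengths follow a condition-specific alpha-stable law, headings are
#' isotropic, and the treated condition switches from the vehicle law to
#' its own law at a configurable frame (emulating drug addition part-way
#' through acquisition; the default `shift_time = 1` applies the treated
#' law from the start).
#'
#' Defaults mirror a 24 h brightfield acquisition at 10-min intervals
#' with on the order of 100 tracked cells per condition and step lengths
#' of a few micrometres: heavy-tailed vehicle steps
#' (alpha 1.5, gamma 0.9, delta 2.6 um) and a treated law with the
#' location and scale pulled down, i.e. fewer long relocating steps.
#'
#' @param params_vehicle,params_treated [stable_params()] step-length
#'   laws (um).
#' @param n_cells cells per condition.
#' @param n_frames frames per track (steps = `n_frames - 1`).
#' @param frame_interval minutes between frames.
#' @param shift_time frame index (1-based step index) at which the
#'   treated condition switches from the vehicle law to the treated law.
#' @param seed integer seed.
#' @return A `walk_sim_config` list.
#' @export
walk_sim_config <- function(
    params_vehicle = stable_params(1.5, 0, 0.9, 2.6),
    params_treated = stable_params(1.5, 0, 0.7, 2.1),
    n_cells = 100, n_frames = 145, frame_interval = 10,
    shift_time = 1, seed = 1) {
  stopifnot(inherits(params_vehicle, "stable_params"),
            inherits(params_treated, "stable_params"),
            n_cells >= 1, n_frames >= 2,
            shift_time >= 1, shift_time <= n_frames)
  structure(list(params_vehicle = params_vehicle,
                 params_treated = params_treated,
                 n_cells = as.integer(n_cells),
                 n_frames = as.integer(n_frames),
                 frame_interval = frame_interval,
                 shift_time = as.integer(shift_time),
                 seed = as.integer(seed)),
            class = "walk_sim_config")
}

# draw n non-negative stable step lengths by rejection resampling --
# deliberately i.i.d. from the conditional law rather than a truncated fit
.sample_steps_nonneg <- function(n, params, max_iter = 1000L) {
  out <- numeric(0)
  total_drawn <- 0; total_kept <- 0
  while (length(out) < n) {
    draw <- sample_stable(max(n, 64L), params)
    total_drawn <- total_drawn + length(draw)
    draw <- draw[draw >= 0]
    total_kept <- total_kept + length(draw)
    if (total_drawn >= 256 && total_kept / total_drawn < 0.5)
      stop("step-length law is mostly negative (rejection rate > 50%); ",
           "choose a larger delta or smaller gamma", call. = FALSE)
    out <- c(out, draw)
    max_iter <- max_iter - 1L
    if (max_iter <= 0L) stop("rejection sampling failed", call. = FALSE)
  }
  out[seq_len(n)]
}

#' Simulate a two-condition Levy-walk cohort
#'
#' Per frame, each cell takes a step whose length is drawn from the
#' condition's alpha-stable law (rejection-resampled to be non-negative)
#' in a heading drawn uniformly on \[0, 2 pi). Each cell gets its own
#' deterministic RNG substream derived from the cohort seed, so cohorts
#' are reproducible regardless of evaluation order.
#'
#' @param cfg a [walk_sim_config()].
#' @return A list with `vehicle` and `treated`, each a named list of
#'   [trajectory()] objects.
#' @export
simulate_levy_walk_cohort <- function(cfg = walk_sim_config()) {
  stopifnot(inherits(cfg, "walk_sim_config"))
  sim_cell <- function(cell_seed, id, params_by_step) {
    with_seed(cell_seed, {
      n_steps <- cfg$n_frames - 1L
      lens <- numeric(n_steps)
      for (p in unique(params_by_step)) {
        idx <- which(params_by_step == p)
        prm <- if (p == 1L) cfg$params_vehicle else cfg$params_treated
        lens[idx] <- .sample_steps_nonneg(length(idx), prm)
      }
      theta <- stats::runif(n_steps, 0, 2 * pi)
      trajectory(id,
                 t = (0:n_steps) * cfg$frame_interval,
                 x = c(0, cumsum(lens * cos(theta))),
                 y = c(0, cumsum(lens * sin(theta))),
                 frame_interval = cfg$frame_interval)
    })
  }
  n_steps <- cfg$n_frames - 1L
  veh_steps <- rep(1L, n_steps)
  trt_steps <- ifelse(seq_len(n_steps) >= cfg$shift_time, 2L, 1L)
  # substreams: distinct 31-bit seeds per cell, fixed scheme
  sub <- function(k) (cfg$seed * 10007L + k) %% .Machine$integer.max
  vehicle <- lapply(seq_len(cfg$n_cells), function(i)
    sim_cell(sub(i), sprintf("veh_%03d", i), veh_steps))
  treated <- lapply(seq_len(cfg$n_cells), function(i)
    sim_cell(sub(cfg$n_cells + i), sprintf("trt_%03d", i), trt_steps))
  names(vehicle) <- vapply(vehicle, `[[`, character(1), "track_id")
  names(treated) <- vapply(treated, `[[`, character(1), "track_id")
  list(vehicle = vehicle, treated = treated)
}

#' FCCS experiment simulation configuration
#'
#' Describes a synthetic FCCS binding experiment: per cell, total
#' green-/red-labelled concentrations are drawn from expression ranges,
#' the complex concentration follows the binding isotherm at the
#' configured true Kd (or is forced to the positive/negative control
#' limit), amplitudes are derived by inverting the concentration
#' relations, and full correlation curves are synthesised from the
#' diffusion model with multiplicative Gaussian noise. QC failures
#' (low CPM / high photobleach) are injected at configured rates.
#'
#' Defaults reflect the published measurement scale: ~30 cells, totals of
#' tens to hundreds of nM in a 0.57 fL volume, 2% curve noise.
#'
#' @param kd_true true dissociation constant (nM).
#' @param green_range,red_range expression ranges (nM) for the totals.
#' @param curve_noise_sd multiplicative sd applied to curve G values.
#' @param conc_noise_sd multiplicative sd applied to the complex
#'   concentration before amplitudes are formed.
#' @param qc_fail_rate probability a cell is given a QC-failing CPM or
#'   photobleach value.
#' @param control_mode `"interacting"` (use the isotherm),
#'   `"tandem_fusion"` (complex = totals; positive control) or
#'   `"independent"` (complex = 0; negative control).
#' @param n_cells number of cells.
#' @param effective_volume litres.
#' @param tau_d_free,tau_d_complex diffusion times (s) of free and bound
#'   species used for curve synthesis.
#' @param seed integer seed.
#' @return An `fccs_sim_config` list.
#' @export
fccs_sim_config <- function(kd_true = 100, green_range = c(30, 80),
                            red_range = c(20, 400),
                            curve_noise_sd = 0.02, conc_noise_sd = 0,
                            qc_fail_rate = 0,
                            control_mode = c("interacting",
                                             "tandem_fusion",
                                             "independent"),
                            n_cells = 30, effective_volume = 0.57e-15,
                            tau_d_free = 5e-4, tau_d_complex = 2e-3,
                            seed = 1) {
  control_mode <- match.arg(control_mode)
  stopifnot(kd_true >= 0, curve_noise_sd >= 0, conc_noise_sd >= 0,
            qc_fail_rate >= 0, qc_fail_rate <= 1, n_cells >= 1)
  structure(list(kd_true = kd_true, green_range = green_range,
                 red_range = red_range, curve_noise_sd = curve_noise_sd,
                 conc_noise_sd = conc_noise_sd,
                 qc_fail_rate = qc_fail_rate, control_mode = control_mode,
                 n_cells = as.integer(n_cells),
                 effective_volume = effective_volume,
                 tau_d_free = tau_d_free, tau_d_complex = tau_d_complex,
                 seed = as.integer(seed)),
            class = "fccs_sim_config")
}

# complex concentration from the single-site isotherm given totals + Kd:
# smaller root of C^2 - (G + R + Kd) C + G R = 0
.complex_from_kd <- function(green_total, red_total, kd) {
  b <- green_total + red_total + kd
  (b - sqrt(b^2 - 4 * green_total * red_total)) / 2
}

#' Simulate an FCCS experiment
#'
#' @param cfg an [fccs_sim_config()].
#' @param lags lag grid (s) for the synthesised curves; defaults to 160
#'   log-spaced points over 1e-6..1 s.
#' @return A list with `table` (one row per cell: true concentrations,
#'   amplitudes, CPM/photobleach QC fields) and `curves` (per cell, a
#'   list of three [correlation_curve()] objects: green_auto, red_auto,
#'   cross).
#' @export
simulate_fccs_experiment <- function(cfg = fccs_sim_config(),
                                     lags = NULL) {
  stopifnot(inherits(cfg, "fccs_sim_config"))
  if (is.null(lags)) lags <- 10^seq(-6, 0, length.out = 160)
  to_nM <- 1e9 / (.N_AVOGADRO * cfg$effective_volume)  # nM per molecule
  with_seed(cfg$seed, {
    rows <- list(); curves <- list()
    for (i in seq_len(cfg$n_cells)) {
      g_tot <- stats::runif(1, cfg$green_range[1], cfg$green_range[2])
      r_tot <- stats::runif(1, cfg$red_range[1], cfg$red_range[2])
      cx <- switch(cfg$control_mode,
        interacting = .complex_from_kd(g_tot, r_tot, cfg$kd_true),
        tandem_fusion = {r_tot <- g_tot; g_tot},
        independent = 0)
      if (cfg$conc_noise_sd > 0 && cx > 0)
        cx <- min(cx * exp(stats::rnorm(1, 0, cfg$conc_noise_sd)),
                  min(g_tot, r_tot))
      # invert the amplitude relations
      Gg0 <- to_nM / g_tot
      Gr0 <- to_nM / r_tot
      Gx0 <- cx * Gg0 * Gr0 / to_nM
      # fractions of slow (complex) diffusers in each autocorrelation
      f_slow_g <- cx / g_tot
      f_slow_r <- cx / r_tot
      mk_curve <- function(channel, G0, f_slow) {
        nc <- if (channel == "cross") 1L else 2L
        cc <- acf_fit_config(n_components = nc,
                             triplet = FALSE,
                             effective_volume = cfg$effective_volume)
        f <- if (nc == 2L) c(1 - f_slow, f_slow) else 1
        td <- if (nc == 2L) c(cfg$tau_d_free, cfg$tau_d_complex) else
          cfg$tau_d_complex
        g <- correlation_model(lags, N = 1 / G0, f = f, tau_d = td,
                               cfg = cc)
        if (cfg$curve_noise_sd > 0)
          g <- g * (1 + stats::rnorm(length(g), 0, cfg$curve_noise_sd))
        correlation_curve(channel, lags, g)
      }
      cell_curves <- list(
        green_auto = mk_curve("green_auto", Gg0, f_slow_g),
        red_auto = mk_curve("red_auto", Gr0, f_slow_r),
        cross = if (Gx0 > 0) mk_curve("cross", Gx0, 1) else
          correlation_curve("cross", lags,
                            stats::rnorm(length(lags), 0,
                                         cfg$curve_noise_sd * 1e-3)))
      fail <- stats::runif(1) < cfg$qc_fail_rate
      rows[[i]] <- data.frame(
        cell_id = sprintf("cell_%03d", i),
        green_total_true = g_tot, red_total_true = r_tot,
        complex_true = cx,
        Gg0 = Gg0, Gr0 = Gr0, Gx0 = Gx0,
        cpm_green_khz = if (fail && stats::runif(1) < 0.5) 0.5 else
          stats::runif(1, 2, 8),
        cpm_red_khz = stats::runif(1, 2, 8),
        bleach_green = stats::runif(1, 0, 0.08),
        bleach_red = if (fail) 0.2 else stats::runif(1, 0, 0.08))
      curves[[i]] <- cell_curves
    }
    tab <- do.call(rbind, rows)
    names(curves) <- tab$cell_id
    list(table = tab, curves = curves)
  })
}

#' Simulate microtubule growth-speed event tables
#'
#' Log-normal base speeds for the reference condition; the treated
#' condition applies a multiplicative factor to the upper tail (events
#' above the reference 2/3 quantile), emulating a selective change in
#' fast polymerisation events. Defaults match the scale of EB3
#' comet-tracking experiments: ~9000 events per condition with median
#' speed around 11 um/min.
#'
#' @param n_ref,n_treated event counts (>= 3).
#' @param meanlog,sdlog log-normal parameters of the base speed law
#'   (um/min).
#' @param fast_shift multiplicative factor applied to treated upper-tail
#'   speeds (1 = no shift).
#' @param seed integer seed.
#' @param ref_label,treated_label condition labels.
#' @return A data.frame with columns `condition`, `growth_speed_um_min`.
#' @export
simulate_growth_speeds <- function(n_ref = 9149, n_treated = 9669,
                                   meanlog = log(11), sdlog = 0.35,
                                   fast_shift = 1.05, seed = 1,
                                   ref_label = "vehicle",
                                   treated_label = "dex") {
  stopifnot(n_ref >= 3, n_treated >= 3)
  if (!is.finite(meanlog) || !is.finite(sdlog) || sdlog <= 0 ||
      fast_shift <= 0)
    stop("invalid distribution parameters", call. = FALSE)
  with_seed(seed, {
    ref <- stats::rlnorm(n_ref, meanlog, sdlog)
    trt <- stats::rlnorm(n_treated, meanlog, sdlog)
    cut <- stats::quantile(ref, 2 / 3, names = FALSE)
    trt[trt > cut] <- trt[trt > cut] * fast_shift
    rbind(data.frame(condition = ref_label, growth_speed_um_min = ref),
          data.frame(condition = treated_label,
                     growth_speed_um_min = trt))
  })
}
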