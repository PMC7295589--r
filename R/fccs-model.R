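#' FCCS fit configuration
#'
#' Settings shared by all correlation-curve fits: the structural parameter
#' S (axial:lateral ratio of the confocal detection volume, fixed at 4),
#' the number of diffusing components (two for autocorrelation; the
#' cross-correlation of a single complex species is fitted with one),
#' whether a triplet-blinking term is included (on for autocorrelation,
#' off for cross-correlation), and the calibrated effective confocal
#' volume (0.57 fL) used to convert amplitudes to molar concentrations.
#'
#' @param S structural parameter (> 0), default 4.
#' @param n_components 1 or 2 diffusing components.
#' @param triplet logical; include the triplet term.
#' @param effective_volume effective confocal volume in litres,
#'   default 0.57e-15.
#' @return An `acf_fit_config` list.
#' @export
acf_fit_config <- function(S = 4, n_components = 2, triplet = TRUE,
                           effective_volume = 0.57e-15) {
  stopifnot(S > 0, n_components %in% c(1, 2), effective_volume > 0)
  structure(list(S = S, n_components = as.integer(n_components),
                 triplet = isTRUE(triplet),
                 effective_volume = effective_volume),
            class = "acf_fit_config")
}

#' A measured correlation curve
#'
#' @param channel one of `"green_auto"`, `"red_auto"`, `"cross"`.
#' @param lags lag times in seconds, strictly increasing, > 0.
#' @param G correlation values at each lag.
#' @param compartment `"cytoplasm"` or `"nucleus"`.
#' @param runs optional matrix of per-run curves (lags x runs, e.g. the
#'   five 5-s repeats of a point measurement) used for inverse-variance
#'   weighting.
#' @return A `correlation_curve` object.
#' @export
correlation_curve <- function(channel, lags, G,
                              compartment = c("cytoplasm", "nucleus"),
                              runs = NULL) {
  channel <- match.arg(channel, c("green_auto", "red_auto", "cross"))
  compartment <- match.arg(compartment)
  stopifnot(is.numeric(lags), is.numeric(G), length(lags) == length(G))
  if (any(lags <= 0) || is.unsorted(lags, strictly = TRUE))
    stop("`lags` must be strictly increasing and positive", call. = FALSE)
  if (any(!is.finite(G)))
    stop("`G` contains non-finite values", call. = FALSE)
  structure(list(channel = channel, lags = lags, G = G,
                 compartment = compartment, runs = runs),
            class = "correlation_curve")
}

#' Multi-component 3D diffusion correlation model
#'
#' The fit model for confocal FCS/FCCS curves:
#' \deqn{G(\tau) = \left[1 + \frac{T}{1-T} e^{-\tau/\tau_T}\right]
#'   \frac{1}{N} \sum_i f_i \left(1 + \frac{\tau}{\tau_{D,i}}\right)^{-1}
#'   \left(1 + \frac{\tau}{S^2 \tau_{D,i}}\right)^{-1/2}}
#' with mean occupancy `N`, component fractions `f_i` summing to one,
#' diffusion times `tau_d`, structural parameter `S`, and (optionally) a
#' triplet fraction `T` with relaxation time `tau_t`. With the triplet
#' term off, `G(0) = 1/N`.
#'
#' @param lag lag times (s), >= 0.
#' @param N mean occupancy (> 0).
#' @param f fractions of each component (recycled/normalised to sum 1).
#' @param tau_d diffusion times (s), one per component.
#' @param T_trip triplet fraction in \[0, 1).
#' @param tau_t triplet relaxation time (s).
#' @param cfg an [acf_fit_config()]; supplies `S` and whether the triplet
#'   factor is applied.
#' @return Numeric vector of model G values.
#' @examples
#' correlation_model(0, N = 10, f = 1, tau_d = 1e-4,
#'                   cfg = acf_fit_config(n_components = 1, triplet = FALSE))
#' @export
correlation_model <- function(lag, N, f, tau_d, T_trip = 0, tau_t = 1e-5,
                              cfg = acf_fit_config()) {
  stopifnot(inherits(cfg, "acf_fit_config"), length(f) == length(tau_d))
  if (any(lag < 0)) stop("`lag` must be >= 0", call. = FALSE)
  if (N <= 0) stop("`N` must be > 0", call. = FALSE)
  if (T_trip < 0 || T_trip >= 1)
    stop("triplet fraction must lie in [0, 1)", call. = FALSE)
  f <- f / sum(f)
  comp <- vapply(seq_along(f), function(i)
    f[i] / ((1 + lag / tau_d[i]) * sqrt(1 + lag / (cfg$S^2 * tau_d[i]))),
    numeric(length(lag)))
  diff_sum <- rowSums(matrix(comp, nrow = length(lag)))
  trip <- if (cfg$triplet && T_trip > 0)
    1 + T_trip / (1 - T_trip) * exp(-lag / tau_t) else rep(1, length(lag))
  trip * diff_sum / N
}

#' Fit the diffusion model to a correlation curve
#'
#' Weighted least squares over a multi-start grid of diffusion times
#' (5 x 5 starts, log-spaced over 1e-5..1 s), refined by quasi-Newton
#' optimisation in transformed coordinates (log N, logit f, log tau_d,
#' logit T, log tau_t). Weights are the inverse variance across per-run
#' repeat curves when available, otherwise uniform. Components are
#' reported with `tau_d1 <= tau_d2`.
#'
#' @param curve a [correlation_curve()].
#' @param cfg an [acf_fit_config()]. By convention autocorrelation curves
#'   are fitted with two components and a triplet term, cross-correlation
#'   curves with one component and no triplet.
#' @return An `acf_fit` object: `N`, `f` (fractions), `tau_d`, `T_trip`,
#'   `tau_t`, `G0` (the fitted zero-lag amplitude of the diffusion part,
#'   1/N), `residual_norm`, `channel`, `compartment`, `converged`.
#' @export
fit_correlation_curve <- function(curve, cfg = NULL) {
  stopifnot(inherits(curve, "correlation_curve"))
  if (is.null(cfg))
    cfg <- if (curve$channel == "cross")
      acf_fit_config(n_components = 1, triplet = FALSE)
    else acf_fit_config(n_components = 2, triplet = TRUE)
  lag <- curve$lags; G <- curve$G
  if (length(lag) < 20 || log10(max(lag) / min(lag)) < 3)
    stop("curve must have >= 20 lag points spanning >= 3 decades",
         call. = FALSE)
  if (max(abs(G)) < 1e-6)
    stop("flat curve: no correlation amplitude to fit", call. = FALSE)
  w <- if (!is.null(curve$runs) && ncol(curve$runs) >= 2) {
    v <- apply(curve$runs, 1, stats::var)
    1 / pmax(v, max(v) * 1e-6)
  } else rep(1, length(G))

  nc <- cfg$n_components
  obj <- function(par) {
    p <- .acf_decode(par, nc, cfg$triplet)
    r <- G - correlation_model(lag, p$N, p$f, p$tau_d, p$T_trip, p$tau_t,
                               cfg)
    sum(w * r^2)
  }
  # multi-start over diffusion times, log-spaced 1e-5..1 s
  tgrid <- 10^seq(-5, 0, length.out = 5)
  starts <- if (nc == 2) {
    pairs <- expand.grid(t1 = tgrid, t2 = tgrid)
    pairs <- pairs[pairs$t1 <= pairs$t2, , drop = FALSE]
    lapply(seq_len(nrow(pairs)), function(i)
      .acf_encode(max(1 / max(G), 0.1), c(0.5, 0.5),
                  c(pairs$t1[i], pairs$t2[i]), 0.05, 5e-6, nc,
                  cfg$triplet))
  } else {
    lapply(tgrid, function(t1)
      .acf_encode(max(1 / max(G), 0.1), 1, t1, 0.05, 5e-6, nc,
                  cfg$triplet))
  }
  # rank starts by their raw objective and polish only the best few
  sval <- vapply(starts, obj, numeric(1))
  starts <- starts[order(sval)][seq_len(min(4L, length(starts)))]
  best <- NULL
  for (s in starts) {
    o <- tryCatch(stats::optim(s, obj, method = "BFGS",
                               control = list(maxit = 500,
                                              reltol = 1e-12)),
                  error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best))
    stop("correlation-curve fit failed to converge from every start",
         call. = FALSE)
  p <- .acf_decode(best$par, nc, cfg$triplet)
  ord <- order(p$tau_d)
  structure(list(N = p$N, f = p$f[ord], tau_d = p$tau_d[ord],
                 T_trip = p$T_trip, tau_t = p$tau_t, G0 = 1 / p$N,
                 residual_norm = sqrt(best$value),
                 channel = curve$channel, compartment = curve$compartment,
                 converged = best$convergence == 0),
            class = "acf_fit")
}

#' @export
print.acf_fit <- function(x, ...) {
  cat(sprintf("<acf_fit %s/%s> N = %.3g (G0 = %.3g)\n", x$channel,
              x$compartment, x$N, x$G0))
  for (i in seq_along(x$f))
    cat(sprintf("  component %d: f = %.3f, tau_d = %.3g s\n", i, x$f[i],
                x$tau_d[i]))
  if (x$T_trip > 0)
    cat(sprintf("  triplet: T = %.3f, tau_t = %.3g s\n", x$T_trip,
                x$tau_t))
  invisible(x)
}

.acf_encode <- function(N, f, tau_d, T_trip, tau_t, nc, triplet) {
  par <- log(N)
  if (nc == 2) par <- c(par, stats::qlogis(f[1]))
  par <- c(par, log(tau_d))
  if (triplet) par <- c(par, stats::qlogis(min(max(T_trip, 1e-4), 0.8)),
                        log(tau_t))
  par
}

.acf_decode <- function(par, nc, triplet) {
  i <- 1
  N <- exp(par[i]); i <- i + 1
  if (nc == 2) {
    f1 <- stats::plogis(par[i]); i <- i + 1
    f <- c(f1, 1 - f1)
  } else f <- 1
  tau_d <- exp(par[i:(i + nc - 1)]); i <- i + nc
  if (triplet) {
    T_trip <- stats::plogis(par[i]) * 0.999
    tau_t <- exp(par[i + 1])
  } else {
    T_trip <- 0; tau_t <- 1e-5
  }
  list(N = N, f = f, tau_d = tau_d, T_trip = T_trip, tau_t = tau_t)
}
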