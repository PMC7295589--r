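#' Avogadro constant (1/mol)
#' @keywords internal
.N_AVOGADRO <- 6.02214076e23

#' Quality-control filter for FCCS point measurements
#'
#' A measurement is rejected if counts per molecule are below 1 kHz in
#' either channel, or if either channel photobleached by more than 10%
#' over the run. Both cuts are strict (`< 1` kHz, `> 0.10`), so boundary
#' values pass.
#'
#' @param cpm_green,cpm_red counts per molecule (kHz).
#' @param bleach_green,bleach_red photobleached fraction in \[0, 1\].
#' @param cpm_min kHz threshold (default 1).
#' @param bleach_max fraction threshold (default 0.10).
#' @return A list with `qc_pass` (logical) and `reasons` (character
#'   vector, empty when passing).
#' @export
qc_filter <- function(cpm_green, cpm_red, bleach_green, bleach_red,
                      cpm_min = 1, bleach_max = 0.10) {
  vals <- c(cpm_green = cpm_green, cpm_red = cpm_red,
            bleach_green = bleach_green, bleach_red = bleach_red)
  if (any(!is.finite(vals)))
    stop("QC fields must be finite", call. = FALSE)
  if (cpm_green < 0 || cpm_red < 0)
    stop("negative CPM is not physical", call. = FALSE)
  if (bleach_green < 0 || bleach_green > 1 || bleach_red < 0 ||
      bleach_red > 1)
    stop("photobleach fractions must lie in [0, 1]", call. = FALSE)
  reasons <- character(0)
  if (cpm_green < cpm_min) reasons <- c(reasons, "low-CPM-green")
  if (cpm_red < cpm_min) reasons <- c(reasons, "low-CPM-red")
  if (bleach_green > bleach_max) reasons <- c(reasons, "bleach-green")
  if (bleach_red > bleach_max) reasons <- c(reasons, "bleach-red")
  list(qc_pass = length(reasons) == 0, reasons = reasons)
}

#' Molar concentrations from correlation amplitudes
#'
#' Converts fitted zero-lag amplitudes to molar concentrations via the
#' calibrated effective confocal volume: the green-channel occupancy is
#' `1/Gg0`, so `[green]_total = 1/(Gg0 * N_A * V_eff)` (likewise red),
#' and the co-diffusing complex concentration follows from the
#' cross-amplitude as `[complex] = Gx0/(Gg0 * Gr0 * N_A * V_eff)`.
#' An unphysical complex exceeding either total by up to 5% (fit noise)
#' is capped at the smaller total with a warning; a larger excess is an
#' error.
#'
#' @param Gg0,Gr0 green/red autocorrelation amplitudes (> 0).
#' @param Gx0 cross-correlation amplitude (>= 0).
#' @param effective_volume effective confocal volume (litres),
#'   default 0.57e-15.
#' @return Named numeric vector `green_total`, `red_total`, `complex`
#'   in nM.
#' @examples
#' concentrations_from_amplitudes(0.1, 0.1, 0)  # ~29.13 nM each, 0 complex
#' @export
concentrations_from_amplitudes <- function(Gg0, Gr0, Gx0,
                                           effective_volume = 0.57e-15) {
  stopifnot(is.finite(Gg0), is.finite(Gr0), is.finite(Gx0))
  if (Gg0 <= 0 || Gr0 <= 0)
    stop("autocorrelation amplitudes must be > 0", call. = FALSE)
  if (Gx0 < 0)
    stop("cross-correlation amplitude must be >= 0", call. = FALSE)
  if (Gx0 > min(Gg0, Gr0) * 1.05)
    stop("unphysical cross amplitude: Gx0 exceeds min(Gg0, Gr0) by > 5%",
         call. = FALSE)
  to_nM <- 1e9 / (.N_AVOGADRO * effective_volume)
  green <- to_nM / Gg0
  red <- to_nM / Gr0
  complex <- Gx0 * to_nM / (Gg0 * Gr0)
  if (complex > min(green, red)) {
    # warn only beyond float noise (the fully bound limit lands exactly
    # on the boundary up to rounding)
    if (complex > min(green, red) * (1 + 1e-9))
      warning("complex concentration capped at min(green, red) total")
    complex <- min(green, red)
  }
  c(green_total = green, red_total = red, complex = complex)
}

#' Relative cross-correlation (RCC)
#'
#' The percentage of the red-labelled species bound to the green-labelled
#' species, from the standard FCCS amplitude relation
#' `bound fraction = Gx(0)/Gg(0)` (equivalently `[complex]/[red]_total`).
#' The complementary ratio `Gx0/Gr0` (fraction of the green species
#' bound) is available via `denominator = "red_auto"`. Values are clipped
#' to \[0, 100\] with a warning outside.
#'
#' @param Gg0,Gr0 autocorrelation amplitudes; the denominator amplitude
#'   must be > 0.
#' @param Gx0 cross-correlation amplitude.
#' @param denominator which autocorrelation amplitude divides `Gx0`:
#'   `"green_auto"` (default) or `"red_auto"`.
#' @return RCC in percent.
#' @export
relative_cross_correlation <- function(Gg0, Gr0 = NULL, Gx0,
                                       denominator = c("green_auto",
                                                       "red_auto")) {
  denominator <- match.arg(denominator)
  den <- if (denominator == "green_auto") Gg0 else Gr0
  if (is.null(den) || !is.finite(den) || den <= 0)
    stop("denominator amplitude must be > 0", call. = FALSE)
  rcc <- 100 * Gx0 / den
  if (rcc < 0 || rcc > 100) {
    if (rcc < -1e-7 || rcc > 100 * (1 + 1e-9))
      warning("RCC ", signif(rcc, 4), "% outside [0, 100]; clipped")
    rcc <- min(max(rcc, 0), 100)
  }
  rcc
}

#' Fit the in vivo dissociation constant
#'
#' Given per-cell FCCS concentrations, fits the single-site binding
#' isotherm
#' \deqn{\frac{[complex]}{[green]_{total}} =
#'   \frac{[red]_{total} - [complex]}{K_d + [red]_{total} - [complex]}}
#' by least squares of the bound fraction `y = complex/green_total`
#' against the unbound partner concentration
#' `x = red_total - complex`. Before fitting, measurements whose
#' `green_total` or `red_total` lies more than `sd_cut` standard
#' deviations from the respective mean are excluded (single pass, each
#' channel tested separately). The confidence interval comes from the
#' parameter covariance of the fit (Wald, on log Kd so the interval
#' respects positivity); a profile-likelihood interval is available with
#' `ci_method = "profile"`.
#'
#' @param measurements data.frame with columns `green_total`, `red_total`,
#'   `complex` (nM). An optional logical `qc_pass` column restricts the
#'   fit to passing rows.
#' @param ci_level confidence level (default 0.95).
#' @param sd_cut outlier cut in standard deviations (default 3).
#' @param ci_method `"wald"` (default) or `"profile"`.
#' @return A `kd_fit` object: `kd` (nM), `ci` (level, lower, upper),
#'   `excluded` (row indices) with `exclusion_reasons`, `residuals`,
#'   `n_used`.
#' @export
fit_kd <- function(measurements, ci_level = 0.95, sd_cut = 3,
                   ci_method = c("wald", "profile")) {
  ci_method <- match.arg(ci_method)
  m <- as.data.frame(measurements)
  stopifnot(all(c("green_total", "red_total", "complex") %in% names(m)))
  if ("qc_pass" %in% names(m)) m <- m[m$qc_pass, , drop = FALSE]
  if (nrow(m) < 5)
    stop("need >= 5 QC-passing measurements, got ", nrow(m),
         call. = FALSE)

  excl <- integer(0); why <- character(0)
  for (ch in c("green_total", "red_total")) {
    v <- m[[ch]]
    s <- stats::sd(v)
    if (s > 0) {
      out <- which(abs(v - mean(v)) > sd_cut * s)
      excl <- union(excl, out)
      why <- c(why, sprintf("%s outside %g SD (row %d)", ch, sd_cut, out))
    }
  }
  keep <- setdiff(seq_len(nrow(m)), excl)
  if (length(keep) == 0)
    stop("all measurements excluded by the ", sd_cut, "-SD rule",
         call. = FALSE)
  d <- m[keep, , drop = FALSE]

  y <- d$complex / d$green_total
  x <- d$red_total - d$complex
  sse <- function(log_kd) sum((y - x / (exp(log_kd) + x))^2)
  opt <- stats::optimize(sse, c(log(1e-6), log(1e6)), tol = 1e-12)
  log_kd <- opt$minimum
  kd <- exp(log_kd)
  res <- y - x / (kd + x)
  n <- length(y)
  sigma2 <- sum(res^2) / max(n - 1, 1)
  # derivative of the model wrt log Kd: -x kd/(kd + x)^2
  grad <- -x * kd / (kd + x)^2
  se_logkd <- sqrt(sigma2 / sum(grad^2))
  zq <- stats::qnorm(1 - (1 - ci_level) / 2)
  if (ci_method == "wald") {
    lower <- exp(log_kd - zq * se_logkd)
    upper <- exp(log_kd + zq * se_logkd)
  } else {
    # profile: invert the likelihood-ratio statistic for one parameter
    crit <- sse(log_kd) * (1 + stats::qf(ci_level, 1, n - 1) / (n - 1))
    f <- function(lk) sse(lk) - crit
    lower <- tryCatch(
      exp(stats::uniroot(f, c(log_kd - 20, log_kd), tol = 1e-10)$root),
      error = function(e) 0)
    upper <- tryCatch(
      exp(stats::uniroot(f, c(log_kd, log_kd + 20), tol = 1e-10)$root),
      error = function(e) Inf)
  }
  if (kd < 1e-5)
    warning("Kd pinned near the zero boundary; data may be saturated")
  structure(
    list(kd = kd, ci = c(level = ci_level, lower = unname(lower),
                         upper = unname(upper)),
         excluded = excl, exclusion_reasons = why,
         residuals = res, n_used = n, ci_method = ci_method),
    class = "kd_fit")
}

#' @export
print.kd_fit <- function(x, ...) {
  cat(sprintf("<kd_fit> Kd = %.4g nM, %g%% CI [%.4g, %.4g] (%s), n = %d\n",
              x$kd, 100 * x$ci[["level"]], x$ci[["lower"]],
              x$ci[["upper"]], x$ci_method, x$n_used))
  if (length(x$excluded) > 0)
    cat("  excluded rows:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Grade the significance of a Kd difference
#'
#' Refits both data sets at each confidence level of a ladder and reports
#' the highest level at which the two intervals are disjoint, or `"n.s."`
#' if they overlap even at the lowest level.
#'
#' @param measurements_a,measurements_b measurement tables as accepted by
#'   [fit_kd()].
#' @param levels confidence ladder, default `c(0.95, 0.99, 0.999, 0.9999)`.
#' @param ... passed to [fit_kd()].
#' @return A list with `grade` (`"n.s."` or the confidence level as a
#'   number) and the per-level interval table.
#' @export
compare_kd <- function(measurements_a, measurements_b,
                       levels = c(0.95, 0.99, 0.999, 0.9999), ...) {
  levels <- sort(levels)
  tab <- do.call(rbind, lapply(levels, function(lv) {
    fa <- fit_kd(measurements_a, ci_level = lv, ...)
    fb <- fit_kd(measurements_b, ci_level = lv, ...)
    data.frame(level = lv,
               a_lower = fa$ci[["lower"]], a_upper = fa$ci[["upper"]],
               b_lower = fb$ci[["lower"]], b_upper = fb$ci[["upper"]],
               disjoint = fa$ci[["upper"]] < fb$ci[["lower"]] ||
                          fb$ci[["upper"]] < fa$ci[["lower"]])
  }))
  grade <- if (any(tab$disjoint)) max(tab$level[tab$disjoint]) else "n.s."
  list(grade = grade, table = tab)
}

#' Process an FCCS measurement table
#'
#' Applies [qc_filter()] row-wise, converts amplitudes to concentrations
#' and computes RCC for every QC-passing measurement.
#'
#' @param table data.frame with columns `Gg0`, `Gr0`, `Gx0`,
#'   `cpm_green_khz`, `cpm_red_khz`, `bleach_green`, `bleach_red` (plus
#'   any identifier columns, carried through).
#' @param effective_volume litres, default 0.57e-15.
#' @param rcc_denominator passed to [relative_cross_correlation()].
#' @return The input with appended columns `qc_pass`, `qc_reasons`,
#'   `green_total`, `red_total`, `complex` (nM; NA when QC fails), `rcc`.
#' @export
process_fccs_table <- function(table, effective_volume = 0.57e-15,
                               rcc_denominator = "green_auto") {
  t <- as.data.frame(table)
  need <- c("Gg0", "Gr0", "Gx0", "cpm_green_khz", "cpm_red_khz",
            "bleach_green", "bleach_red")
  stopifnot(all(need %in% names(t)))
  out <- lapply(seq_len(nrow(t)), function(i) {
    qc <- qc_filter(t$cpm_green_khz[i], t$cpm_red_khz[i],
                    t$bleach_green[i], t$bleach_red[i])
    if (!qc$qc_pass)
      return(data.frame(qc_pass = FALSE,
                        qc_reasons = paste(qc$reasons, collapse = ";"),
                        green_total = NA_real_, red_total = NA_real_,
                        complex = NA_real_, rcc = NA_real_))
    conc <- concentrations_from_amplitudes(t$Gg0[i], t$Gr0[i], t$Gx0[i],
                                           effective_volume)
    data.frame(qc_pass = TRUE, qc_reasons = "",
               green_total = conc[["green_total"]],
               red_total = conc[["red_total"]],
               complex = conc[["complex"]],
               rcc = relative_cross_correlation(
                 t$Gg0[i], t$Gr0[i], t$Gx0[i],
                 denominator = rcc_denominator))
  })
  cbind(t, do.call(rbind, out))
}
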