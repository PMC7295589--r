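#' Vehicle-anchored tertile analysis of growth speeds
#'
#' Splits the reference (vehicle) condition's growth-speed events into
#' equal thirds by speed and applies the same two bin edges to every
#' other condition -- so treatment-induced shifts show up as unequal bin
#' occupancy and changed within-bin medians rather than moving bins.
#' Edges are the 1/3 and 2/3 empirical quantiles of the reference
#' condition (type-7 linear interpolation); bins are left-open,
#' right-closed, `(-Inf, e1], (e1, e2], (e2, Inf)`, so ties at an edge
#' fall into the lower bin.
#'
#' @param events data.frame with columns `condition` and
#'   `growth_speed_um_min` (> 0).
#' @param reference_condition label of the anchoring condition.
#' @param quantile_type quantile algorithm (default 7).
#' @return A `tertile_summary` object: `edges` (two speeds, um/min),
#'   `reference_condition` and `table` (one row per condition x bin with
#'   `n` and `median_speed`).
#' @export
tertile_analysis <- function(events, reference_condition,
                             quantile_type = 7) {
  ev <- as.data.frame(events)
  stopifnot(all(c("condition", "growth_speed_um_min") %in% names(ev)))
  if (any(ev$growth_speed_um_min <= 0))
    stop("growth speeds must be > 0", call. = FALSE)
  ref <- ev$growth_speed_um_min[ev$condition == reference_condition]
  if (length(ref) == 0)
    stop("reference condition '", reference_condition,
         "' not present in the event table", call. = FALSE)
  if (length(ref) < 3)
    stop("reference condition needs >= 3 events", call. = FALSE)
  edges <- stats::quantile(ref, c(1, 2) / 3, type = quantile_type,
                           names = FALSE)
  bins <- c("slow", "medium", "fast")
  tab <- do.call(rbind, lapply(split(ev, ev$condition), function(d) {
    bin <- cut(d$growth_speed_um_min, c(-Inf, edges, Inf), labels = bins,
               right = TRUE)
    do.call(rbind, lapply(bins, function(b) {
      v <- d$growth_speed_um_min[bin == b]
      data.frame(condition = d$condition[1], bin = b, n = length(v),
                 median_speed = if (length(v)) stats::median(v) else
                   NA_real_)
    }))
  }))
  rownames(tab) <- NULL
  structure(list(reference_condition = reference_condition,
                 edges = edges, table = tab),
            class = "tertile_summary")
}

#' @export
print.tertile_summary <- function(x, ...) {
  cat(sprintf("<tertile_summary> reference '%s', edges %.3g / %.3g um/min\n",
              x$reference_condition, x$edges[1], x$edges[2]))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Step-length frequency distributions
#'
#' Shared-bin frequency curves of pooled step lengths across conditions,
#' the representation in which a treatment that suppresses long
#' relocating steps appears as a left shift of the curve.
#'
#' @param steps named list of numeric step-length vectors, one per
#'   condition.
#' @param bin_width bin width (um).
#' @param normalise when `TRUE` (default) frequencies sum to 1 within
#'   each condition; otherwise raw counts are returned.
#' @return A data.frame with columns `condition`, `mid` (bin midpoint,
#'   um) and `frequency`.
#' @export
step_length_histogram <- function(steps, bin_width = 0.25,
                                  normalise = TRUE) {
  stopifnot(is.list(steps), length(steps) > 0,
            !is.null(names(steps)))
  if (!is.numeric(bin_width) || bin_width <= 0)
    stop("`bin_width` must be > 0", call. = FALSE)
  all_v <- unlist(steps)
  breaks <- seq(floor(min(all_v) / bin_width) * bin_width,
                max(all_v) + bin_width, by = bin_width)
  do.call(rbind, lapply(names(steps), function(cond) {
    h <- graphics::hist(steps[[cond]], breaks = breaks, plot = FALSE)
    freq <- if (normalise) h$counts / sum(h$counts) else h$counts
    data.frame(condition = cond, mid = h$mids, frequency = freq)
  }))
}

#' Earliest-significant-time rank-sum scan
#'
#' At every shared time point, compares the cumulative distances of
#' treated and vehicle cells still tracked at that time with a two-sided
#' Mann-Whitney/Wilcoxon rank-sum test, and reports the earliest time at
#' which the treated median is reduced below the vehicle median with
#' `p < alpha`. No multiplicity correction is applied across the scan:
#' the threshold (default 1e-4) is a per-time-point criterion, which is
#' why it is set so conservatively.
#'
#' Tracks ending before a scanned time point drop out of that time point
#' only. The exact null distribution is used when both groups have at
#' most 50 cells and there are no ties; otherwise the tie-corrected
#' normal approximation (the behaviour of [stats::wilcox.test()]).
#'
#' @param treated,vehicle [cumulative_distance_matrix()] objects on a
#'   common frame interval.
#' @param alpha per-time-point significance threshold (default 0.0001).
#' @param require_reduction if `TRUE` (default) a time point only counts
#'   as a detection when the treated median is below the vehicle median;
#'   set `FALSE` for a direction-free scan.
#' @param min_group smallest group size at which a time point is scanned
#'   (default 2).
#' @return A `rank_sum_scan` object: `table` (per time point: `t_min`,
#'   `n_vehicle`, `n_treated`, `median_vehicle`, `median_treated`,
#'   `p_value`, `significant`), `alpha` and
#'   `earliest_significant_time` (minutes, or `NA` when never reached).
#' @export
rank_sum_scan <- function(treated, vehicle, alpha = 0.0001,
                          require_reduction = TRUE, min_group = 2) {
  stopifnot(inherits(treated, "cum_dist_matrix"),
            inherits(vehicle, "cum_dist_matrix"))
  if (treated$frame_interval != vehicle$frame_interval)
    stop("groups are on different acquisition grids", call. = FALSE)
  at_time <- function(m, k) {
    v <- vapply(m$series, function(s) if (length(s) >= k) s[k] else
      NA_real_, numeric(1))
    v[!is.na(v)]
  }
  n_t <- max(lengths(treated$series))
  n_v <- max(lengths(vehicle$series))
  ks <- 2:min(n_t, n_v)   # skip t = 0 where every distance is 0
  if (length(at_time(treated, 1)) == 0 || length(at_time(vehicle, 1)) == 0)
    stop("empty group at the first time point", call. = FALSE)
  rows <- lapply(ks, function(k) {
    a <- at_time(treated, k); b <- at_time(vehicle, k)
    if (length(a) < min_group || length(b) < min_group) return(NULL)
    # exact null distribution for small tie-free groups; tie-corrected
    # normal approximation otherwise
    use_exact <- length(a) < 50 && length(b) < 50 &&
      !anyDuplicated(c(a, b))
    p <- stats::wilcox.test(a, b, alternative = "two.sided",
                            exact = use_exact,
                            correct = TRUE)$p.value
    med_a <- stats::median(a); med_b <- stats::median(b)
    sig <- p < alpha && (!require_reduction || med_a < med_b)
    data.frame(t_min = treated$frame_interval * (k - 1),
               n_treated = length(a), n_vehicle = length(b),
               median_treated = med_a, median_vehicle = med_b,
               p_value = p, significant = sig)
  })
  tab <- do.call(rbind, rows)
  earliest <- if (!is.null(tab) && any(tab$significant))
    min(tab$t_min[tab$significant]) else NA_real_
  structure(list(table = tab, alpha = alpha,
                 earliest_significant_time = earliest),
            class = "rank_sum_scan")
}

#' @export
print.rank_sum_scan <- function(x, ...) {
  cat(sprintf("<rank_sum_scan> %d time points, alpha = %g\n",
              nrow(x$table), x$alpha))
  if (is.na(x$earliest_significant_time))
    cat("  no significant reduction detected\n")
  else
    cat(sprintf("  earliest significant reduction at t = %g min\n",
                x$earliest_significant_time))
  invisible(x)
}
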