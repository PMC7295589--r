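#' Construct a single-cell trajectory
#'
#' A trajectory is one cell's time-ordered 2-D path: times in minutes and
#' positions in micrometres, as exported by a tracking tool. Times must be
#' strictly increasing and at least two points are required.
#'
#' @param track_id identifier (coerced to character).
#' @param t numeric vector of acquisition times (minutes).
#' @param x,y numeric position vectors (um).
#' @param frame_interval nominal acquisition interval (minutes), e.g. 5 or
#'   10 depending on the imaging protocol.
#' @return A `trajectory` object.
#' @export
trajectory <- function(track_id, t, x, y, frame_interval = 10) {
  track_id <- as.character(track_id)
  stopifnot(length(track_id) == 1L, is.numeric(t), is.numeric(x),
            is.numeric(y), length(t) == length(x), length(t) == length(y))
  if (length(t) < 2L)
    stop("trajectory '", track_id, "' has fewer than 2 points",
         call. = FALSE)
  if (any(!is.finite(t)) || any(!is.finite(x)) || any(!is.finite(y)))
    stop("trajectory '", track_id, "' has non-finite coordinates",
         call. = FALSE)
  if (any(diff(t) <= 0))
    stop("trajectory '", track_id, "' has non-increasing times",
         call. = FALSE)
  structure(list(track_id = track_id, t = t, x = x, y = y,
                 frame_interval = frame_interval),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory '%s'> %d points, t = %g..%g min\n",
              x$track_id, length(x$t), x$t[1], x$t[length(x$t)]))
  invisible(x)
}

#' Read cell tracks from CSV
#'
#' Expects columns `track_id`, `t_min`, `x_um`, `y_um` (header required).
#' Rows with missing coordinates are dropped with a message; duplicate
#' (track, time) pairs are an error.
#'
#' @param path CSV file path.
#' @param frame_interval acquisition interval in minutes.
#' @return A named list of [trajectory()] objects, points sorted by time.
#' @export
load_tracks <- function(path, frame_interval = 10) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("track_id", "t_min", "x_um", "y_um")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0)
    stop("track table ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  bad <- !is.finite(tab$x_um) | !is.finite(tab$y_um) | !is.finite(tab$t_min)
  if (any(bad)) {
    message("load_tracks: dropped ", sum(bad),
            " row(s) with missing coordinates")
    tab <- tab[!bad, , drop = FALSE]
  }
  dup <- duplicated(tab[, c("track_id", "t_min")])
  if (any(dup))
    stop("duplicate (track, time) rows for track(s): ",
         paste(unique(tab$track_id[dup]), collapse = ", "), call. = FALSE)
  trajs <- lapply(split(tab, tab$track_id), function(d) {
    d <- d[order(d$t_min), , drop = FALSE]
    trajectory(d$track_id[1], d$t_min, d$x_um, d$y_um, frame_interval)
  })
  trajs[order(names(trajs))]
}

#' Write cell tracks to CSV
#'
#' Inverse of [load_tracks()]; used by the synthetic generators.
#'
#' @param trajs list of trajectories.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(trajs, path) {
  tab <- do.call(rbind, lapply(trajs, function(tr)
    data.frame(track_id = tr$track_id, t_min = tr$t, x_um = tr$x,
               y_um = tr$y)))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Step lengths of a trajectory
#'
#' The per-frame step length is the planar Euclidean (Pythagorean)
#' distance between consecutive positions:
#' `c = sqrt(a^2 + b^2)` with `a` and `b` the x and y displacements.
#'
#' @param traj a [trajectory()].
#' @return A `step_series` object: `track_id`, numeric `steps` (um, one
#'   per consecutive frame pair) and `dt` (the matching time gaps, min).
#' @examples
#' step_lengths(trajectory("a", c(0, 10), c(0, 3), c(0, 4)))$steps  # 5
#' @export
step_lengths <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  structure(list(track_id = traj$track_id,
                 steps = sqrt(diff(traj$x)^2 + diff(traj$y)^2),
                 dt = diff(traj$t)),
            class = "step_series")
}

#' Kinematic summary of a trajectory
#'
#' Computes the per-track migration statistics:
#' * `total_displacement`: cumulative path length, the sum of all step
#'   lengths -- the "overall distance moved" convention used for
#'   violin-plot displacement readouts (not the straight-line distance);
#' * `net_displacement`: straight-line start-to-end distance;
#' * `median_step_length`: median of the per-frame step lengths;
#' * `mean_speed`: total path length divided by track duration (um/min),
#'   so gaps in acquisition are normalised by the actual elapsed time;
#' * `duration`: minutes from first to last point.
#'
#' @param traj a [trajectory()].
#' @return A one-row data.frame with the fields above plus `track_id` and
#'   `n_points`.
#' @export
kinematics_summary <- function(traj) {
  ss <- step_lengths(traj)
  total <- sum(ss$steps)
  duration <- traj$t[length(traj$t)] - traj$t[1]
  data.frame(
    track_id = traj$track_id,
    n_points = length(traj$t),
    total_displacement = total,
    net_displacement = sqrt((traj$x[length(traj$x)] - traj$x[1])^2 +
                            (traj$y[length(traj$y)] - traj$y[1])^2),
    median_step_length = stats::median(ss$steps),
    mean_speed = total / duration,
    duration = duration)
}

#' Summarise a set of trajectories
#'
#' @param trajs list of trajectories.
#' @return A data.frame with one [kinematics_summary()] row per track.
#' @export
summarise_tracks <- function(trajs) {
  do.call(rbind, c(lapply(trajs, kinematics_summary),
                   list(make.row.names = FALSE)))
}

#' Track filter configuration
#'
#' Stationary debris is discounted by requiring a minimum mean movement
#' speed; the default threshold of 2.5 um/min is applied as a strict
#' inequality ("above 2.5"), so a track at exactly the threshold is
#' rejected.
#'
#' @param min_mean_speed um/min (default 2.5).
#' @param min_track_length minimum number of points (default 2).
#' @param object_size_um imaging-side segmentation size filter, recorded
#'   for provenance only -- it is never applied here because no images are
#'   processed by this package.
#' @return A `track_filter_config` list.
#' @export
track_filter_config <- function(min_mean_speed = 2.5, min_track_length = 2,
                                object_size_um = 25) {
  stopifnot(min_mean_speed >= 0, min_track_length >= 2)
  structure(list(min_mean_speed = min_mean_speed,
                 min_track_length = min_track_length,
                 object_size_um = object_size_um),
            class = "track_filter_config")
}

#' Filter tracks by minimum movement speed
#'
#' @param trajs list of trajectories.
#' @param cfg a [track_filter_config()].
#' @return A list with `kept` (trajectories), `rejected` (trajectories)
#'   and `reasons` (character vector, named by track id, for the rejected
#'   tracks).
#' @export
filter_tracks <- function(trajs, cfg = track_filter_config()) {
  stopifnot(inherits(cfg, "track_filter_config"))
  if (length(trajs) == 0)
    return(list(kept = list(), rejected = list(), reasons = character(0)))
  reasons <- character(0)
  keep <- vapply(trajs, function(tr) {
    if (length(tr$t) < cfg$min_track_length) {
      reasons[tr$track_id] <<- sprintf("track length %d < %d points",
                                       length(tr$t), cfg$min_track_length)
      return(FALSE)
    }
    ks <- kinematics_summary(tr)
    if (!(ks$mean_speed > cfg$min_mean_speed)) {
      reasons[tr$track_id] <<- sprintf(
        "mean speed %.3g um/min not above %.3g", ks$mean_speed,
        cfg$min_mean_speed)
      return(FALSE)
    }
    TRUE
  }, logical(1))
  list(kept = trajs[keep], rejected = trajs[!keep], reasons = reasons)
}

#' Anchor trajectories at the origin
#'
#' Translates every track so its first point lies at (0, 0) -- the
#' standard rose-plot transform. Optionally subsamples a fixed number of
#' tracks at random (rose plots conventionally show 20 randomly chosen
#' cells), reproducibly under `seed`.
#'
#' @param trajs list of trajectories.
#' @param n_cells optional number of tracks to sample for display.
#' @param seed integer seed used when `n_cells` is given.
#' @return A list of translated trajectories.
#' @export
to_origin <- function(trajs, n_cells = NULL, seed = NULL) {
  if (!is.null(n_cells) && n_cells < length(trajs)) {
    idx <- if (is.null(seed)) sample(length(trajs), n_cells) else
      with_seed(seed, sample(length(trajs), n_cells))
    trajs <- trajs[sort(idx)]
  }
  lapply(trajs, function(tr) {
    tr$x <- tr$x - tr$x[1]
    tr$y <- tr$y - tr$y[1]
    tr
  })
}

#' Cumulative-distance matrix for one condition
#'
#' For each track, the running sum of step lengths aligned on the shared
#' acquisition grid. Tracks of different durations are allowed (ragged
#' series); every series starts at 0 and is non-decreasing. This is the
#' input format for the earliest-significant-time scan.
#'
#' @param trajs list of trajectories sharing a frame interval.
#' @param condition condition label.
#' @return A `cum_dist_matrix` object: `condition`, `frame_interval`,
#'   `times` (the union acquisition grid, relative to each track's start)
#'   and `series` (named list of cumulative-distance vectors).
#' @export
cumulative_distance_matrix <- function(trajs, condition = "condition") {
  stopifnot(length(trajs) > 0)
  fi <- unique(vapply(trajs, function(tr) tr$frame_interval, numeric(1)))
  if (length(fi) != 1L)
    stop("tracks do not share a frame interval: ",
         paste(fi, collapse = ", "), call. = FALSE)
  series <- lapply(trajs, function(tr) c(0, cumsum(step_lengths(tr)$steps)))
  names(series) <- vapply(trajs, function(tr) tr$track_id, character(1))
  n_max <- max(lengths(series))
  structure(list(condition = condition, frame_interval = fi,
                 times = (seq_len(n_max) - 1) * fi, series = series),
            class = "cum_dist_matrix")
}

#' @export
print.cum_dist_matrix <- function(x, ...) {
  cat(sprintf(
    "<cum_dist_matrix '%s'> %d tracks, %d time points (every %g min)\n",
    x$condition, length(x$series), length(x$times), x$frame_interval))
  invisible(x)
}
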