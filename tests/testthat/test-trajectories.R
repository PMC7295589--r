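test_that("step lengths follow the planar Pythagorean rule", {
  tr <- trajectory("a", c(0, 10), x = c(0, 3), y = c(0, 4))
  expect_equal(step_lengths(tr)$steps, 5)

  still <- trajectory("b", (0:4) * 10, rep(2, 5), rep(-1, 5))
  expect_equal(step_lengths(still)$steps, rep(0, 4))

  # brute-force per-pair oracle on a random track
  tr <- random_track(n = 100, seed = 11)
  manual <- vapply(seq_len(99), function(i)
    sqrt((tr$x[i + 1] - tr$x[i])^2 + (tr$y[i + 1] - tr$y[i])^2),
    numeric(1))
  expect_equal(step_lengths(tr)$steps, manual)
})

test_that("trajectory invariants are enforced", {
  expect_error(trajectory("a", 0, 0, 0), "fewer than 2")
  expect_error(trajectory("a", c(0, 0), c(0, 1), c(0, 1)),
               "non-increasing")
  expect_error(trajectory("a", c(0, 10), c(0, NA), c(0, 1)),
               "non-finite")
})

test_that("kinematics summary: path length, net displacement, medians", {
  tr <- straight_track(n = 3, step = 1)
  ks <- kinematics_summary(tr)
  expect_equal(ks$total_displacement, 2)
  expect_equal(ks$net_displacement, 2)
  expect_equal(ks$median_step_length, 1)
  expect_equal(ks$mean_speed, 2 / 20)
  expect_equal(ks$duration, 20)

  # out-and-back: path exceeds net
  oab <- trajectory("oab", c(0, 10, 20), c(0, 1, 0), c(0, 0, 0))
  ks <- kinematics_summary(oab)
  expect_equal(ks$total_displacement, 2)
  expect_equal(ks$net_displacement, 0)

  # additivity: total equals sum of the step series
  tr <- random_track(n = 50, seed = 3)
  expect_equal(kinematics_summary(tr)$total_displacement,
               sum(step_lengths(tr)$steps))
})

test_that("path length >= net displacement on random walks", {
  for (i in 1:25) {
    tr <- random_track(id = paste0("rw", i), n = 30, seed = i)
    ks <- kinematics_summary(tr)
    expect_gte(ks$total_displacement, ks$net_displacement)
  }
})

test_that("track CSV round trip preserves coordinates", {
  cohort <- simulate_levy_walk_cohort(
    walk_sim_config(n_cells = 4, n_frames = 10, seed = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracks(cohort$vehicle, path)
  back <- load_tracks(path, frame_interval = 10)
  expect_setequal(names(back), names(cohort$vehicle))
  for (id in names(back)) {
    expect_equal(back[[id]]$x, cohort$vehicle[[id]]$x)
    expect_equal(back[[id]]$y, cohort$vehicle[[id]]$y)
    expect_equal(back[[id]]$t, cohort$vehicle[[id]]$t)
  }
})

test_that("load_tracks validates format and duplicates", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(track_id = 1, t_min = 0:2, wrong = 0:2), path,
            row.names = FALSE)
  expect_error(load_tracks(path), "missing required column")

  write.csv(data.frame(track_id = 1, t_min = c(0, 10, 10),
                       x_um = 1:3, y_um = 1:3), path, row.names = FALSE)
  expect_error(load_tracks(path), "duplicate \\(track, time\\)")

  # rows with missing coordinates dropped with a message
  write.csv(data.frame(track_id = 1, t_min = c(0, 10, 20),
                       x_um = c(0, NA, 2), y_um = c(0, 1, 2)), path,
            row.names = FALSE)
  expect_message(tr <- load_tracks(path), "dropped 1")
  expect_length(tr[[1]]$t, 2)
})

test_that("speed filter applies a strict threshold and partitions input", {
  # 2.0 um/min: 20 um per 10-min frame
  slow <- trajectory("slow", c(0, 10), c(0, 20), c(0, 0))
  boundary <- trajectory("boundary", c(0, 10), c(0, 25), c(0, 0))
  fast <- trajectory("fast", c(0, 10), c(0, 26), c(0, 0))
  res <- filter_tracks(list(slow = slow, boundary = boundary, fast = fast))
  expect_named(res$kept, "fast")
  expect_setequal(names(res$rejected), c("slow", "boundary"))
  expect_match(res$reasons[["slow"]], "not above 2.5")

  # partition + idempotence on a synthetic cohort
  cohort <- simulate_levy_walk_cohort(
    walk_sim_config(n_cells = 30, n_frames = 12, seed = 2))$vehicle
  cfg <- track_filter_config(min_mean_speed = 0.25)
  res <- filter_tracks(cohort, cfg)
  expect_equal(length(res$kept) + length(res$rejected), length(cohort))
  expect_setequal(c(names(res$kept), names(res$rejected)), names(cohort))
  again <- filter_tracks(res$kept, cfg)
  expect_equal(names(again$kept), names(res$kept))
  expect_length(again$rejected, 0)
})

test_that("to_origin anchors at (0,0), preserves shape, samples reproducibly", {
  tr <- trajectory("a", c(0, 10, 20), c(7, 8, 9), c(-3, -2, -5))
  out <- to_origin(list(a = tr))[[1]]
  expect_equal(c(out$x[1], out$y[1]), c(0, 0))
  expect_equal(step_lengths(out)$steps, step_lengths(tr)$steps)

  cohort <- simulate_levy_walk_cohort(
    walk_sim_config(n_cells = 30, n_frames = 6, seed = 9))$vehicle
  s1 <- to_origin(cohort, n_cells = 20, seed = 4)
  s2 <- to_origin(cohort, n_cells = 20, seed = 4)
  expect_equal(names(s1), names(s2))
  expect_length(s1, 20)
})

test_that("cumulative-distance matrices are running sums of step series", {
  cm <- cumulative_distance_matrix(list(straight_track()), "veh")
  expect_equal(cm$series[[1]], c(0, 1, 2))

  tr <- random_track(n = 40, seed = 8)
  cm <- cumulative_distance_matrix(list(tr), "veh")
  s <- cm$series[[1]]
  expect_equal(s[length(s)], kinematics_summary(tr)$total_displacement)
  expect_equal(diff(s), step_lengths(tr)$steps)
  expect_true(all(diff(s) >= 0))

  # ragged cohort: per-time-point group sizes count surviving tracks
  set.seed(21)
  lens <- sample(10:30, 15, replace = TRUE)
  trs <- lapply(seq_along(lens), function(i)
    random_track(id = paste0("t", i), n = lens[i], seed = 100 + i))
  cm <- cumulative_distance_matrix(trs, "veh")
  for (k in c(1, 10, 25)) {
    n_at_k <- sum(vapply(cm$series, function(s) length(s) >= k,
                         logical(1)))
    expect_equal(n_at_k, sum(lens >= k))
  }

  # mixed frame intervals are an alignment error
  other <- trajectory("o", c(0, 5), c(0, 1), c(0, 1), frame_interval = 5)
  expect_error(cumulative_distance_matrix(list(straight_track(), other)),
               "frame interval")
})

test_that("kinematics are invariant under rigid motion", {
  tr <- random_track(n = 60, seed = 13)
  theta <- 0.7
  rot <- trajectory(tr$track_id, tr$t,
                    cos(theta) * tr$x - sin(theta) * tr$y + 11,
                    sin(theta) * tr$x + cos(theta) * tr$y - 4,
                    tr$frame_interval)
  a <- kinematics_summary(tr); b <- kinematics_summary(rot)
  for (col in c("total_displacement", "net_displacement",
                "median_step_length", "mean_speed", "duration"))
    expect_equal(a[[col]], b[[col]])
})
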