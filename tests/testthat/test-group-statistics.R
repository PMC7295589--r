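test_that("tertile analysis balances reference bins and conserves counts", {
  ev <- data.frame(condition = "vehicle",
                   growth_speed_um_min = 10:18)
  ts <- tertile_analysis(ev, "vehicle")
  ref <- ts$table[ts$table$condition == "vehicle", ]
  expect_equal(ref$n, c(3, 3, 3))
  expect_true(all(diff(ts$edges) > 0))

  # treated identical to reference: identical per-bin medians
  ev2 <- rbind(ev, transform(ev, condition = "dex"))
  ts2 <- tertile_analysis(ev2, "vehicle")
  wide <- split(ts2$table, ts2$table$condition)
  expect_equal(wide$dex$median_speed, wide$vehicle$median_speed)

  expect_error(tertile_analysis(ev, "missing"), "not present")
  expect_error(tertile_analysis(
    data.frame(condition = "vehicle", growth_speed_um_min = c(-1, 2, 3)),
    "vehicle"), "> 0")
})

test_that("reference bins balanced within 1 and counts conserved at scale", {
  tab <- simulate_growth_speeds(n_ref = 9000, n_treated = 9500,
                                fast_shift = 1.05, seed = 2)
  ts <- tertile_analysis(tab, "vehicle")
  ref_n <- ts$table$n[ts$table$condition == "vehicle"]
  expect_lte(max(ref_n) - min(ref_n), 1)
  expect_equal(sum(ref_n), 9000)
  trt_n <- ts$table$n[ts$table$condition == "dex"]
  expect_equal(sum(trt_n), 9500)

  # an upper-tail speed increase raises the treated fast-bin median
  fast <- ts$table[ts$table$bin == "fast", ]
  expect_gt(fast$median_speed[fast$condition == "dex"],
            fast$median_speed[fast$condition == "vehicle"])

  # no shift: medians agree within Monte-Carlo error
  tab0 <- simulate_growth_speeds(n_ref = 9000, n_treated = 9000,
                                 fast_shift = 1, seed = 3)
  ts0 <- tertile_analysis(tab0, "vehicle")
  f0 <- ts0$table[ts0$table$bin == "fast", ]
  expect_lt(abs(diff(f0$median_speed)) / f0$median_speed[1], 0.02)
})

test_that("step-length histograms share bins and normalise", {
  h <- step_length_histogram(list(veh = rep(1.1, 10)), bin_width = 0.5)
  expect_equal(sum(h$frequency > 0), 1)
  expect_equal(sum(h$frequency), 1)
  expect_error(step_length_histogram(list(a = 1:3), bin_width = 0),
               "> 0")

  # a reduced location parameter left-shifts the frequency curve
  veh <- sample_stable(20000, stable_params(1.5, 0, 0.3, 2.6), seed = 1)
  trt <- sample_stable(20000, stable_params(1.5, 0, 0.3, 2.0), seed = 2)
  h2 <- step_length_histogram(list(vehicle = veh, treated = trt),
                              bin_width = 0.2)
  mode_of <- function(cond) {
    d <- h2[h2$condition == cond, ]
    d$mid[which.max(d$frequency)]
  }
  expect_lt(mode_of("treated"), mode_of("vehicle"))
  for (cond in c("vehicle", "treated"))
    expect_equal(sum(h2$frequency[h2$condition == cond]), 1)
})

test_that("rank-sum scan finds no effect when cohorts are identical", {
  cohort <- simulate_levy_walk_cohort(
    walk_sim_config(n_cells = 30, n_frames = 20, seed = 4))$vehicle
  cm <- cumulative_distance_matrix(cohort, "veh")
  scan <- rank_sum_scan(cm, cm)
  expect_true(is.na(scan$earliest_significant_time))
  expect_true(all(scan$table$p_value > 0.9))
})

test_that("scan detects an injected step-scale reduction at/after onset", {
  cfg <- walk_sim_config(
    params_vehicle = stable_params(1.5, 0, 0.9, 2.6),
    params_treated = stable_params(1.5, 0, 0.9 * 0.6, 2.6 * 0.6),
    n_cells = 100, n_frames = 19, shift_time = 6, seed = 10)
  cohort <- simulate_levy_walk_cohort(cfg)
  scan <- rank_sum_scan(cumulative_distance_matrix(cohort$treated, "trt"),
                        cumulative_distance_matrix(cohort$vehicle, "veh"))
  expect_false(is.na(scan$earliest_significant_time))
  expect_gte(scan$earliest_significant_time, 60)  # frame 6 at 10 min
  expect_equal(scan$alpha, 1e-4)
  # direction requirement: treated median below vehicle at detection
  det <- scan$table[scan$table$t_min == scan$earliest_significant_time, ]
  expect_lt(det$median_treated, det$median_vehicle)
})

test_that("scan is symmetric up to the direction requirement", {
  cfg <- walk_sim_config(n_cells = 40, n_frames = 12, seed = 6,
                         params_treated = stable_params(1.5, 0, 0.5, 1.6))
  cohort <- simulate_levy_walk_cohort(cfg)
  cmt <- cumulative_distance_matrix(cohort$treated, "trt")
  cmv <- cumulative_distance_matrix(cohort$vehicle, "veh")
  fwd <- rank_sum_scan(cmt, cmv, alpha = 0.01)
  rev <- rank_sum_scan(cmv, cmt, alpha = 0.01)
  expect_equal(fwd$table$p_value, rev$table$p_value)
  # reversed direction: reduction requirement blocks detection
  expect_true(is.na(rev$earliest_significant_time))
  # direction-free scan recovers it
  rev2 <- rank_sum_scan(cmv, cmt, alpha = 0.01,
                        require_reduction = FALSE)
  expect_equal(rev2$earliest_significant_time,
               fwd$earliest_significant_time)
})

test_that("stronger reductions are detected no later", {
  t_of <- function(scale) {
    cfg <- walk_sim_config(
      params_treated = stable_params(1.5, 0, 0.9 * scale, 2.6 * scale),
      n_cells = 60, n_frames = 16, shift_time = 3, seed = 8)
    cohort <- simulate_levy_walk_cohort(cfg)
    rank_sum_scan(
      cumulative_distance_matrix(cohort$treated, "t"),
      cumulative_distance_matrix(cohort$vehicle, "v"),
      alpha = 0.001)$earliest_significant_time
  }
  weak <- t_of(0.7); strong <- t_of(0.4)
  expect_false(is.na(strong))
  expect_true(is.na(weak) || strong <= weak)
})

test_that("null rejection rate at alpha = 1e-4 is conservative", {
  # single time point, repeated seeded simulations under the null
  set.seed(99)
  rej <- 0; n_sim <- 1000
  for (i in seq_len(n_sim)) {
    a <- rlnorm(30); b <- rlnorm(30)
    if (wilcox.test(a, b)$p.value < 1e-4) rej <- rej + 1
  }
  expect_lte(rej / n_sim, 0.001)
})
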