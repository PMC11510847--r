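test_that("sprint threshold is the mean split velocity", {
  expect_equal(sprint_threshold_from_split(10, 2.0), 5.0)
  expect_equal(sprint_threshold_from_split(10, 1.8), 10 / 1.8)
  expect_error(sprint_threshold_from_split(10, 10.0),
               class = "threshold_unusable")
  expect_error(sprint_threshold_from_split(0, 2), class = "invalid_argument")
  expect_error(sprint_threshold_from_split(10, -1), class = "invalid_argument")
})

test_that("acceleration is the backward first difference times the rate", {
  tr <- trace_from_speeds(c(2.0, 2.5))
  expect_equal(compute_acceleration(tr), c(0, 5.0))
  expect_equal(compute_acceleration(trace_from_speeds(rep(3, 50))),
               rep(0, 50))
  expect_equal(compute_acceleration(trace_from_speeds(c(4.0, 3.5)))[2], -5.0)
})

test_that("optional smoothing is a centred moving average with valid window", {
  tr <- trace_from_speeds(c(1, 5, 1, 5, 1, 5, 1, 5))
  raw <- compute_acceleration(tr)
  smo <- compute_acceleration(tr, smoothing_window = 3)
  expect_lt(max(abs(smo)), max(abs(raw)))
  # edge truncation: window-3 smoothing of the first sample averages 2 values
  expect_equal(smo[2], (mean(c(1, 5, 1)) - mean(c(1, 5))) * 10)
  expect_error(compute_acceleration(tr, smoothing_window = 2),
               class = "invalid_argument")
  expect_error(compute_acceleration(tr, smoothing_window = 0),
               class = "invalid_argument")
})

test_that("zone assignment follows the documented boundary conventions", {
  th <- zone_thresholds(5.0)
  z <- assign_zone(c(1.0, 3.0, 5.5, 1.5), c(-0.5, 2.5, -2.4, 0.0), th)
  expect_equal(as.character(z$speed_zone), c("LS", "MS", "HS", "MS"))
  expect_equal(as.character(z$accel_type), c("LD", "HA", "HD", "LD"))
  # exact boundary cases: +-2 m/s^2 inclusive on the mild side, sprint
  # entry inclusive for HS
  zb <- assign_zone(c(5.0, 0.0, 2.0), c(2.0, -2.0, 2.0001), th)
  expect_equal(as.character(zb$speed_zone), c("HS", "LS", "MS"))
  expect_equal(as.character(zb$accel_type), c("LA", "LD", "HA"))
})

test_that("zone assignment partitions the (speed, accel) plane", {
  th <- zone_thresholds(5.0)
  grid <- expand.grid(
    v = c(0, 0.1, 1.4999, 1.5, 3, 4.9999, 5, 8),
    a = c(-5, -2.0001, -2, -0.5, 0, 0.5, 2, 2.0001, 5)
  )
  z <- assign_zone(grid$v, grid$a, th)
  expect_false(any(is.na(z$speed_zone)))
  expect_false(any(is.na(z$accel_type)))
  # each pair maps to exactly one of the 12 cells
  expect_true(all(table(z$speed_zone, z$accel_type) >= 0))
  expect_equal(nrow(z), nrow(grid))
})

test_that("constant-speed distance integrates into the LS_LD cell", {
  tr <- trace_from_speeds(rep(1.0, 600))
  zd <- accumulate_zone_distances(tr, compute_acceleration(tr),
                                  zone_thresholds(5))
  expect_equal(unname(zd$cells[["LS_LD"]]), 60.0)
  expect_equal(sum(zd$cells[names(zd$cells) != "LS_LD"]), 0)
  expect_equal(zd$total_m, 60.0)
  expect_equal(zd$playing_time_min, 1.0)
})

test_that("off-field and halftime samples contribute nothing", {
  tr <- trace_from_speeds(rep(2, 100), on_field = FALSE)
  zd <- accumulate_zone_distances(tr, compute_acceleration(tr),
                                  zone_thresholds(5))
  expect_equal(sum(zd$cells), 0)
  expect_equal(zd$playing_time_min, 0)
  ht <- trace_from_speeds(rep(2, 100), period = "HT")
  zdht <- accumulate_zone_distances(ht, compute_acceleration(ht),
                                    zone_thresholds(5))
  expect_equal(sum(zdht$cells), 0)
  expect_equal(zdht$playing_time_min, 0)
})

test_that("misaligned acceleration series is rejected", {
  tr <- trace_from_speeds(rep(1, 50))
  expect_error(
    accumulate_zone_distances(tr, rep(0, 49), zone_thresholds(5)),
    class = "invalid_argument"
  )
})

test_that("vectorised accumulation equals the per-sample loop oracle", {
  th <- zone_thresholds(5.2)
  for (s in 1:20) {
    tr <- random_trace(n = 300, seed = s)
    acc <- compute_acceleration(tr)
    got <- accumulate_zone_distances(tr, acc, th)
    ref <- zone_loop_oracle(tr, acc, th)
    expect_equal(got$cells, ref$cells, tolerance = 1e-12)
    expect_equal(got$playing_time_min, ref$playing_time_min)
  }
})

test_that("the twelve cells conserve total on-field distance", {
  th <- zone_thresholds(5.2)
  for (s in 1:100) {
    tr <- random_trace(n = 200, seed = 1000 + s)
    zd <- accumulate_zone_distances(tr, compute_acceleration(tr), th)
    keep <- tr$on_field & tr$period != "HT"
    expect_equal(sum(zd$cells), zd$total_m, tolerance = 1e-6)
    expect_equal(zd$total_m, sum(tr$speed_mps[keep]) / 10, tolerance = 1e-9)
  }
})

test_that("doubling the trace doubles every cell", {
  th <- zone_thresholds(5.0)
  v <- c(0, 1, 2, 3, 3, 2, 1, 0.5, 0.2, 0)
  tr1 <- trace_from_speeds(rep(v, 10))
  tr2 <- trace_from_speeds(rep(v, 20))
  z1 <- accumulate_zone_distances(tr1, compute_acceleration(tr1), th)
  z2 <- accumulate_zone_distances(tr2, compute_acceleration(tr2), th)
  # the single join sample between copies differs; tolerance covers it
  expect_equal(z2$cells, 2 * z1$cells, tolerance = 0.02)
  expect_equal(z2$playing_time_min, 2 * z1$playing_time_min)
})

test_that("comparator summaries reduce the grid as the older methods do", {
  th <- zone_thresholds(5.0)
  flat <- trace_from_speeds(rep(2, 100))
  cs <- comparator_summaries(flat, compute_acceleration(flat), th)
  expect_equal(cs$total_accel_distance_m, 0)
  expect_true(is.na(cs$accel_decel_ratio))
  expect_false(cs$ratio_defined)
  expect_equal(unname(cs$four_bin[c("HA", "HD")]), c(0, 0))

  for (s in 1:10) {
    tr <- random_trace(n = 300, seed = 300 + s)
    acc <- compute_acceleration(tr)
    zd <- accumulate_zone_distances(tr, acc, th)
    cs <- comparator_summaries(tr, acc, th)
    m <- matrix(zd$cells, nrow = 3, byrow = TRUE)
    # four-bin output is the speed-marginalised 12-cell grid, exactly
    expect_equal(unname(cs$four_bin), unname(colSums(m)))
    expect_equal(cs$total_accel_distance_m,
                 unname(cs$four_bin[["HA"]] + cs$four_bin[["HD"]]))
  }
})

test_that("the accel/decel quotient matches a hand-enumerated ramp", {
  # accelerate hard, hold, decelerate hard: per-sample bookkeeping by hand
  v <- c(0, 0.3, 0.6, 0.9, 1.2, 1.2, 1.2, 0.9, 0.6, 0.3, 0)
  tr <- trace_from_speeds(v)
  acc <- compute_acceleration(tr) # +-3 m/s^2 on the ramps
  cs <- comparator_summaries(tr, acc, zone_thresholds(5))
  up <- sum(v[acc > 2]) / 10
  down <- sum(v[acc < -2]) / 10
  expect_equal(cs$accel_decel_ratio, up / down)
  expect_equal(cs$total_accel_distance_m, up + down)
})

test_that("trace validation rejects malformed series", {
  expect_error(speed_trace(c(0, 0.1), c(1, -1), c(TRUE, TRUE), c("H1", "H1")),
               class = "invalid_argument")
  expect_error(speed_trace(c(0, 0.3), c(1, 1), c(TRUE, TRUE), c("H1", "H1")),
               class = "invalid_argument")
  expect_error(speed_trace(c(0, 0.1), c(1, 1), c(TRUE, TRUE), c("X", "H1")),
               class = "invalid_argument")
  expect_error(zone_thresholds(1.0), class = "invalid_argument")
})
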