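make_sync_log <- function(geo, duration = 6 * 3600, clock_offset = NULL,
                          clock_drift = NULL, resolution = 0, seed = 1,
                          tag_id = "sync") {
  path <- simulate_true_path(movement_scenario(
    "stationary", start = unname(benthtrack:::sync_position(geo)),
    duration = duration, seed = seed))
  simulate_detections(path, geo, tag_id = tag_id,
                      clock_offset = clock_offset,
                      clock_drift = clock_drift,
                      resolution = resolution, seed = seed + 1)
}

test_that("clock synchronization recovers injected offsets and drift", {
  geo <- port_geometry()

  log <- make_sync_log(geo, clock_offset = c(St2 = 0.250))
  ck <- synchronize_clocks(log, geo)
  s2 <- ck$samples[ck$samples$receiver_id == "St2", ]
  expect_true(all(abs(s2$offset_s - 0.250) < 1e-9))

  # zero offsets with 1-ms quantization: recovered offsets within the bound
  logq <- make_sync_log(geo, resolution = 1e-3, seed = 5)
  ckq <- synchronize_clocks(logq, geo)
  expect_lt(max(abs(ckq$samples$offset_s)), 2e-3 + 1e-12)

  # linear drift 1 ms/hour: piecewise-linear estimate tracks it
  drift <- 1e-3 / 3600
  logd <- make_sync_log(geo, clock_drift = c(St3 = drift),
                        resolution = 1e-3, seed = 8)
  ckd <- synchronize_clocks(logd, geo)
  s3 <- ckd$samples[ckd$samples$receiver_id == "St3", ]
  expect_true(all(abs(s3$offset_s - drift * s3$time_s) <= 2e-3 + 1e-12))
})

test_that("unheard receivers are flagged unusable", {
  geo <- port_geometry()
  log <- make_sync_log(geo)
  log2 <- log[log$receiver_id != "St1", ]
  class(log2) <- class(log)
  expect_warning(ck <- synchronize_clocks(log2, geo), "St1")
  expect_identical(ck$unusable, "St1")
  corr <- apply_clock_correction(log2, ck)
  expect_false("St1" %in% corr$receiver_id)
})

test_that("arrival grouping enforces the all-receiver rule per tag", {
  geo <- port_geometry()
  log <- make_sync_log(geo, tag_id = "A")
  sets <- group_arrivals(log, geo)
  n_em <- nrow(attr(log, "emissions"))
  expect_equal(nrow(sets$times), n_em)
  expect_true(all(rowSums(!is.na(sets$times)) == 5))

  # dropping one receiver's detection removes that emission entirely
  drop_row <- which(log$receiver_id == "St2")[3]
  victim <- log$emission[drop_row]
  log3 <- log[-drop_row, ]
  class(log3) <- class(log)
  sets3 <- group_arrivals(log3, geo)
  expect_equal(nrow(sets3$times), n_em - 1L)
  expect_equal(sets3$tallies$insufficient, 1L)

  # relaxed mode keeps the 4-receiver set
  sets4 <- group_arrivals(log3, geo, require_all = FALSE)
  expect_equal(nrow(sets4$times), n_em)

  # two interleaved tags never mix
  logB <- make_sync_log(geo, seed = 42, tag_id = "B")
  both <- rbind(as.data.frame(log), as.data.frame(logB))
  class(both) <- class(log)
  setsB <- group_arrivals(both, geo)
  expect_setequal(unique(setsB$tag_id), c("A", "B"))
  expect_equal(sum(setsB$tag_id == "A"), n_em)
})

test_that("TDOA solve inverts noise-free geometry", {
  geo <- array_geometry(
    data.frame(receiver_id = paste0("St", 1:5),
               x = c(0, 80, 80, 0, 40), y = c(0, 0, 80, 80, 40)),
    "St5", sound_speed = 1500)
  rec <- cbind(geo$x, geo$y)

  arr_for <- function(p, t0 = 100) {
    d <- sqrt((rec[, 1] - p[1])^2 + (rec[, 2] - p[2])^2)
    setNames(t0 + d / 1500, geo$receiver_id)
  }
  fix <- solve_tdoa(arr_for(c(30, 20)), geo)
  expect_lt(sqrt((fix$x - 30)^2 + (fix$y - 20)^2), 1e-6)
  expect_equal(fix$time_s, 100, tolerance = 1e-8)

  # tag exactly at a receiver position
  fix2 <- solve_tdoa(arr_for(c(0, 0)), geo)
  expect_lt(sqrt(fix2$x^2 + fix2$y^2), 1e-6)

  # solutions outside the bounding box are rejected with a reason
  far <- solve_tdoa(arr_for(c(300, 300)), geo, bbox_pad = 20)
  expect_false(far$ok)
  expect_identical(far$reason, "outside_bbox")

  expect_identical(
    solve_tdoa(setNames(c(1, 2, NA, NA, NA), geo$receiver_id), geo)$reason,
    "too_few_receivers")
})

test_that("fixes are invariant to a common clock shift", {
  geo <- port_geometry()
  path <- simulate_true_path(movement_scenario(
    "random_walk", sigma_true = 0.01, duration = 4 * 3600, seed = 3))
  det <- simulate_detections(path, geo, resolution = 1e-3, seed = 4)
  sets <- group_arrivals(det, geo)
  fx1 <- locate_fixes(sets, geo)

  det2 <- det
  det2$arrival_time_s <- det2$arrival_time_s + 123.456
  sets2 <- group_arrivals(det2, geo)
  fx2 <- locate_fixes(sets2, geo)
  expect_equal(fx1$x, fx2$x, tolerance = 1e-9)
  expect_equal(fx1$y, fx2$y, tolerance = 1e-9)

  # discarding rule: fixes <= emissions, equality without dropout
  expect_equal(nrow(fx1), nrow(attr(det, "emissions")))
})

test_that("resampling picks nearest fixes and flags gaps", {
  fixes <- data.frame(tag_id = "t", time_s = seq(0, 10 * 3600, by = 120),
                      x = 1, y = 2, residual = 0, n_receivers = 5L)
  hr <- resample_series(fixes, "hourly")
  expect_equal(nrow(hr), 11L)
  expect_false(any(hr$gap))

  # 3-hour outage -> 3 consecutive gaps
  out <- fixes[fixes$time_s < 4.5 * 3600 | fixes$time_s > 7.5 * 3600, ]
  hr2 <- resample_series(out, "hourly")
  expect_equal(sum(hr2$gap), 3L)
  expect_true(all(hr2$gap[c(6, 7, 8)]))

  # duplicate timestamps: earliest (first) kept and tallied
  dup <- rbind(fixes[1:3, ], transform(fixes[2, ], x = 99))
  hr3 <- resample_series(dup, step = 120)
  expect_equal(hr3$x[2], 1)
  expect_gte(attr(hr3, "tallies")$duplicates, 1L)

  empty <- resample_series(fixes[0, ], "hourly")
  expect_equal(nrow(empty), 0L)
})

test_that("localization errors match the bivariate-normal closed form", {
  truth <- c(40, 40)
  est0 <- data.frame(x = rep(40, 10), y = rep(40, 10))
  r0 <- localization_error_report(est0, truth)
  expect_equal(r0$mean, 0)
  expect_equal(r0$sd, 0)

  tau <- 0.5
  set.seed(31)
  n <- 2e4
  est <- data.frame(x = truth[1] + rnorm(n, 0, tau),
                    y = truth[2] + rnorm(n, 0, tau))
  r <- localization_error_report(est, truth)
  expect_equal(r$mean, tau * sqrt(pi / 2), tolerance = 0.02)
})
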