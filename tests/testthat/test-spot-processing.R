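test_that("scans are assigned to dwell windows with half-open boundaries", {
  log <- data.frame(spot_index = 0L, t_arrive_s = 0, t_leave_s = 1)
  mk <- function(t) stick_scan(c(100, 200), c(1, 2), t = t)
  stream <- scan_stream("r", list(mk(0.0), mk(0.5), mk(1.0)))
  asg <- assign_scans(log, stream)
  expect_equal(names(asg$spots), "0")
  expect_length(asg$spots[["0"]], 2)       # t = 0.0 and 0.5
  expect_equal(asg$n_discarded, 1L)        # t = 1.0: half-open interval
})

test_that("assignment matches the brute-force interval oracle and partitions", {
  set.seed(21)
  edges <- sort(runif(100, 0, 100))
  log <- data.frame(spot_index = sample(1000L, 50),
                    t_arrive_s = edges[seq(1, 99, 2)],
                    t_leave_s = edges[seq(2, 100, 2)])
  times <- runif(1000, -5, 105)
  stream <- scan_stream("r", lapply(times, function(t)
    stick_scan(c(100, 200), c(1, 2), t = t)))
  asg <- assign_scans(log, stream)

  expected <- oracle_assign(sort(times), log)
  got <- rep(NA_integer_, length(times))
  for (k in names(asg$spots)) {
    ts <- vapply(asg$spots[[k]], `[[`, 0, "start_time_s")
    got[match(ts, sort(times))] <- as.integer(k)
  }
  expect_equal(got, as.integer(expected))
  n_assigned <- sum(lengths(asg$spots))
  expect_equal(n_assigned + asg$n_discarded, length(times))  # partition
})

test_that("resampling is exact on grid points and linear between them", {
  g <- mz_grid(100, 110, 0.5)
  s <- stick_scan(grid_points(g), seq_along(grid_points(g)))
  expect_equal(resample_scan(s, g), as.numeric(seq_along(grid_points(g))))

  ramp <- stick_scan(c(100, 101), c(0, 10))
  expect_equal(resample_scan(ramp, mz_grid(100, 101, 0.5))[2], 5)

  expect_warning(v <- resample_scan(stick_scan(105, 3), g), "< 2 points")
  expect_equal(v, numeric(length(grid_points(g))))
})

test_that("resampling agrees with an independent interpolation oracle", {
  set.seed(5)
  g <- mz_grid(100, 900, 0.37)
  for (i in 1:5) {
    mzv <- sort(runif(40, 80, 950))
    inten <- runif(40, 0, 100)
    s <- stick_scan(mzv, inten)
    expect_lt(max(abs(resample_scan(s, g) -
                        oracle_interp(s$mz, s$intensity, grid_points(g)))),
              1e-9)
  }
})

test_that("spot averaging and base-peak normalization behave canonically", {
  g <- mz_grid(100, 200, 1)
  s <- stick_scan(c(100, 150, 200), c(5, 20, 10))
  avg <- average_spot(list(s, s), g, 0L)
  expect_equal(avg$intensity, resample_scan(s, g))
  expect_equal(avg$n_scans, 2L)

  # mean of random scans matches the element-wise oracle
  set.seed(9)
  scans <- lapply(1:5, function(i)
    stick_scan(sort(runif(15, 100, 200)), runif(15, 0, 50)))
  avg5 <- average_spot(scans, g, 1L)
  direct <- Reduce(`+`, lapply(scans, resample_scan, grid = g)) / 5
  expect_equal(avg5$intensity, direct, tolerance = 1e-12)

  nrm <- base_peak_normalize(avg)
  expect_equal(max(nrm$intensity), 1)
  expect_equal(which.max(nrm$intensity), which.max(avg$intensity))
  expect_equal(base_peak_normalize(nrm)$intensity, nrm$intensity)  # idempotent

  empty <- base_peak_normalize(average_spot(list(), g, 2L))
  expect_equal(empty$qc_flag, "empty")
  expect_equal(sum(empty$intensity), 0)
})

test_that("QC flags low-TIC spots against the median", {
  g <- mz_grid(100, 200, 1)
  mk <- function(scale) average_spot(list(stick_scan(c(120, 160),
                                                     scale * c(10, 5))), g)
  same <- qc_flag_spots(list(mk(1), mk(1), mk(1)))
  expect_true(all(vapply(same, `[[`, "", "qc_flag") == "ok"))

  one_low <- qc_flag_spots(list(mk(1), mk(1), mk(1), mk(0.01)),
                           min_tic_fraction = 0.1)
  expect_equal(vapply(one_low, `[[`, "", "qc_flag"),
               c("ok", "ok", "ok", "low_signal"))
})

test_that("planted failed transfers are recovered with sensitivity 1", {
  sheet <- brain_cohort_sheet(seed = 4, failed_spot_probability = 0.25)
  lay <- build_tma_layout(sheet_plates(sheet), 2)
  g <- mz_grid(500, 1000, 0.05)
  sim <- simulate_fullscan_run(lay, sheet, noise_model(seed = 14), g,
                               scans_per_spot = 2)
  res <- process_fullscan(sim$stream, sim$stage_log, lay, sim$plate_map, g)
  flagged <- sort(unname(vapply(Filter(function(s) s$qc_flag == "low_signal",
                                       res$spots), `[[`, 0L, "spot_index")))
  planted <- sort(sim$manifest$spots$spot_index[sim$manifest$spots$failed])
  expect_gt(length(planted), 0)
  expect_equal(flagged, planted)
})

test_that("biopsy averaging resolves provenance and ignores scale", {
  sheet <- brain_cohort_sheet(seed = 2)
  lay <- build_tma_layout(sheet_plates(sheet), 4)
  g <- mz_grid(500, 1000, 0.05)
  sim <- simulate_fullscan_run(lay, sheet, quiet_noise(3), g,
                               scans_per_spot = 2)
  res <- process_fullscan(sim$stream, sim$stage_log, lay, sim$plate_map, g)
  expect_length(res$profiles, 36L)
  expect_true(all(vapply(res$profiles, `[[`, 0L, "n_spots_used") == 4L))

  # identical replicates: profile equals the (normalized) spot spectrum
  b1_spots <- sim$manifest$spots$spot_index[sim$manifest$spots$biopsy_id == "B001"]
  one <- Filter(function(s) s$spot_index == b1_spots[1], res$spots)[[1]]
  expect_equal(res$profiles[[1]]$intensity, one$intensity, tolerance = 1e-12)

  # global intensity scaling leaves every biopsy profile unchanged
  scaled <- sim$stream
  scaled$scans <- lapply(scaled$scans, function(s) {
    s$intensity <- s$intensity * 37.5
    s
  })
  res2 <- process_fullscan(scaled, sim$stage_log, lay, sim$plate_map, g)
  for (i in seq_along(res$profiles)) {
    expect_equal(res2$profiles[[i]]$intensity, res$profiles[[i]]$intensity,
                 tolerance = 1e-12)
  }
})
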