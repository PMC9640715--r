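test_that("mzML write/read round-trips scan arrays and times", {
  set.seed(7)
  dir <- withr::local_tempdir()
  scans <- lapply(1:10, function(i) {
    mzv <- sort(runif(20, 100, 1000))
    stick_scan(mzv, runif(20, 1, 1e5), t = i * 0.1)
  })
  stream <- scan_stream("rt", scans)
  write_mzml(stream, file.path(dir, "rt.mzML"))
  back <- read_fullscan_run(file.path(dir, "rt.mzML"))
  expect_length(back$scans, 10)
  for (i in 1:10) {
    expect_equal(back$scans[[i]]$start_time_s, scans[[i]]$start_time_s,
                 tolerance = 1e-9)
    expect_equal(back$scans[[i]]$mz, scans[[i]]$mz, tolerance = 1e-9)
    expect_equal(back$scans[[i]]$intensity, scans[[i]]$intensity,
                 tolerance = 1e-6)
  }
})

test_that("readers sort by time, split by MS level, and validate", {
  dir <- withr::local_tempdir()
  s_late <- stick_scan(c(100, 200), c(1, 2), t = 5)
  s_early <- stick_scan(c(100, 200), c(3, 4), t = 1)
  s_ms2 <- stick_scan(c(128, 129), c(10, 5), t = 3, mode = "msms")
  # written out of time order, MS1 and MS2 interleaved
  write_mzml(structure(list(run_id = "x", scans = list(s_late, s_ms2, s_early)),
                       class = "scan_stream"),
             file.path(dir, "mix.mzML"))
  fs <- read_fullscan_run(file.path(dir, "mix.mzML"))
  expect_length(fs$scans, 2)  # MS1 only
  expect_equal(vapply(fs$scans, `[[`, 0, "start_time_s"), c(1, 5))
  ms <- read_msms_run(file.path(dir, "mix.mzML"))
  expect_length(ms$scans, 1)
  expect_equal(ms$scans[[1]]$precursor_window, c(146.5, 3))

  write_mzml(scan_stream("ms2only", list(s_ms2)), file.path(dir, "m2.mzML"))
  expect_error(read_fullscan_run(file.path(dir, "m2.mzML")), "no MS1")
  expect_error(read_fullscan_run(file.path(dir, "absent.mzML")), "no such file")
})

test_that("per-spot MS/MS directories map file names to spot indices", {
  dir <- withr::local_tempdir()
  expect_length(read_msms_runs(dir), 0)

  ms <- scan_stream("s", list(stick_scan(c(128, 129), c(10, 5), mode = "msms")))
  write_mzml(ms, file.path(dir, "spot_0007.mzML"))
  write_mzml(ms, file.path(dir, "spot_0008.mzML"))
  runs <- read_msms_runs(dir)
  expect_equal(names(runs), c("7", "8"))
  expect_length(runs[["7"]]$scans, 1)

  write_mzml(ms, file.path(dir, "oddname.mzML"))
  expect_warning(read_msms_runs(dir), "oddname")

  file.remove(file.path(dir, "oddname.mzML"))
  write_mzml(ms, file.path(dir, "spot_7.mzML"))  # same index, new file
  expect_error(suppressWarnings(read_msms_runs(dir)), "duplicate spot index")
})

test_that("stage logs are validated: ordering, direction, overlap", {
  dir <- withr::local_tempdir()
  log <- data.frame(spot_index = c(2L, 0L, 1L),
                    t_arrive_s = c(2.4, 0, 1.2),
                    t_leave_s = c(3.4, 1.0, 2.2))
  path <- file.path(dir, "log.csv")
  write_stage_log(log, path)
  back <- read_stage_log(path)
  expect_equal(back$spot_index, c(0L, 1L, 2L))  # reordered by arrival

  expect_error(read_stage_log(data.frame(spot_index = 5L, t_arrive_s = 2,
                                         t_leave_s = 1)),
               "t_arrive >= t_leave")
  expect_error(read_stage_log(data.frame(spot_index = 0:1,
                                         t_arrive_s = c(0, 0.5),
                                         t_leave_s = c(1, 1.5))),
               "overlapping")

  # property: any random interval set containing an overlap is rejected
  set.seed(11)
  for (i in 1:20) {
    a <- sort(runif(6, 0, 10))
    ok_log <- data.frame(spot_index = 0:2, t_arrive_s = a[c(1, 3, 5)],
                         t_leave_s = a[c(2, 4, 6)])
    expect_silent(read_stage_log(ok_log))
    bad <- ok_log
    bad$t_leave_s[1] <- bad$t_arrive_s[2] + runif(1, 0.01, 1)
    expect_error(read_stage_log(bad), "overlap|t_arrive")
  }
})

test_that("plate maps validate uniqueness and round-trip via CSV and YAML", {
  sheet <- brain_cohort_sheet(seed = 1)
  pm <- sheet_plate_map(sheet)
  expect_equal(nrow(pm), 36L)
  dir <- withr::local_tempdir()
  for (f in c("pm.csv", "pm.yaml")) {
    write_plate_map(pm, file.path(dir, f))
    back <- read_plate_map(file.path(dir, f))
    expect_equal(back$biopsy_id, pm$biopsy_id)
    expect_equal(back$well, pm$well)
    expect_equal(back$tcp, pm$tcp, tolerance = 1e-12)
  }
  dup <- rbind(as.data.frame(pm), as.data.frame(pm)[1, ])
  dup$biopsy_id[nrow(dup)] <- "Bdup"
  expect_error(read_plate_map(dup), "duplicate \\(plate_id, well\\)")
  dup2 <- as.data.frame(pm)
  dup2$biopsy_id[2] <- dup2$biopsy_id[1]
  dup2$well[2] <- "P24"
  expect_error(read_plate_map(dup2), "duplicate biopsy_id")
})

test_that("result tables are deterministic and round-trip bit-identically", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "t.csv")
  empty <- data.frame(biopsy_id = character(), score = numeric())
  write_table(empty, path)
  expect_equal(readLines(path), "\"biopsy_id\",\"score\"")

  set.seed(3)
  rec <- data.frame(biopsy_id = sprintf("B%03d", sample(100)),
                    spot_index = sample(100L),
                    score = rnorm(100) * 10^sample(-5:5, 100, TRUE))
  write_table(rec, path)
  back <- utils::read.csv(path, stringsAsFactors = FALSE)
  ord <- order(rec$biopsy_id, rec$spot_index)
  expect_identical(back$score, rec$score[ord])  # bit-identical doubles
  expect_equal(back$biopsy_id, rec$biopsy_id[ord])
})
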