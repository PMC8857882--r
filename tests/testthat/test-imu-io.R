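# Reading/writing recordings and the configurable column mapping.

test_that("accelerometer values declared in g are converted with standard gravity", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ax,ay,az,gx,gy,gz",
               "0,0,1,0,0,0", "0,0,1,0,0,0", "0,0,1,0,0,0"), f)
  cm <- columnMap(accel = c("ax", "ay", "az"), gyro = c("gx", "gy", "gz"),
                  accelUnit = "g")
  rec <- readRecording(f, cm, fs = 246)
  expect_equal(sqrt(rowSums(accel(rec)^2)),
               rep(9.80665, 3), tolerance = 1e-12)
})

test_that("unit conversion is exactly linear", {
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  set.seed(4)
  vals <- matrix(round(runif(18, -1, 1), 6), 3, 6)
  hdr <- "ax,ay,az,gx,gy,gz"
  writeLines(c(hdr, apply(vals, 1, paste, collapse = ",")), f1)
  scaled <- vals
  scaled[, 1:3] <- scaled[, 1:3] * standardGravity()
  writeLines(c(hdr, apply(format(scaled, digits = 17), 1,
                          paste, collapse = ",")), f2)
  cmG <- columnMap(accel = c("ax", "ay", "az"), gyro = c("gx", "gy", "gz"),
                   accelUnit = "g")
  cmSI <- columnMap(accel = c("ax", "ay", "az"), gyro = c("gx", "gy", "gz"))
  expect_equal(accel(readRecording(f1, cmG, fs = 100)),
               accel(readRecording(f2, cmSI, fs = 100)),
               tolerance = 1e-12)
})

test_that("a column mapped twice is rejected", {
  expect_error(
    columnMap(accel = c("ax", "ax", "az"), gyro = c("gx", "gy", "gz")),
    "mapped more than once")
})

test_that("write/read round trip preserves samples, channels and metadata", {
  out <- generateRecording(
    exerciseTemplate("half_squat", nReps = 3, cycleDuration = 1.5),
    perturbationConfig(noiseAccelSd = 0.02, noiseGyroSd = 0.01,
                       leadIn = 0.5, leadOut = 0.5, seed = 9),
    session = "home", subject = "S07")
  rec <- out$recording
  f <- withr::local_tempfile(fileext = ".csv")
  writeRecording(rec, f)
  back <- readRecording(f)
  expect_equal(nSamples(back), nSamples(rec))
  expect_equal(accel(back), accel(rec), tolerance = 1e-9)
  expect_equal(gyro(back), gyro(rec), tolerance = 1e-9)
  expect_equal(sampleTimes(back), sampleTimes(rec), tolerance = 1e-9)
  expect_identical(recordingMeta(back)$subject, "S07")
  expect_identical(recordingMeta(back)$exercise, "half_squat")
  expect_identical(recordingMeta(back)$session, "home")
  expect_equal(samplingRate(back), 246)
})

test_that("recordings without magnetometer write no magnetometer columns", {
  rec <- restRecording(10)
  f <- withr::local_tempfile(fileext = ".csv")
  writeRecording(rec, f)
  hdr <- strsplit(readLines(f, n = 1), ",")[[1]]
  expect_false(any(c("mx", "my", "mz") %in% hdr))
  expect_true(all(c("time_s", "ax_mps2", "gz_rads") %in% hdr))
})

test_that("degenerate or out-of-range recordings are refused", {
  expect_error(IMURecording(accel = matrix(0, 1, 3), gyro = matrix(0, 1, 3),
                            fs = 246), "at least 2")
  expect_error(IMURecording(accel = matrix(0, 0, 3), gyro = matrix(0, 0, 3),
                            fs = 246), "at least 2")
  # above the 16 g accelerometer range
  expect_error(IMURecording(accel = cbind(0, 0, rep(200, 5)),
                            gyro = matrix(0, 5, 3), fs = 246), "16 g")
  # above the 2000 dps gyroscope range
  expect_error(IMURecording(accel = matrix(0, 5, 3),
                            gyro = cbind(rep(40, 5), 0, 0), fs = 246),
               "2000 dps")
  # sampling rate inconsistent with timestamps
  expect_error(IMURecording(accel = matrix(0, 10, 3),
                            gyro = matrix(0, 10, 3),
                            time = seq(0, 0.9, by = 0.1), fs = 246),
               "median sampling interval")
})

test_that("missing and malformed columns produce informative errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ax,ay,az,gx,gy,gz", "0,0,1,0,0,0", "0,bad,1,0,0,0"), f)
  cm <- columnMap(accel = c("ax", "ay", "az"), gyro = c("gx", "gy", "gz"))
  expect_error(readRecording(f, cm, fs = 100), "column 'ay' at data row 2")
  cm2 <- columnMap(accel = c("ax", "ay", "missing_col"),
                   gyro = c("gx", "gy", "gz"))
  expect_error(readRecording(f, cm2, fs = 100), "missing_col")
})

test_that("column maps load from YAML configuration files", {
  f <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("time: t", "accel_x: a1", "accel_y: a2", "accel_z: a3",
               "gyro_x: w1", "gyro_y: w2", "gyro_z: w3",
               "accel_unit: g", "gyro_unit: dps"), f)
  cm <- readColumnMap(f)
  expect_identical(cm@time, "t")
  expect_identical(cm@accel, c("a1", "a2", "a3"))
  expect_identical(cm@accelUnit, "g")
  expect_identical(cm@gyroUnit, "dps")
  f2 <- withr::local_tempfile(fileext = ".yml")
  writeLines("accel_x: a1", f2)
  expect_error(readColumnMap(f2), "misses key")
})

test_that("time is reconstructed from the sampling rate when unmapped", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ax,ay,az,gx,gy,gz",
               paste(rep("0,0,1,0,0,0", 5), collapse = "\n")), f)
  cm <- columnMap(accel = c("ax", "ay", "az"), gyro = c("gx", "gy", "gz"),
                  accelUnit = "g")
  rec <- readRecording(f, cm, fs = 10)
  expect_equal(sampleTimes(rec), (0:4) / 10)
  expect_error(readRecording(f, cm), "no sampling rate")
})
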