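#' @include AllClasses.R utils.R
NULL

#' Construct a column mapping for delimited IMU files
#'
#' @param accel,gyro character(3) of column names in x, y, z order.
#' @param time timestamp column name, or `NA` when time is implicit from
#'   the sampling rate (reconstructed as `(0:(N-1))/fs`).
#' @param mag optional character(3) of magnetometer columns.
#' @param accelUnit `"mps2"` or `"g"`; values declared in g are converted
#'   with g = 9.80665 m/s^2.
#' @param gyroUnit `"rads"` or `"dps"`.
#' @return A [ColumnMap-class].
#' @export
columnMap <- function(accel, gyro, time = NA_character_,
                      mag = character(0),
                      accelUnit = c("mps2", "g"),
                      gyroUnit = c("rads", "dps")) {
  methods::new("ColumnMap",
    time = as.character(time),
    accel = as.character(accel),
    gyro = as.character(gyro),
    mag = as.character(mag),
    accelUnit = match.arg(accelUnit),
    gyroUnit = match.arg(gyroUnit))
}

#' The canonical column mapping written by writeRecording
#' @param withMag include magnetometer columns?
#' @return A [ColumnMap-class].
#' @rdname columnMap
#' @export
canonicalColumnMap <- function(withMag = FALSE) {
  columnMap(time = "time_s",
            accel = c("ax_mps2", "ay_mps2", "az_mps2"),
            gyro = c("gx_rads", "gy_rads", "gz_rads"),
            mag = if (withMag) c("mx", "my", "mz") else character(0),
            accelUnit = "mps2", gyroUnit = "rads")
}

#' Read a column mapping from a plain-text (YAML) configuration file
#'
#' Recognised keys: `time`, `accel_x/y/z`, `gyro_x/y/z`, optional
#' `mag_x/y/z`, `accel_unit` (`mps2`/`g`), `gyro_unit` (`rads`/`dps`).
#'
#' @param path configuration file path.
#' @return A [ColumnMap-class].
#' @export
readColumnMap <- function(path) {
  if (!file.exists(path))
    .imuStop("configError", "column-map file '%s' does not exist", path)
  y <- yaml::read_yaml(path)
  need <- c("accel_x", "accel_y", "accel_z", "gyro_x", "gyro_y", "gyro_z")
  missing <- setdiff(need, names(y))
  if (length(missing) > 0L)
    .imuStop("configError", "column map misses key(s): %s",
             paste(missing, collapse = ", "))
  mag <- character(0)
  if (all(c("mag_x", "mag_y", "mag_z") %in% names(y)))
    mag <- c(y$mag_x, y$mag_y, y$mag_z)
  columnMap(
    time = if (is.null(y$time)) NA_character_ else y$time,
    accel = c(y$accel_x, y$accel_y, y$accel_z),
    gyro = c(y$gyro_x, y$gyro_y, y$gyro_z),
    mag = mag,
    accelUnit = if (is.null(y$accel_unit)) "mps2" else y$accel_unit,
    gyroUnit = if (is.null(y$gyro_unit)) "rads" else y$gyro_unit)
}

.pullColumns <- function(df, cols, what, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L)
    .imuStop("configError",
             "file '%s' misses mapped %s column(s): %s",
             path, what, paste(missing, collapse = ", "))
  m <- sapply(cols, function(cn) {
    v <- df[[cn]]
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad) > 0L)
        .imuStop("parseError",
                 "non-numeric value in column '%s' at data row %d of '%s'",
                 cn, bad[1], path)
      v <- num
    }
    v
  })
  matrix(m, ncol = length(cols))
}

#' Read a single-sensor IMU recording from a delimited text file
#'
#' Reads a comma-delimited file with a header row through a configurable
#' [columnMap()] and returns a validated recording with all channels in SI
#' units (accelerometer values declared in g are multiplied by
#' g = 9.80665 m/s^2, gyroscope dps converted to rad/s). Study metadata is
#' taken from the arguments, falling back to a YAML sidecar
#' (`<path>.meta`) when one exists.
#'
#' @param path CSV file path.
#' @param colmap a [ColumnMap-class]; default the canonical mapping
#'   written by [writeRecording()].
#' @param fs sampling rate, Hz; required when the map has no time column,
#'   otherwise estimated from the median sampling interval when omitted.
#' @param subject,exercise,session,dominantLeg metadata overrides.
#' @return An [IMURecording-class].
#' @export
readRecording <- function(path, colmap = canonicalColumnMap(), fs = NULL,
                          subject = NULL, exercise = NULL, session = NULL,
                          dominantLeg = NULL) {
  if (!file.exists(path))
    .imuStop("configError", "recording file '%s' does not exist", path)
  methods::validObject(colmap)
  df <- utils::read.csv(path, check.names = FALSE)

  side <- list()
  metaPath <- paste0(path, ".meta")
  if (file.exists(metaPath)) side <- yaml::read_yaml(metaPath)

  if (is.na(colmap@time)) {
    if (is.null(fs)) fs <- side$fs
    if (is.null(fs))
      .imuStop("configError",
               "no time column mapped and no sampling rate given")
    time <- NULL
  } else {
    time <- as.numeric(.pullColumns(df, colmap@time, "time", path))
    if (is.null(fs)) fs <- side$fs
    if (is.null(fs)) fs <- 1 / stats::median(diff(time))
    dt <- diff(time)
    jit <- stats::quantile(abs(dt - stats::median(dt)), 0.99) /
      stats::median(dt)
    if (is.finite(jit) && jit > 0.05)
      .imuWarn("samplingJitterWarning",
               "sampling-interval jitter exceeds 5%% in '%s'", path)
  }

  acc <- .pullColumns(df, colmap@accel, "accelerometer", path)
  if (colmap@accelUnit == "g") acc <- acc * .GRAVITY
  gyr <- .pullColumns(df, colmap@gyro, "gyroscope", path)
  if (colmap@gyroUnit == "dps") gyr <- gyr * pi / 180
  mag <- NULL
  if (length(colmap@mag) == 3L)
    mag <- .pullColumns(df, colmap@mag, "magnetometer", path)

  pick <- function(arg, key) {
    if (!is.null(arg)) arg
    else if (!is.null(side[[key]])) side[[key]]
    else NA
  }
  IMURecording(accel = acc, gyro = gyr, fs = fs, time = time, mag = mag,
               subject = pick(subject, "subject"),
               exercise = pick(exercise, "exercise"),
               session = pick(session, "session"),
               dominantLeg = pick(dominantLeg, "dominant_leg"))
}

#' Write a recording to the canonical delimited format
#'
#' Writes a comma-delimited file with the canonical header (`time_s`,
#' `ax_mps2`, `ay_mps2`, `az_mps2`, `gx_rads`, `gy_rads`, `gz_rads`, plus
#' `mx`, `my`, `mz` when a magnetometer is present) and a YAML sidecar
#' `<path>.meta` carrying subject, exercise, session, dominant-leg flag
#' and sampling rate. The file round-trips through [readRecording()] with
#' the canonical column map.
#'
#' @param rec a valid [IMURecording-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeRecording <- function(rec, path) {
  methods::validObject(rec)
  df <- data.frame(time_s = sampleTimes(rec))
  a <- accel(rec)
  g <- gyro(rec)
  df$ax_mps2 <- a[, 1]; df$ay_mps2 <- a[, 2]; df$az_mps2 <- a[, 3]
  df$gx_rads <- g[, 1]; df$gy_rads <- g[, 2]; df$gz_rads <- g[, 3]
  m <- magnetometer(rec)
  if (!is.null(m)) { df$mx <- m[, 1]; df$my <- m[, 2]; df$mz <- m[, 3] }
  ok <- tryCatch({
    utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    .imuStop("ioError", "cannot write '%s': %s", path,
             conditionMessage(ok))
  meta <- recordingMeta(rec)
  yaml::write_yaml(list(subject = meta$subject, exercise = meta$exercise,
                        session = meta$session,
                        dominant_leg = meta$dominantLeg,
                        fs = samplingRate(rec)),
                   paste0(path, ".meta"))
  invisible(path)
}
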