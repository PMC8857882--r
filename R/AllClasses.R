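# Central S4 containers for the shank-IMU exercise pipeline.

## standard gravity, m/s^2
.GRAVITY <- 9.80665

## sensor full-scale limits (16 g accelerometer, 2000 dps gyroscope)
.ACCEL_MAX <- 16 * .GRAVITY
.GYRO_MAX <- 2000 * pi / 180

.EXERCISES <- c("knee_extension", "split_squat", "clam_advanced",
                "half_squat", "mountain_climber")
.SESSIONS <- c("lab", "home", "demo")

#' Exercise and session vocabularies
#'
#' `exerciseNames()` returns the five supported physiotherapy exercises;
#' `sessionNames()` the recognised recording sessions (supervised lab visit,
#' unsupervised home capture, and the physiotherapist's demonstration).
#'
#' @return A character vector.
#' @export
exerciseNames <- function() .EXERCISES

#' @rdname exerciseNames
#' @export
sessionNames <- function() .SESSIONS

#' Standard gravity used for unit conversion
#'
#' The conversion constant between accelerometer g units and m/s^2
#' (9.80665 m/s^2 exactly). Movement intensity divides by this value.
#'
#' @return A numeric scalar, m/s^2.
#' @export
standardGravity <- function() .GRAVITY

#' IMURecording: a single-sensor inertial recording
#'
#' Raw multichannel time series from one 9-DoF IMU capture of one subject
#' performing one exercise in one session. Channels are stored in SI units
#' (acceleration in m/s^2 including gravity as sensed, angular velocity in
#' rad/s); unit conversion happens at read time. The nominal sampling rate
#' of the target sensor is 246 Hz.
#'
#' @slot time numeric vector of sample times in seconds, monotone
#'   non-decreasing.
#' @slot accel N x 3 matrix of triaxial acceleration, m/s^2.
#' @slot gyro N x 3 matrix of triaxial angular velocity, rad/s.
#' @slot mag N x 3 matrix of magnetometer readings (arbitrary units) or a
#'   0 x 3 matrix when absent.
#' @slot fs nominal sampling rate, Hz.
#' @slot meta named list: `subject`, `exercise`, `session`, `dominantLeg`.
#'
#' @seealso [IMURecording()] for the validating constructor,
#'   [readRecording()] / [writeRecording()] for file IO.
#' @export
setClass("IMURecording",
  representation(
    time = "numeric",
    accel = "matrix",
    gyro = "matrix",
    mag = "matrix",
    fs = "numeric",
    meta = "list"
  ),
  prototype(
    mag = matrix(numeric(0), ncol = 3),
    meta = list(subject = NA_character_, exercise = NA_character_,
                session = NA_character_, dominantLeg = NA)
  )
)

setValidity("IMURecording", function(object) {
  msg <- character(0)
  n <- length(object@time)
  if (n < 2L)
    msg <- c(msg, "recording must contain at least 2 samples")
  if (!is.numeric(object@accel) || ncol(object@accel) != 3L ||
      nrow(object@accel) != n)
    msg <- c(msg, "accel must be a numeric N x 3 matrix matching time")
  if (!is.numeric(object@gyro) || ncol(object@gyro) != 3L ||
      nrow(object@gyro) != n)
    msg <- c(msg, "gyro must be a numeric N x 3 matrix matching time")
  if (nrow(object@mag) > 0L &&
      (ncol(object@mag) != 3L || nrow(object@mag) != n))
    msg <- c(msg, "mag, when present, must be an N x 3 matrix matching time")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a positive scalar")
  if (length(msg) > 0L) return(msg)

  if (any(!is.finite(object@time)) || any(diff(object@time) < 0))
    msg <- c(msg, "time must be finite and monotone non-decreasing")
  dt <- stats::median(diff(object@time))
  if (is.finite(dt) && abs(dt - 1 / object@fs) * object@fs >= 0.05)
    msg <- c(msg, sprintf(
      "median sampling interval (%.6g s) deviates by >= 5%% from 1/fs (%.6g s)",
      dt, 1 / object@fs))
  amag <- sqrt(rowSums(object@accel^2))
  if (any(!is.finite(amag)) || any(amag > .ACCEL_MAX + 1e-6))
    msg <- c(msg, "acceleration magnitude exceeds the 16 g sensor range")
  gmag <- sqrt(rowSums(object@gyro^2))
  if (any(!is.finite(gmag)) || any(gmag > .GYRO_MAX + 1e-6))
    msg <- c(msg, "angular velocity magnitude exceeds the 2000 dps range")
  ex <- object@meta$exercise
  if (!is.null(ex) && !is.na(ex) && !ex %in% .EXERCISES)
    msg <- c(msg, sprintf("unknown exercise '%s'", ex))
  se <- object@meta$session
  if (!is.null(se) && !is.na(se) && !se %in% .SESSIONS)
    msg <- c(msg, sprintf("unknown session '%s'", se))
  if (length(msg) > 0L) msg else TRUE
})

#' Construct an IMURecording
#'
#' Validating constructor. Channels are given in SI units; if `time` is
#' `NULL` it is reconstructed from the sampling rate as `(0:(N-1))/fs`.
#'
#' @param accel N x 3 matrix, m/s^2 (gravity-inclusive as sensed).
#' @param gyro N x 3 matrix, rad/s.
#' @param fs sampling rate, Hz.
#' @param time optional numeric vector of sample times, seconds.
#' @param mag optional N x 3 magnetometer matrix.
#' @param subject,exercise,session,dominantLeg study metadata. `exercise`
#'   must be one of [exerciseNames()] and `session` one of [sessionNames()]
#'   (or `NA`).
#' @return A validated [IMURecording-class] object.
#' @examples
#' rest <- IMURecording(
#'   accel = cbind(0, 0, rep(standardGravity(), 500)),
#'   gyro = matrix(0, 500, 3), fs = 246)
#' nSamples(rest)
#' @export
IMURecording <- function(accel, gyro, fs, time = NULL, mag = NULL,
                         subject = NA_character_, exercise = NA_character_,
                         session = NA_character_, dominantLeg = NA) {
  accel <- as.matrix(accel)
  gyro <- as.matrix(gyro)
  n <- nrow(accel)
  if (is.null(time)) time <- seq_len(n) / fs - 1 / fs
  if (is.null(mag)) mag <- matrix(numeric(0), ncol = 3)
  else mag <- as.matrix(mag)
  dimnames(accel) <- list(NULL, c("ax", "ay", "az"))
  dimnames(gyro) <- list(NULL, c("gx", "gy", "gz"))
  methods::new("IMURecording",
    time = as.numeric(time), accel = accel, gyro = gyro, mag = mag,
    fs = as.numeric(fs),
    meta = list(subject = as.character(subject),
                exercise = as.character(exercise),
                session = as.character(session),
                dominantLeg = dominantLeg))
}

#' SegmentationResult: repetition structure of one recording
#'
#' The outcome of repetition segmentation: the acceleration axis in which
#' the movement predominantly occurs, the active section of the trial that
#' contains the repetitions, and the per-repetition boundaries derived from
#' the periodicity of the signal's peaks.
#'
#' @slot principalAxis integer in 1..3 (x, y, z).
#' @slot activeWindow numeric `c(t1, t2)`, seconds, within the recording
#'   span.
#' @slot cycleBounds strictly increasing boundary times (length
#'   `nCycles + 1`), all inside the active window.
#' @slot nCycles integer number of detected movement cycles.
#' @slot meanCycleDuration seconds; equals
#'   `diff(range(cycleBounds)) / nCycles`.
#' @slot dominantPeriod the autocorrelation-derived period estimate,
#'   seconds.
#' @seealso [segmentRecording()]
#' @export
setClass("SegmentationResult",
  representation(
    principalAxis = "integer",
    activeWindow = "numeric",
    cycleBounds = "numeric",
    nCycles = "integer",
    meanCycleDuration = "numeric",
    dominantPeriod = "numeric"
  )
)

setValidity("SegmentationResult", function(object) {
  msg <- character(0)
  if (length(object@principalAxis) != 1L ||
      !object@principalAxis %in% 1:3)
    msg <- c(msg, "principalAxis must be 1, 2 or 3")
  w <- object@activeWindow
  if (length(w) != 2L || !all(is.finite(w)) || w[1] >= w[2])
    msg <- c(msg, "activeWindow must be c(t1, t2) with t1 < t2")
  b <- object@cycleBounds
  if (object@nCycles < 1L)
    msg <- c(msg, "nCycles must be >= 1")
  if (length(b) != object@nCycles + 1L)
    msg <- c(msg, "cycleBounds must have length nCycles + 1")
  if (any(diff(b) <= 0))
    msg <- c(msg, "cycleBounds must be strictly increasing")
  if (length(w) == 2L && length(b) > 0L &&
      (min(b) < w[1] - 1e-9 || max(b) > w[2] + 1e-9))
    msg <- c(msg, "cycleBounds must lie within the active window")
  if (length(b) >= 2L &&
      abs(object@meanCycleDuration -
          (max(b) - min(b)) / object@nCycles) > 1e-9)
    msg <- c(msg, "meanCycleDuration inconsistent with cycleBounds")
  if (length(msg) > 0L) msg else TRUE
})

#' MetricSet: the movement-quality metrics of one recording
#'
#' Scalar summary of one segmented recording. Units follow the field's
#' reporting conventions: movement intensity in g, RAV in rad/s, kinetic
#' value in J/kg (m^2/s^2), DTW distance in m/s^2; LDLJ and regularity are
#' dimensionless.
#'
#' @slot cycleDuration mean repetition duration, s.
#' @slot ldlj log dimensionless jerk (negative; closer to zero = smoother).
#' @slot miMean mean movement intensity, g.
#' @slot miVar variability (SD) of movement intensity, g.
#' @slot rav range of angular velocity, rad/s.
#' @slot kineticValue work-done proxy, J/kg.
#' @slot regularityAd1 first-peak autocorrelation coefficient, in [-1, 1].
#' @slot dtwDistance mean path-normalised DTW distance between consecutive
#'   repetitions, m/s^2.
#' @slot nCycles repetition count from segmentation.
#' @seealso [computeMetricSet()]
#' @export
setClass("MetricSet",
  representation(
    cycleDuration = "numeric",
    ldlj = "numeric",
    miMean = "numeric",
    miVar = "numeric",
    rav = "numeric",
    kineticValue = "numeric",
    regularityAd1 = "numeric",
    dtwDistance = "numeric",
    nCycles = "integer"
  )
)

setValidity("MetricSet", function(object) {
  msg <- character(0)
  nonneg <- c(miMean = object@miMean, miVar = object@miVar,
              rav = object@rav, kineticValue = object@kineticValue,
              dtwDistance = object@dtwDistance)
  bad <- names(nonneg)[is.finite(nonneg) & nonneg < 0]
  if (length(bad) > 0L)
    msg <- c(msg, paste0("negative value for ", paste(bad, collapse = ", ")))
  if (is.finite(object@regularityAd1) && object@regularityAd1 > 1 + 1e-12)
    msg <- c(msg, "regularityAd1 cannot exceed 1")
  if (length(msg) > 0L) msg else TRUE
})

#' ColumnMap: mapping from file columns to IMU channels
#'
#' Describes how the columns of a delimited text file map onto the required
#' channels (time or sample index, triaxial acceleration, triaxial angular
#' velocity, optional magnetometer) and in which units the accelerometer
#' and gyroscope values are declared. This makes the reader configurable
#' for externally deposited files whose schema differs from the canonical
#' one written by [writeRecording()].
#'
#' @slot time column name for the timestamp, or `NA` when time is implicit
#'   from the sampling rate.
#' @slot accel,gyro character(3) of column names (x, y, z order).
#' @slot mag character(3) of magnetometer columns or `character(0)`.
#' @slot accelUnit `"mps2"` or `"g"`.
#' @slot gyroUnit `"rads"` or `"dps"`.
#' @seealso [columnMap()], [readColumnMap()]
#' @export
setClass("ColumnMap",
  representation(
    time = "character",
    accel = "character",
    gyro = "character",
    mag = "character",
    accelUnit = "character",
    gyroUnit = "character"
  )
)

setValidity("ColumnMap", function(object) {
  msg <- character(0)
  if (length(object@accel) != 3L) msg <- c(msg, "accel must map 3 columns")
  if (length(object@gyro) != 3L) msg <- c(msg, "gyro must map 3 columns")
  if (!length(object@mag) %in% c(0L, 3L))
    msg <- c(msg, "mag must map 0 or 3 columns")
  if (!object@accelUnit %in% c("mps2", "g"))
    msg <- c(msg, "accelUnit must be 'mps2' or 'g'")
  if (!object@gyroUnit %in% c("rads", "dps"))
    msg <- c(msg, "gyroUnit must be 'rads' or 'dps'")
  mapped <- c(if (!is.na(object@time)) object@time,
              object@accel, object@gyro, object@mag)
  dup <- unique(mapped[duplicated(mapped)])
  if (length(dup) > 0L)
    msg <- c(msg, sprintf("column(s) mapped more than once: %s",
                          paste(dup, collapse = ", ")))
  if (length(msg) > 0L) msg else TRUE
})

#' ExerciseTemplate: generative parameters of one synthetic exercise
#'
#' Parameters of the synthetic-recording generator for one exercise. The
#' default cycle durations are the paces demonstrated in the instruction
#' videos; the acceleration signal is produced by rotating the gravity
#' vector through a minimum-jerk tilt trajectory each cycle, plus dynamic
#' acceleration bursts (large for the cardiorespiratory mountain climber,
#' small for the slow strengthening exercises).
#'
#' @slot name one of [exerciseNames()].
#' @slot cycleDuration nominal repetition duration, s.
#' @slot nReps number of repetitions (the protocol instructs six to eight).
#' @slot tiltAmplitude peak gravity-vector rotation per cycle, rad,
#'   in (0, pi].
#' @slot rotationAxis sensor axis (1..3) about which the tilt occurs.
#' @slot dynamicBurstG peak dynamic acceleration per cycle, g.
#' @slot gyroAmplitude extra angular-velocity wobble amplitude, rad/s.
#' @slot burstFreq frequency of the dynamic burst oscillation, Hz.
#' @seealso [exerciseTemplate()], [generateRecording()]
#' @export
setClass("ExerciseTemplate",
  representation(
    name = "character",
    cycleDuration = "numeric",
    nReps = "integer",
    tiltAmplitude = "numeric",
    rotationAxis = "integer",
    dynamicBurstG = "numeric",
    gyroAmplitude = "numeric",
    burstFreq = "numeric"
  )
)

setValidity("ExerciseTemplate", function(object) {
  msg <- character(0)
  if (!object@name %in% .EXERCISES)
    msg <- c(msg, sprintf("unknown exercise '%s'", object@name))
  if (object@cycleDuration <= 0) msg <- c(msg, "cycleDuration must be > 0")
  if (object@nReps < 2L) msg <- c(msg, "nReps must be >= 2")
  if (object@tiltAmplitude <= 0 || object@tiltAmplitude > pi)
    msg <- c(msg, "tiltAmplitude must be in (0, pi]")
  if (!object@rotationAxis %in% 1:3)
    msg <- c(msg, "rotationAxis must be 1, 2 or 3")
  if (object@dynamicBurstG < 0) msg <- c(msg, "dynamicBurstG must be >= 0")
  if (length(msg) > 0L) msg else TRUE
})

#' PerturbationConfig: realism perturbations for the generator
#'
#' Controls the deviations from a perfectly periodic exercise recording:
#' cycle-to-cycle duration and amplitude jitter, sub-movement bursts that
#' degrade smoothness, wide-band sensor noise, and quiescent lead-in /
#' lead-out. All-zero perturbations give an exactly periodic, noise-free
#' signal.
#'
#' @slot durationJitter fractional SD of the per-cycle duration.
#' @slot amplitudeJitter fractional SD of the per-cycle tilt amplitude.
#' @slot submovementRate expected sub-movement bursts per cycle.
#' @slot submovementAmp sub-movement burst amplitude, m/s^2.
#' @slot noiseAccelSd accelerometer white-noise SD, m/s^2.
#' @slot noiseGyroSd gyroscope white-noise SD, rad/s.
#' @slot leadIn,leadOut quiescence before/after the repetitions, s.
#' @slot seed integer random seed; identical seeds give identical
#'   recordings.
#' @seealso [perturbationConfig()], [generateRecording()]
#' @export
setClass("PerturbationConfig",
  representation(
    durationJitter = "numeric",
    amplitudeJitter = "numeric",
    submovementRate = "numeric",
    submovementAmp = "numeric",
    noiseAccelSd = "numeric",
    noiseGyroSd = "numeric",
    leadIn = "numeric",
    leadOut = "numeric",
    seed = "integer"
  )
)

setValidity("PerturbationConfig", function(object) {
  vals <- c(durationJitter = object@durationJitter,
            amplitudeJitter = object@amplitudeJitter,
            submovementRate = object@submovementRate,
            submovementAmp = object@submovementAmp,
            noiseAccelSd = object@noiseAccelSd,
            noiseGyroSd = object@noiseGyroSd,
            leadIn = object@leadIn, leadOut = object@leadOut)
  bad <- names(vals)[vals < 0]
  if (length(bad) > 0L)
    paste0("negative value for ", paste(bad, collapse = ", "))
  else TRUE
})
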