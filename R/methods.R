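#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname imu-accessors
setMethod("accel", "IMURecording", function(object) object@accel)

#' @rdname imu-accessors
setMethod("gyro", "IMURecording", function(object) object@gyro)

#' @rdname imu-accessors
setMethod("magnetometer", "IMURecording", function(object) {
  if (nrow(object@mag) == 0L) NULL else object@mag
})

#' @rdname imu-accessors
setMethod("sampleTimes", "IMURecording", function(object) object@time)

#' @rdname imu-accessors
setMethod("samplingRate", "IMURecording", function(object) object@fs)

#' @rdname imu-accessors
setMethod("nSamples", "IMURecording", function(object) length(object@time))

#' @rdname imu-accessors
setMethod("recordingMeta", "IMURecording", function(object) object@meta)

#' @rdname imu-accessors
setMethod("principalAxis", "SegmentationResult",
          function(object) object@principalAxis)

#' @rdname imu-accessors
setMethod("activeWindow", "SegmentationResult",
          function(object) object@activeWindow)

#' @rdname imu-accessors
setMethod("cycleBounds", "SegmentationResult",
          function(object) object@cycleBounds)

#' @rdname imu-accessors
setMethod("nCycles", "SegmentationResult", function(object) object@nCycles)

#' @rdname imu-accessors
setMethod("nCycles", "MetricSet", function(object) object@nCycles)

#' @rdname imu-accessors
setMethod("meanCycleDuration", "SegmentationResult",
          function(object) object@meanCycleDuration)

#' @rdname imu-accessors
setMethod("dominantPeriod", "SegmentationResult",
          function(object) object@dominantPeriod)

setMethod("show", "IMURecording", function(object) {
  m <- object@meta
  dur <- diff(range(object@time))
  cat(sprintf("IMURecording: %d samples, %.1f s @ %g Hz\n",
              length(object@time), dur, object@fs))
  cat(sprintf("  subject: %s  exercise: %s  session: %s\n",
              m$subject, m$exercise, m$session))
  cat(sprintf("  channels: accel [m/s^2], gyro [rad/s]%s\n",
              if (nrow(object@mag) > 0L) ", mag" else ""))
})

setMethod("show", "SegmentationResult", function(object) {
  cat(sprintf("SegmentationResult: axis %s, window [%.2f, %.2f] s\n",
              c("x", "y", "z")[object@principalAxis],
              object@activeWindow[1], object@activeWindow[2]))
  cat(sprintf("  %d cycles, mean duration %.3f s (dominant period %.3f s)\n",
              object@nCycles, object@meanCycleDuration,
              object@dominantPeriod))
})

setMethod("show", "MetricSet", function(object) {
  cat("MetricSet:\n")
  cat(sprintf("  cycle duration  %8.3f s      (n = %d cycles)\n",
              object@cycleDuration, object@nCycles))
  cat(sprintf("  LDLJ            %8.3f\n", object@ldlj))
  cat(sprintf("  MI mean / var   %8.3f / %.3f g\n",
              object@miMean, object@miVar))
  cat(sprintf("  RAV             %8.3f rad/s\n", object@rav))
  cat(sprintf("  kinetic value   %8.3f J/kg\n", object@kineticValue))
  cat(sprintf("  regularity Ad1  %8.3f\n", object@regularityAd1))
  cat(sprintf("  DTW distance    %8.3f m/s^2\n", object@dtwDistance))
})

setMethod("show", "ExerciseTemplate", function(object) {
  cat(sprintf(
    "ExerciseTemplate '%s': %d reps of %.2f s, tilt %.2f rad, burst %.2f g\n",
    object@name, object@nReps, object@cycleDuration, object@tiltAmplitude,
    object@dynamicBurstG))
})

#' Coerce a MetricSet to a one-row data frame
#'
#' Produces the tidy serialization used in batch tables: one row with
#' columns `n_cycles`, `cycle_duration_s`, `ldlj`, `mi_mean_g`, `miv_g`,
#' `rav_rads`, `kinetic_jkg`, `regularity_ad1`, `dtw_mps2`.
#'
#' @param x a [MetricSet-class].
#' @param row.names,optional,... ignored (base signature).
#' @return A one-row `data.frame`.
#' @exportS3Method base::as.data.frame
#' @export
as.data.frame.MetricSet <- function(x, row.names = NULL, optional = FALSE,
                                    ...) {
  data.frame(
    n_cycles = x@nCycles,
    cycle_duration_s = x@cycleDuration,
    ldlj = x@ldlj,
    mi_mean_g = x@miMean,
    miv_g = x@miVar,
    rav_rads = x@rav,
    kinetic_jkg = x@kineticValue,
    regularity_ad1 = x@regularityAd1,
    dtw_mps2 = x@dtwDistance
  )
}

#' Names of the metric columns in tidy tables
#'
#' @return Character vector of the eight metric column names used by
#'   [runBatch()] and [summarizeSessions()].
#' @export
metricColumns <- function() {
  c("cycle_duration_s", "ldlj", "mi_mean_g", "miv_g", "rav_rads",
    "kinetic_jkg", "regularity_ad1", "dtw_mps2")
}
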