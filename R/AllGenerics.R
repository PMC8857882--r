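#' @include AllClasses.R
NULL

#' Accessors for IMU recordings and segmentation results
#'
#' Extract the components of an [IMURecording-class] or
#' [SegmentationResult-class] without touching slots directly.
#'
#' @param object an `IMURecording` or `SegmentationResult`.
#' @return The corresponding component: numeric vectors/matrices for the
#'   channel accessors, scalars for rates and counts, a named list for
#'   `recordingMeta`.
#' @name imu-accessors
#' @aliases accel gyro magnetometer sampleTimes samplingRate nSamples
#'   recordingMeta principalAxis activeWindow cycleBounds nCycles
#'   meanCycleDuration dominantPeriod
NULL

#' @rdname imu-accessors
#' @export
setGeneric("accel", function(object) standardGeneric("accel"))

#' @rdname imu-accessors
#' @export
setGeneric("gyro", function(object) standardGeneric("gyro"))

#' @rdname imu-accessors
#' @export
setGeneric("magnetometer", function(object) standardGeneric("magnetometer"))

#' @rdname imu-accessors
#' @export
setGeneric("sampleTimes", function(object) standardGeneric("sampleTimes"))

#' @rdname imu-accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @rdname imu-accessors
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))

#' @rdname imu-accessors
#' @export
setGeneric("recordingMeta", function(object) standardGeneric("recordingMeta"))

#' @rdname imu-accessors
#' @export
setGeneric("principalAxis", function(object) standardGeneric("principalAxis"))

#' @rdname imu-accessors
#' @export
setGeneric("activeWindow", function(object) standardGeneric("activeWindow"))

#' @rdname imu-accessors
#' @export
setGeneric("cycleBounds", function(object) standardGeneric("cycleBounds"))

#' @rdname imu-accessors
#' @export
setGeneric("nCycles", function(object) standardGeneric("nCycles"))

#' @rdname imu-accessors
#' @export
setGeneric("meanCycleDuration",
           function(object) standardGeneric("meanCycleDuration"))

#' @rdname imu-accessors
#' @export
setGeneric("dominantPeriod", function(object) standardGeneric("dominantPeriod"))
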