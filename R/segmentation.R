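#' @include AllClasses.R utils.R metrics-filter.R
NULL

#' Pipeline configuration
#'
#' Collects the tunable parameters of segmentation and metric computation
#' in one named list. Values can be overridden individually; unknown keys
#' are rejected.
#'
#' @param ... `key = value` overrides of the defaults below.
#' @return A named list with class `imuRehabConfig`:
#' \describe{
#'   \item{filterCutoffHz, filterOrder}{zero-phase Butterworth low-pass
#'     used before jerk computation (6 Hz, order 2).}
#'   \item{activityThreshold}{floor of the moving-SD activity threshold,
#'     m/s^2 (0.1).}
#'   \item{activityWindowS}{moving-SD window, s (1).}
#'   \item{activityGapS}{maximum sub-threshold dip bridged inside an
#'     active span, s (5) — covers the near-still dwell between
#'     repetitions of slow exercises.}
#'   \item{prominenceFraction}{peak prominence as a fraction of the
#'     signal's interquartile range (0.25).}
#'   \item{separationFraction}{minimum peak separation as a fraction of
#'     the dominant period (0.5).}
#'   \item{periodBounds}{plausible dominant-period range, s
#'     (c(0.25, 30)).}
#'   \item{periodPeakFraction}{fundamental-period guard: the dominant
#'     period is the smallest autocorrelation peak lag within this
#'     fraction of the highest peak (0.4).}
#'   \item{axisOverrides}{named list mapping exercise names to a fixed
#'     principal axis (1..3 or "x"/"y"/"z"); empty by default.}
#'   \item{kineticGravityMode}{"subtract_mean_magnitude" (default) or
#'     "none".}
#'   \item{regularityReps}{repetitions entering the regularity
#'     autocorrelation (5).}
#'   \item{regularityRemoveMean}{mean-centre before autocorrelation
#'     (TRUE).}
#' }
#' @examples
#' cfg <- pipelineConfig(axisOverrides = list(knee_extension = "z"))
#' cfg$filterCutoffHz
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    filterCutoffHz = 6,
    filterOrder = 2L,
    activityThreshold = 0.1,
    activityWindowS = 1,
    activityGapS = 5,
    prominenceFraction = 0.25,
    separationFraction = 0.5,
    periodBounds = c(0.25, 30),
    periodPeakFraction = 0.4,
    axisOverrides = list(),
    kineticGravityMode = "subtract_mean_magnitude",
    regularityReps = 5L,
    regularityRemoveMean = TRUE
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0L)
    .imuStop("configError", "unknown configuration key(s): %s",
             paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "imuRehabConfig")
}

.axisIndex <- function(axis) {
  if (is.character(axis)) {
    i <- match(tolower(axis), c("x", "y", "z"))
    if (is.na(i)) .imuStop("configError", "unknown axis '%s'", axis)
    return(i)
  }
  i <- as.integer(axis)
  if (!i %in% 1:3) .imuStop("configError", "axis index must be 1..3")
  i
}

#' Select the acceleration axis in which the movement predominantly occurs
#'
#' Different exercises express their movement on different sensor axes
#' (e.g. the longitudinal axis during supine knee extension, the frontal
#' axis during the advanced clam). If a per-exercise override is
#' configured it wins; otherwise the axis whose band-passed (0.1--6 Hz)
#' acceleration has the largest variance is chosen. Ties resolve to the
#' lowest axis index with a warning.
#'
#' @param rec an [IMURecording-class].
#' @param override optional fixed axis (1..3 or "x"/"y"/"z"), e.g. from
#'   `pipelineConfig()$axisOverrides[[exercise]]`.
#' @return Integer axis index in 1..3.
#' @export
selectPrincipalAxis <- function(rec, override = NULL) {
  if (!is.null(override)) return(.axisIndex(override))
  fs <- samplingRate(rec)
  a <- accel(rec)
  v <- vapply(1:3, function(k) {
    x <- a[, k]
    if (stats::sd(x) == 0) return(0)
    stats::var(bandpassFilter(x, fs, c(0.1, 6)))
  }, numeric(1))
  if (all(v <= .Machine$double.eps))
    .imuStop("degenerateInputError",
             "all acceleration axes are constant; no principal axis")
  best <- which(v >= max(v) - 1e-12 * max(v))
  if (length(best) > 1L)
    .imuWarn("axisTieWarning",
             "variance tie between axes %s; choosing the lowest index",
             paste(c("x", "y", "z")[best], collapse = ", "))
  best[1]
}

#' Extract the section of the trial that contains the repetitions
#'
#' Finds the longest contiguous span in which a centred moving-window
#' (default 1 s) standard deviation of the mean-removed signal exceeds an
#' activity threshold `max(activityThreshold, 10%% of the peak moving
#' SD)`, and expands it by half the moving window on each side (clipped to
#' the recording).
#'
#' @param signal numeric vector, the principal-axis acceleration, m/s^2.
#' @param fs sampling rate, Hz.
#' @param time optional vector of sample times; defaults to `(0:(N-1))/fs`.
#' @param config a [pipelineConfig()] list.
#' @return Numeric `c(t1, t2)` in seconds.
#' @export
extractActiveWindow <- function(signal, fs, time = NULL,
                                config = pipelineConfig()) {
  n <- length(signal)
  if (n < 2 * fs)
    .imuStop("degenerateInputError",
             "activity detection needs at least 2 s of signal")
  if (is.null(time)) time <- seq_len(n) / fs - 1 / fs
  w <- max(2L, round(config$activityWindowS * fs))
  ms <- movingSD(signal - mean(signal), w)
  thr <- max(config$activityThreshold, 0.1 * max(ms))
  active <- ms > thr
  if (!any(active))
    .imuStop("noActivityError",
             "no sample exceeds the activity threshold (%.3g m/s^2)", thr)
  # bridge brief sub-threshold dips (the near-still dwell between
  # repetitions of slow exercises) so one exercise bout stays one span
  r0 <- rle(active)
  ends0 <- cumsum(r0$lengths)
  gapMax <- round(config$activityGapS * fs)
  for (k in seq_along(r0$values)) {
    if (!r0$values[k] && k > 1L && k < length(r0$values) &&
        r0$lengths[k] <= gapMax)
      active[(ends0[k] - r0$lengths[k] + 1L):ends0[k]] <- TRUE
  }
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  k <- runs[which.max(r$lengths[runs])]
  i1 <- max(1L, starts[k] - w %/% 2L)
  i2 <- min(n, ends[k] + w %/% 2L)
  c(time[i1], time[i2])
}

#' Delimit individual repetitions from the periodicity of the signal
#'
#' Estimates the dominant period from the highest non-zero-lag peak of the
#' normalized (biased) autocorrelation of the mean-removed signal, detects
#' movement-cycle peaks (minimum separation half a period, minimum
#' prominence a quarter of the signal's interquartile range), and places
#' cycle boundaries at inter-peak midpoints, extrapolating half a period
#' outward at both ends (clipped to the window).
#'
#' @param signal numeric vector: principal-axis acceleration within the
#'   active window, m/s^2.
#' @param fs sampling rate, Hz.
#' @param time optional sample times (defaults to `(0:(N-1))/fs`); cycle
#'   bounds are reported on this time base.
#' @param config a [pipelineConfig()] list.
#' @return List with `cycleBounds` (length `nCycles + 1`), `nCycles`,
#'   `meanCycleDuration` (s), `dominantPeriod` (s) and `peakTimes`.
#' @export
segmentCycles <- function(signal, fs, time = NULL,
                          config = pipelineConfig()) {
  n <- length(signal)
  if (is.null(time)) time <- seq_len(n) / fs - 1 / fs
  x <- signal - mean(signal)
  if (stats::sd(x) == 0)
    .imuStop("tooFewRepetitionsError",
             "constant signal: no repetitions to segment")
  ac <- autocorrBiased(x)
  lo <- max(2L, ceiling(config$periodBounds[1] * fs))
  hi <- min(n - 1L, floor(config$periodBounds[2] * fs), n %/% 2L + 1L)
  if (hi <= lo)
    .imuStop("implausiblePeriodError",
             "signal too short for the plausible period range")
  seg <- ac[(lo + 1L):(hi + 1L)]          # lags lo..hi (ac[1] is lag 0)
  pk <- findPeaks(seg)
  if (length(pk) == 0L)
    .imuStop("tooFewRepetitionsError",
             "no periodicity peak in the autocorrelation")
  # subharmonic guard: cycle jitter can let a multiple of the period edge
  # out the fundamental, so take the smallest lag whose peak is within
  # periodPeakFraction of the best one
  strong <- pk[seg[pk] >= config$periodPeakFraction * max(seg[pk])]
  if (length(strong) == 0L) strong <- pk[which.max(seg[pk])]
  lagHat <- lo + strong[1] - 1L
  period <- lagHat / fs
  if (period < config$periodBounds[1] || period > config$periodBounds[2])
    .imuStop("implausiblePeriodError",
             "estimated period %.3g s outside plausible range", period)
  minSep <- max(1L, round(config$separationFraction * lagHat))
  prom <- config$prominenceFraction * stats::IQR(x)
  peaks <- findPeaks(x, minProminence = prom, minSeparation = minSep)
  if (length(peaks) < 2L)
    .imuStop("tooFewRepetitionsError",
             "fewer than 2 movement-cycle peaks detected")
  pt <- time[peaks]
  half <- period / 2
  bounds <- c(max(time[1], pt[1] - half),
              (pt[-length(pt)] + pt[-1]) / 2,
              min(time[n], pt[length(pt)] + half))
  nc <- length(peaks)
  list(cycleBounds = bounds, nCycles = nc,
       meanCycleDuration = (bounds[nc + 1L] - bounds[1]) / nc,
       dominantPeriod = period, peakTimes = pt)
}

#' Segment a recording into exercise repetitions
#'
#' Full segmentation of one recording: principal-axis selection (honouring
#' any configured per-exercise override), active-window extraction, and
#' repetition delimitation.
#'
#' @param rec an [IMURecording-class].
#' @param config a [pipelineConfig()] list; `config$axisOverrides` may fix
#'   the axis for the recording's exercise.
#' @param axis optional explicit axis override (takes precedence over the
#'   configured table).
#' @return A [SegmentationResult-class].
#' @examples
#' rec <- generateRecording(exerciseTemplate("half_squat"),
#'                          perturbationConfig(seed = 1))$recording
#' segmentRecording(rec)
#' @export
segmentRecording <- function(rec, config = pipelineConfig(), axis = NULL) {
  ex <- recordingMeta(rec)$exercise
  if (is.null(axis) && !is.na(ex) && ex %in% names(config$axisOverrides))
    axis <- config$axisOverrides[[ex]]
  ax <- selectPrincipalAxis(rec, override = axis)
  tm <- sampleTimes(rec)
  sig <- accel(rec)[, ax]
  win <- extractActiveWindow(sig, samplingRate(rec), time = tm,
                             config = config)
  idx <- .windowIndex(tm, win[1], win[2])
  cyc <- segmentCycles(sig[idx], samplingRate(rec), time = tm[idx],
                       config = config)
  methods::new("SegmentationResult",
    principalAxis = as.integer(ax),
    activeWindow = win,
    cycleBounds = cyc$cycleBounds,
    nCycles = as.integer(cyc$nCycles),
    meanCycleDuration = cyc$meanCycleDuration,
    dominantPeriod = cyc$dominantPeriod)
}
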