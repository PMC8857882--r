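#' @include AllClasses.R utils.R metrics-filter.R segmentation.R dtw.R
NULL

#' Log dimensionless jerk (LDLJ) movement smoothness
#'
#' Smoothness of the movement between `t1` and `t2` from the integrated
#' squared jerk of the (already low-pass filtered) triaxial acceleration:
#' \deqn{LDLJ = -\ln\!\left(\frac{t_2 - t_1}{a_{peak}^2}
#'   \int_{t_1}^{t_2} \dddot{x}^2 + \dddot{y}^2 + \dddot{z}^2 \, dt\right)}
#' where \eqn{a_{peak}} is the peak magnitude of the total acceleration
#' minus its mean over the same interval. The duration/amplitude factor
#' makes the quantity dimensionless; values closer to zero indicate
#' smoother movement (typical exercise recordings fall around -3 to -10).
#' Jerk is obtained by central differences (one-sided at the ends) and
#' integrated by the trapezoid rule.
#'
#' @param accel N x 3 matrix of low-pass filtered acceleration over the
#'   movement window, m/s^2 (see [lowpassFilter()]).
#' @param fs sampling rate, Hz.
#' @return Negative scalar (dimensionless).
#' @export
ldlj <- function(accel, fs) {
  accel <- as.matrix(accel)
  n <- nrow(accel)
  if (n < 3L)
    .imuStop("degenerateInputError", "LDLJ needs at least 3 samples")
  dt <- 1 / fs
  jerk2 <- numeric(n)
  for (k in seq_len(ncol(accel))) {
    a <- accel[, k]
    j <- c(a[2] - a[1],
           (a[3:n] - a[1:(n - 2)]) / 2,
           a[n] - a[n - 1]) / dt
    jerk2 <- jerk2 + j^2
  }
  integral <- trapz(jerk2, dt)
  mag <- sqrt(rowSums(accel^2))
  apeak <- max(mag) - mean(mag)
  if (apeak <= 0)
    .imuStop("degenerateInputError",
             "constant acceleration magnitude: LDLJ undefined")
  if (integral <= 0)
    .imuStop("degenerateInputError", "zero jerk: LDLJ undefined")
  duration <- (n - 1) * dt
  -log(duration / apeak^2 * integral)
}

#' Movement intensity (MI) and its variability
#'
#' Movement intensity is the Euclidean norm of the raw triaxial
#' acceleration expressed in g:
#' \deqn{MI(t) = \sqrt{\ddot{x}^2 + \ddot{y}^2 + \ddot{z}^2} / g.}
#' The summary is its mean and its variability (standard deviation) over
#' the window. No filtering is applied; the metric is independent of
#' sensor orientation, and near-periodic movement without intensity bursts
#' yields a mean close to 1 g with variability close to 0 g.
#'
#' @param accel N x 3 matrix of raw acceleration, m/s^2.
#' @return Named numeric `c(mi_mean, mi_var)` in g.
#' @examples
#' movementIntensity(cbind(0, 0, rep(standardGravity(), 100)))
#' @export
movementIntensity <- function(accel) {
  accel <- as.matrix(accel)
  mi <- sqrt(rowSums(accel^2)) / .GRAVITY
  c(mi_mean = mean(mi),
    mi_var = if (length(mi) > 1L) stats::sd(mi) else 0)
}

#' Range of angular velocity (RAV)
#'
#' Magnitude of the rotational velocity: within each repetition the
#' minimum of the Euclidean norm of the raw angular velocity is subtracted
#' from its maximum, and the per-repetition ranges are averaged.
#'
#' @param gyro N x 3 matrix of raw angular velocity, rad/s.
#' @param cycleBounds repetition boundary times (length nCycles + 1), s.
#' @param time sample times matching `gyro` rows, s.
#' @return Scalar, rad/s.
#' @export
rav <- function(gyro, cycleBounds, time) {
  gyro <- as.matrix(gyro)
  wmag <- sqrt(rowSums(gyro^2))
  nc <- length(cycleBounds) - 1L
  if (nc < 1L)
    .imuStop("degenerateInputError", "RAV needs at least one repetition")
  ranges <- vapply(seq_len(nc), function(r) {
    idx <- .windowIndex(time, cycleBounds[r], cycleBounds[r + 1L])
    if (length(idx) == 0L)
      .imuStop("segmentationConsistencyError",
               "repetition %d contains no samples", r)
    max(wmag[idx]) - min(wmag[idx])
  }, numeric(1))
  mean(ranges)
}

#' Kinetic value (work-done proxy)
#'
#' An indicator of the work done per unit mass over the exercise: the
#' squared time-integral of the resultant acceleration over the active
#' window, divided by two (units m^2/s^2 = J/kg). Integrating the raw
#' gravity-inclusive magnitude over tens of seconds is dominated by the
#' ~9.81 m/s^2 baseline, so the default mode integrates the absolute
#' deviation of the magnitude from its window mean; mode `"none"`
#' integrates the raw magnitude literally.
#'
#' @param accel N x 3 matrix of raw acceleration over the active window,
#'   m/s^2.
#' @param fs sampling rate, Hz.
#' @param gravityMode `"subtract_mean_magnitude"` (default) or `"none"`.
#' @return Scalar, J/kg.
#' @export
kineticValue <- function(accel, fs, gravityMode = c("subtract_mean_magnitude",
                                                    "none")) {
  gravityMode <- match.arg(gravityMode)
  accel <- as.matrix(accel)
  if (nrow(accel) < 2L)
    .imuStop("degenerateInputError", "kinetic value needs >= 2 samples")
  mag <- sqrt(rowSums(accel^2))
  if (gravityMode == "subtract_mean_magnitude")
    mag <- abs(mag - mean(mag))
  v <- trapz(mag, 1 / fs)
  v^2 / 2
}

#' Movement regularity from the autocorrelation first peak (Ad1)
#'
#' Similarity between neighbouring exercise repetitions: the mean-removed
#' principal-axis acceleration of the first `nReps` repetitions is
#' compared with a delayed copy of itself through the biased
#' autocorrelation \eqn{A(m) = (1/N)\sum_{i=1}^{N-m} a_i a_{i+m}},
#' normalised by the zero-lag maximum so coefficients peak at 1. The
#' coefficient reported (Ad1) is the first local maximum located near the
#' dominant period (searched within 0.5--1.5 periods, guarding against
#' spurious near-zero-lag maxima). Because recordings with different
#' lengths are not comparable under this estimator, only the first five
#' repetitions enter by default.
#'
#' @param signal principal-axis acceleration, m/s^2.
#' @param fs sampling rate, Hz.
#' @param cycleBounds repetition boundary times, s.
#' @param time sample times matching `signal`, s.
#' @param nReps repetitions to use (default 5); if fewer are available all
#'   are used with a warning.
#' @param period optional dominant period, s; defaults to the mean
#'   repetition duration implied by `cycleBounds`.
#' @param removeMean mean-centre before autocorrelation (default TRUE).
#' @return Scalar Ad1 in [-1, 1].
#' @export
regularity <- function(signal, fs, cycleBounds, time, nReps = 5L,
                       period = NULL, removeMean = TRUE) {
  nc <- length(cycleBounds) - 1L
  if (nc < 1L)
    .imuStop("degenerateInputError", "regularity needs >= 1 repetition")
  if (nc < nReps) {
    .imuWarn("fewRepetitionsWarning",
             "only %d repetitions available (requested %d); using all",
             nc, nReps)
    nReps <- nc
  }
  idx <- .windowIndex(time, cycleBounds[1], cycleBounds[nReps + 1L])
  x <- signal[idx]
  if (removeMean) x <- x - mean(x)
  if (stats::sd(x) == 0)
    .imuStop("degenerateInputError",
             "zero-variance signal: regularity undefined")
  if (is.null(period))
    period <- (cycleBounds[nReps + 1L] - cycleBounds[1]) / nReps
  ac <- autocorrBiased(x)
  n <- length(x)
  lagHat <- round(period * fs)
  lo <- max(2L, floor(0.5 * lagHat))
  hi <- min(n - 1L, ceiling(1.5 * lagHat))
  if (hi <= lo)
    .imuStop("degenerateInputError",
             "signal too short relative to the dominant period")
  seg <- ac[(lo + 1L):(hi + 1L)]
  pk <- findPeaks(seg)
  if (length(pk) == 0L) {
    # no interior maximum: fall back to the largest coefficient in range
    return(max(seg))
  }
  seg[pk[1]]
}

#' Movement stability from dynamic time warping (DTW)
#'
#' Compares the acceleration signals of consecutive repetitions of the
#' same recording. Each consecutive pair is aligned by classic DTW
#' (absolute-difference local cost, symmetric steps, no window
#' constraint); the pair distance is the accumulated cost at the end point
#' normalised by the optimal warping-path length, and the recording-level
#' value is the mean over all consecutive pairs. Smaller values indicate
#' better control: successive repetitions that can be aligned with little
#' residual difference.
#'
#' @param signal principal-axis acceleration, m/s^2.
#' @param cycleBounds repetition boundary times, s.
#' @param time sample times matching `signal`, s.
#' @return Scalar mean normalised distance, m/s^2.
#' @seealso [dtwDistance()] for a single pair.
#' @export
dtwStability <- function(signal, cycleBounds, time) {
  nc <- length(cycleBounds) - 1L
  if (nc < 2L)
    .imuStop("degenerateInputError", "DTW stability needs >= 2 repetitions")
  reps <- lapply(seq_len(nc), function(r) {
    idx <- .windowIndex(time, cycleBounds[r], cycleBounds[r + 1L])
    if (length(idx) < 2L)
      .imuStop("segmentationConsistencyError",
               "repetition %d has fewer than 2 samples", r)
    signal[idx]
  })
  d <- vapply(seq_len(nc - 1L), function(r) {
    dtwDistance(reps[[r]], reps[[r + 1L]])$normalized
  }, numeric(1))
  mean(d)
}

#' Compute the full metric set of a segmented recording
#'
#' Assembles the eight movement-quality metrics of one recording. Only
#' the jerk-based smoothness uses low-pass filtered acceleration; all
#' other metrics operate on the raw signals. LDLJ, movement intensity and
#' the kinetic value are computed over the active window; RAV, regularity
#' and DTW use the per-repetition boundaries; the cycle duration is taken
#' from the segmentation.
#'
#' @param rec an [IMURecording-class].
#' @param seg a [SegmentationResult-class] for `rec`; computed on the fly
#'   when `NULL`.
#' @param config a [pipelineConfig()] list.
#' @return A [MetricSet-class].
#' @examples
#' rec <- generateRecording(exerciseTemplate("half_squat"),
#'                          perturbationConfig(seed = 7))$recording
#' computeMetricSet(rec)
#' @export
computeMetricSet <- function(rec, seg = NULL, config = pipelineConfig()) {
  if (is.null(seg)) seg <- segmentRecording(rec, config = config)
  tm <- sampleTimes(rec)
  fs <- samplingRate(rec)
  win <- activeWindow(seg)
  idx <- .windowIndex(tm, win[1], win[2])
  araw <- accel(rec)[idx, , drop = FALSE]
  graw <- gyro(rec)[idx, , drop = FALSE]
  twin <- tm[idx]
  ax <- principalAxis(seg)
  bounds <- cycleBounds(seg)

  wrap <- function(metric, expr) {
    tryCatch(expr, error = function(e) {
      .imuStop("metricError", "metric '%s' failed: %s",
               metric, conditionMessage(e))
    })
  }

  afilt <- wrap("ldlj", lowpassFilter(araw, fs, fc = config$filterCutoffHz,
                                      order = config$filterOrder))
  mi <- wrap("movement_intensity", movementIntensity(araw))
  methods::new("MetricSet",
    cycleDuration = meanCycleDuration(seg),
    ldlj = wrap("ldlj", ldlj(afilt, fs)),
    miMean = unname(mi["mi_mean"]),
    miVar = unname(mi["mi_var"]),
    rav = wrap("rav", rav(graw, bounds, twin)),
    kineticValue = wrap("kinetic_value",
                        kineticValue(araw, fs,
                                     gravityMode = config$kineticGravityMode)),
    regularityAd1 = wrap("regularity",
      regularity(araw[, ax], fs, bounds, twin,
                 nReps = config$regularityReps,
                 period = dominantPeriod(seg),
                 removeMean = config$regularityRemoveMean)),
    dtwDistance = wrap("dtw", dtwStability(araw[, ax], bounds, twin)),
    nCycles = nCycles(seg))
}
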