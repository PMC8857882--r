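#' @include AllClasses.R utils.R imu-io.R
NULL

## per-exercise generator defaults:
## cycle duration = pace demonstrated in the instruction videos (s);
## labPace = typical participant pace in the supervised session (s);
## tilt/burst/wobble chosen to reproduce the character of each task
## (slow strengthening movements are gravity-reorientation dominated,
## the cardiorespiratory mountain climber adds large dynamic bursts).
.TEMPLATES <- list(
  knee_extension = list(demoPace = 12.5, labPace = 7.5, tilt = 0.9,
                        axis = 1L, burstG = 0.18, wobble = 0.10),
  split_squat = list(demoPace = 4.4, labPace = 3.7, tilt = 0.5,
                     axis = 2L, burstG = 0.18, wobble = 0.15),
  clam_advanced = list(demoPace = 8.0, labPace = 4.0, tilt = 0.7,
                       axis = 1L, burstG = 0.21, wobble = 0.10),
  half_squat = list(demoPace = 4.4, labPace = 3.5, tilt = 0.4,
                    axis = 2L, burstG = 0.09, wobble = 0.10),
  mountain_climber = list(demoPace = 2.2, labPace = 1.7, tilt = 0.5,
                          axis = 1L, burstG = 2.70, wobble = 1.00)
)

#' Demonstration and typical lab paces per exercise
#'
#' `demoPaces()` returns the cycle durations demonstrated by the
#' physiotherapist in the instruction videos (the reference tempo for
#' adherence); `labPaces()` the typical participant pace in the
#' supervised session used as the cohort-generator baseline.
#'
#' @return Named numeric vector, seconds per repetition.
#' @export
demoPaces <- function() {
  vapply(.TEMPLATES, function(t) t$demoPace, numeric(1))
}

#' @rdname demoPaces
#' @export
labPaces <- function() {
  vapply(.TEMPLATES, function(t) t$labPace, numeric(1))
}

#' Construct an exercise template
#'
#' Generative parameters for one synthetic exercise recording. Defaults
#' follow the per-exercise demonstration paces (knee extension 12.5 s,
#' split squat 4.4 s, advanced clam 8 s, half squat 4.4 s, mountain
#' climber 2.2 s) and seven repetitions (the protocol instructs six to
#' eight).
#'
#' @param name one of [exerciseNames()].
#' @param cycleDuration repetition duration, s.
#' @param nReps number of repetitions.
#' @param tiltAmplitude peak gravity-vector rotation per cycle, rad.
#' @param rotationAxis sensor axis (1..3) about which the tilt occurs.
#' @param dynamicBurstG peak dynamic acceleration per cycle, g.
#' @param gyroAmplitude extra angular-velocity wobble, rad/s.
#' @param burstFreq burst oscillation frequency, Hz; default one
#' oscillation per cycle (one acceleration and one deceleration phase).
#' @return An [ExerciseTemplate-class].
#' @export
exerciseTemplate <- function(name, cycleDuration = NULL, nReps = 7L,
                             tiltAmplitude = NULL, rotationAxis = NULL,
                             dynamicBurstG = NULL, gyroAmplitude = NULL,
                             burstFreq = NULL) {
  if (!name %in% names(.TEMPLATES))
    .imuStop("configError", "unknown exercise '%s'", name)
  d <- .TEMPLATES[[name]]
  if (is.null(cycleDuration)) cycleDuration <- d$demoPace
  if (is.null(tiltAmplitude)) tiltAmplitude <- d$tilt
  if (is.null(rotationAxis)) rotationAxis <- d$axis
  if (is.null(dynamicBurstG)) dynamicBurstG <- d$burstG
  if (is.null(gyroAmplitude)) gyroAmplitude <- d$wobble
  if (is.null(burstFreq)) burstFreq <- 1 / cycleDuration
  methods::new("ExerciseTemplate",
    name = name, cycleDuration = as.numeric(cycleDuration),
    nReps = as.integer(nReps), tiltAmplitude = as.numeric(tiltAmplitude),
    rotationAxis = as.integer(rotationAxis),
    dynamicBurstG = as.numeric(dynamicBurstG),
    gyroAmplitude = as.numeric(gyroAmplitude),
    burstFreq = as.numeric(burstFreq))
}

#' Construct a perturbation configuration
#'
#' @param durationJitter fractional SD of the per-cycle duration.
#' @param amplitudeJitter fractional SD of the per-cycle tilt.
#' @param submovementRate expected sub-movement bursts per cycle.
#' @param submovementAmp sub-movement amplitude, m/s^2.
#' @param noiseAccelSd accelerometer noise SD, m/s^2.
#' @param noiseGyroSd gyroscope noise SD, rad/s.
#' @param leadIn,leadOut quiescence before/after the repetitions, s.
#' @param seed integer random seed.
#' @return A [PerturbationConfig-class].
#' @export
perturbationConfig <- function(durationJitter = 0, amplitudeJitter = 0,
                               submovementRate = 0, submovementAmp = 0,
                               noiseAccelSd = 0, noiseGyroSd = 0,
                               leadIn = 3, leadOut = 3, seed = 1L) {
  methods::new("PerturbationConfig",
    durationJitter = durationJitter, amplitudeJitter = amplitudeJitter,
    submovementRate = submovementRate, submovementAmp = submovementAmp,
    noiseAccelSd = noiseAccelSd, noiseGyroSd = noiseGyroSd,
    leadIn = leadIn, leadOut = leadOut, seed = as.integer(seed))
}

#' Default realism perturbations per exercise
#'
#' Cycle-to-cycle jitter and sensor-noise defaults emulating the observed
#' character of each task: the fast cardiorespiratory mountain climber is
#' intrinsically harder to repeat consistently and receives about three
#' times the jitter of the slow strengthening exercises.
#'
#' @param exercise one of [exerciseNames()].
#' @param seed random seed.
#' @return A [PerturbationConfig-class].
#' @export
defaultPerturbation <- function(exercise, seed = 1L) {
  fast <- identical(exercise, "mountain_climber")
  perturbationConfig(
    durationJitter = if (fast) 0.12 else 0.04,
    amplitudeJitter = if (fast) 0.15 else 0.05,
    submovementRate = if (fast) 2 else 1,
    submovementAmp = if (fast) 0.8 else 0.25,
    noiseAccelSd = 0.03, noiseGyroSd = 0.005,
    leadIn = 3, leadOut = 3, seed = seed)
}

## run expr under a locally seeded RNG, restoring the caller's state
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic shank-IMU exercise recording
#'
#' Produces an accelerometer/gyroscope recording emulating repetitions of
#' one exercise. Each cycle rotates the gravity vector by a minimum-jerk
#' tilt trajectory (out and back) about the template's rotation axis —
#' the mechanism by which real shank recordings acquire their periodicity
#' — and adds a Gaussian-windowed dynamic-acceleration burst directed
#' along the instantaneous gravity direction (so the acceleration norm,
#' and hence movement intensity, scales directly with the burst
#' parameter). The gyroscope carries the analytic angular velocity of the
#' tilt plus a secondary wobble. Perturbations add per-cycle duration and
#' amplitude jitter, sub-movement bursts (4 Hz, degrading smoothness) and
#' white sensor noise. Identical seeds give bit-identical recordings.
#'
#' @param template an [ExerciseTemplate-class].
#' @param perturb a [PerturbationConfig-class].
#' @param fs sampling rate, Hz (nominal 246).
#' @param session,subject metadata stored in the recording.
#' @return List with `recording` (an [IMURecording-class]) and `truth`:
#'   per-cycle start times, durations and tilt amplitudes, plus the lead-in
#'   used.
#' @examples
#' out <- generateRecording(exerciseTemplate("mountain_climber", nReps = 5),
#'                          perturbationConfig(seed = 42))
#' out$truth$cycleDurations
#' @export
generateRecording <- function(template, perturb = perturbationConfig(),
                              fs = 246, session = "lab",
                              subject = NA_character_) {
  methods::validObject(template)
  methods::validObject(perturb)
  if (fs < 20 / template@cycleDuration)
    .imuStop("configError",
             "sampling rate %g Hz too low for %g s cycles", fs,
             template@cycleDuration)
  .withSeed(perturb@seed, {
    nR <- template@nReps
    dur <- template@cycleDuration *
      pmax(0.2, 1 + stats::rnorm(nR, 0, perturb@durationJitter))
    tilt <- template@tiltAmplitude *
      pmax(0.05, 1 + stats::rnorm(nR, 0, perturb@amplitudeJitter))
    starts <- perturb@leadIn + c(0, cumsum(dur[-nR]))
    total <- perturb@leadIn + sum(dur) + perturb@leadOut
    n <- floor(total * fs) + 1L
    tm <- (seq_len(n) - 1L) / fs

    theta <- numeric(n)
    omega <- numeric(n)
    burst <- numeric(n)
    subm <- numeric(n)
    for (k in seq_len(nR)) {
      idx <- which(tm >= starts[k] & tm < starts[k] + dur[k])
      tau <- (tm[idx] - starts[k]) / dur[k]      # 0..1 within the cycle
      # out-and-back minimum-jerk tilt: first half up, second half down
      up <- tau < 0.5
      theta[idx] <- tilt[k] * ifelse(up, minJerkPos(2 * tau),
                                     minJerkPos(2 * (1 - tau)))
      omega[idx] <- tilt[k] * (2 / dur[k]) *
        ifelse(up, minJerkVel(2 * tau), -minJerkVel(2 * (1 - tau)))
      # dynamic burst: Gaussian-windowed sinusoid centred mid-cycle
      if (template@dynamicBurstG > 0) {
        sig <- 0.12 * dur[k]
        centre <- starts[k] + dur[k] / 2
        b <- template@dynamicBurstG * .GRAVITY *
          exp(-((tm[idx] - centre)^2) / (2 * sig^2)) *
          cos(2 * pi * template@burstFreq * (tm[idx] - centre))
        # zero-mean within the cycle: intensity fluctuates around 1 g
        # (MIV tracks the burst amplitude) without shifting the mean
        burst[idx] <- b - mean(b)
      }
      # sub-movements: short 4 Hz wiggles at random positions in the cycle
      nSub <- stats::rpois(1, perturb@submovementRate)
      if (nSub > 0 && perturb@submovementAmp > 0) {
        centres <- starts[k] + stats::runif(nSub, 0.1, 0.9) * dur[k]
        for (ct in centres) {
          w <- 0.12                               # burst width, s
          subm <- subm + perturb@submovementAmp *
            exp(-((tm - ct)^2) / (2 * w^2)) * sin(2 * pi * 4 * (tm - ct))
        }
      }
    }

    axR <- template@rotationAxis
    # gravity direction in the sensor frame under rotation by theta about
    # axis axR: the axis orthogonal to both picks up sin(theta)
    gdir <- matrix(0, n, 3)
    other <- c(2L, 1L, 1L)[axR]      # axis receiving the sin component
    gdir[, other] <- sin(theta)
    gdir[, 3L] <- cos(theta)
    if (axR == 3L) {                  # rotation about z tilts x instead
      gdir[, 1L] <- sin(theta); gdir[, 2L] <- 0
    }
    acc <- gdir * (.GRAVITY + burst)
    acc[, other] <- acc[, other] + subm
    if (perturb@noiseAccelSd > 0)
      acc <- acc + matrix(stats::rnorm(3 * n, 0, perturb@noiseAccelSd),
                          n, 3)

    gyr <- matrix(0, n, 3)
    gyr[, axR] <- omega
    wobbleAxis <- if (axR == 1L) 3L else 1L
    if (template@gyroAmplitude > 0) {
      act <- tm >= perturb@leadIn & tm <= total - perturb@leadOut
      gyr[act, wobbleAxis] <- template@gyroAmplitude *
        sin(2 * pi * template@burstFreq * tm[act])
    }
    if (perturb@noiseGyroSd > 0)
      gyr <- gyr + matrix(stats::rnorm(3 * n, 0, perturb@noiseGyroSd),
                          n, 3)

    rec <- IMURecording(accel = acc, gyro = gyr, fs = fs, time = tm,
                        subject = subject, exercise = template@name,
                        session = session)
    list(recording = rec,
         truth = list(cycleStarts = starts, cycleDurations = dur,
                      tiltAmplitudes = tilt,
                      meanCycleDuration = mean(dur),
                      leadIn = perturb@leadIn))
  })
}

#' Generate a synthetic study cohort
#'
#' Emulates a two-session study design: `nSubjects` subjects each perform the five
#' exercises in a supervised lab session and an unsupervised home
#' session. Per-exercise baseline paces default to the typical lab paces
#' ([labPaces()]); subjects receive lognormal pace and amplitude offsets
#' (mean 1), and home sessions are scaled by per-exercise pace
#' multipliers — by default the home pace is reduced for knee extension
#' (0.77) and mountain climber (0.88) and unchanged otherwise.
#'
#' @param nSubjects number of subjects.
#' @param exercises exercises to include (default all five).
#' @param sessionEffects named numeric vector/list of home-pace
#'   multipliers per exercise; exercises not named get 1.
#' @param paces named baseline cycle durations, s; default [labPaces()].
#' @param subjectSdLog SD (log scale) of the subject pace offset.
#' @param seed integer master seed; per-recording seeds are derived from
#'   it deterministically.
#' @param outDir when non-`NULL`, recordings are written there as
#'   canonical CSV (plus sidecars) via [writeRecording()] together with a
#'   `manifest.csv`.
#' @return List with `manifest` (data.frame: file, subject, exercise,
#'   session, n_reps, true_cycle_duration, seed) and `recordings` (list of
#'   [IMURecording-class], named as the manifest's `file` column; kept in
#'   memory also when files are written).
#' @export
generateCohort <- function(nSubjects = 30L,
                           exercises = exerciseNames(),
                           sessionEffects = c(knee_extension = 0.77,
                                              mountain_climber = 0.88),
                           paces = labPaces(),
                           subjectSdLog = 0.18,
                           seed = 1L, outDir = NULL) {
  if (nSubjects < 1L)
    .imuStop("configError", "nSubjects must be >= 1")
  sessions <- c("lab", "home")
  rows <- list()
  recs <- list()
  i <- 0L
  subjOffset <- .withSeed(seed, {
    matrix(stats::rlnorm(nSubjects * length(exercises),
                         meanlog = -subjectSdLog^2 / 2,
                         sdlog = subjectSdLog),
           nSubjects, length(exercises))
  })
  nrepsDraw <- .withSeed(seed + 1000L, {
    matrix(sample(6:8, nSubjects * length(exercises) * 2, replace = TRUE),
           ncol = 2)
  })
  for (s in seq_len(nSubjects)) {
    for (e in seq_along(exercises)) {
      ex <- exercises[e]
      for (sess in sessions) {
        i <- i + 1L
        mult <- 1
        if (sess == "home" && ex %in% names(sessionEffects))
          mult <- as.numeric(sessionEffects[[ex]])
        pace <- paces[[ex]] * subjOffset[s, e] * mult
        nReps <- nrepsDraw[(s - 1L) * length(exercises) + e,
                           match(sess, sessions)]
        recSeed <- (seed + 7919L * i) %% .Machine$integer.max
        tpl <- exerciseTemplate(ex, cycleDuration = pace, nReps = nReps)
        out <- generateRecording(tpl, defaultPerturbation(ex, seed = recSeed),
                                 session = sess,
                                 subject = sprintf("S%02d", s))
        fname <- sprintf("S%02d_%s_%s.csv", s, ex, sess)
        rows[[i]] <- data.frame(
          file = fname, subject = sprintf("S%02d", s), exercise = ex,
          session = sess, n_reps = nReps,
          true_cycle_duration = out$truth$meanCycleDuration,
          seed = recSeed)
        recs[[fname]] <- out$recording
      }
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    for (f in names(recs))
      writeRecording(recs[[f]], file.path(outDir, f))
    utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(manifest = manifest, recordings = recs)
}
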