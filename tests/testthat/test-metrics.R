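# The eight movement-quality metrics against closed forms, invariances
# and paired comparisons on generator output.

test_that("movement intensity of a gravity-only rest recording is 1 g", {
  mi <- movementIntensity(accel(restRecording()))
  expect_identical(unname(mi["mi_mean"]), 1)
  expect_identical(unname(mi["mi_var"]), 0)
})

test_that("movement intensity is rotation invariant", {
  set.seed(3)
  a <- matrix(rnorm(300, sd = 2), 100, 3)
  a[, 3] <- a[, 3] + standardGravity()
  R <- randomRotation(7)
  expect_equal(movementIntensity(a %*% R), movementIntensity(a),
               tolerance = 1e-12)
})

test_that("intensity variability vanishes for constant-magnitude signals", {
  tt <- (0:999) / 246
  a <- standardGravity() * cbind(cos(2 * pi * tt), sin(2 * pi * tt), 0)
  mi <- movementIntensity(a)
  expect_equal(unname(mi["mi_mean"]), 1, tolerance = 1e-12)
  expect_lt(unname(mi["mi_var"]), 1e-12)
})

test_that("LDLJ matches the closed form for a sinusoidal acceleration", {
  # a(t) = A sin(w t): jerk amplitude A w, integrated squared jerk
  # A^2 w^2 T / 2 over whole periods; peak-minus-mean of |a| is
  # A (1 - 2/pi). The result is independent of A.
  fs <- 246; f0 <- 0.5; T <- 20
  tt <- (0:(T * fs - 1)) / fs
  for (A in c(1, 5)) {
    x <- cbind(A * sin(2 * pi * f0 * tt), 0, 0)
    w <- 2 * pi * f0
    expected <- -log(T * (w^2 * T / 2) / (1 - 2 / pi)^2)
    expect_equal(ldlj(x, fs), expected, tolerance = 0.005)
  }
})

test_that("sub-movement bursts strictly reduce LDLJ smoothness", {
  tpl <- exerciseTemplate("half_squat", cycleDuration = 3.5)
  vals <- vapply(c(0, 0.5, 1.5), function(amp) {
    mean(vapply(1:8, function(seed) {
      out <- generateRecording(tpl,
        perturbationConfig(durationJitter = 0.03, amplitudeJitter = 0.03,
                           submovementRate = 2, submovementAmp = amp,
                           noiseAccelSd = 0.03, noiseGyroSd = 0.005,
                           seed = seed))
      seg <- segmentRecording(out$recording)
      ms <- computeMetricSet(out$recording, seg)
      ms@ldlj
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("LDLJ is invariant to time rescaling of the same path", {
  fs <- 246
  mk <- function(T) {
    tau <- (0:(T * fs - 1)) / (T * fs - 1)
    cbind(sin(pi * tau)^2, 0.3 * sin(2 * pi * tau), 0)
  }
  v1 <- ldlj(mk(5), fs)
  v2 <- ldlj(mk(10), fs)
  expect_equal(v1, v2, tolerance = 0.02)
})

test_that("LDLJ rejects degenerate input", {
  expect_error(ldlj(cbind(rep(1, 100), 0, 0), 246),
               class = "degenerateInputError")
})

test_that("RAV follows closed forms and positive homogeneity", {
  fs <- 100; T <- 2
  tt <- (0:(8 * T * fs - 1)) / fs
  # constant angular velocity: zero range
  expect_identical(rav(cbind(0.5, 0, 0)[rep(1, 200), ],
                       c(0, 1, 2), (0:199) / 100), 0)
  # |w| = 0.2 + 0.2 sin(2 pi t / T): per-cycle range 0.4
  g <- cbind(0.2 + 0.2 * sin(2 * pi * tt / T), 0, 0)
  bounds <- seq(0, 8 * T, by = T)
  expect_equal(rav(g, bounds, tt), 0.4, tolerance = 0.02 * 0.4)
  expect_equal(rav(2 * g, bounds, tt), 2 * rav(g, bounds, tt),
               tolerance = 1e-12)
})

test_that("kinetic value follows its closed forms", {
  fs <- 100; T <- 4
  n <- T * fs + 1
  # zero dynamic acceleration
  expect_identical(kineticValue(matrix(0, n, 3), fs, "none"), 0)
  expect_equal(kineticValue(cbind(0, 0, rep(9.80665, n)), fs), 0,
               tolerance = 1e-18)
  # constant resultant c integrated over T: (cT)^2 / 2
  cc <- 1.7
  expect_equal(kineticValue(cbind(0, 0, rep(cc, n)), fs, "none"),
               (cc * T)^2 / 2, tolerance = 1e-9)
  # alternating deviation +/- c around a gravity baseline, default mode
  dev <- cc * rep(c(1, -1), length.out = n)
  expect_equal(kineticValue(cbind(0, 0, 9.80665 + dev), fs),
               (cc * T)^2 / 2, tolerance = 1e-6)
})

test_that("the kinetic value separates vigorous from slow exercises", {
  # mountain-climber template versus half squat at matched duration
  kin <- vapply(c("mountain_climber", "half_squat"), function(ex) {
    out <- generateRecording(
      exerciseTemplate(ex, cycleDuration = 2.2, nReps = 7),
      defaultPerturbation(ex, seed = 4))
    ms <- computeMetricSet(out$recording)
    ms@kineticValue
  }, numeric(1))
  expect_gt(kin["mountain_climber"], 10 * kin["half_squat"])
})

test_that("regularity reaches the biased-estimator ceiling on periodic input", {
  P <- 200L; nReps <- 5L
  x <- periodicSignal(P, nReps)
  fs <- 100
  tt <- (seq_along(x) - 1) / fs
  bounds <- seq(0, length(x) / fs, by = P / fs)
  ad1 <- regularity(x, fs, bounds, tt, nReps = 5L, period = P / fs)
  expect_equal(ad1, (length(x) - P) / length(x), tolerance = 1e-6)
  expect_equal(ad1, 0.8, tolerance = 1e-6)
})

test_that("zero-lag autocorrelation is always 1 and white noise is irregular", {
  set.seed(31)
  for (i in 1:5) {
    x <- rnorm(5000)
    expect_identical(autocorrBiased(x)[1], 1)
    ad1 <- regularity(x, fs = 100, cycleBounds = seq(0, 50, by = 10),
                      time = (0:4999) / 100, nReps = 5L, period = 10)
    expect_lt(abs(ad1), 0.1)
  }
})

test_that("regularity falls back to available repetitions with a warning", {
  x <- periodicSignal(100, 3)
  expect_warning(
    ad1 <- regularity(x, 100, seq(0, 3, by = 1), (0:299) / 100,
                      nReps = 5L, period = 1),
    class = "fewRepetitionsWarning")
  expect_gt(ad1, 0.5)
})

test_that("the mountain climber is less regular than the slow exercises", {
  regOf <- function(ex) {
    mean(vapply(1:6, function(seed) {
      out <- generateRecording(
        exerciseTemplate(ex, cycleDuration = labPaces()[[ex]]),
        defaultPerturbation(ex, seed = seed))
      ms <- computeMetricSet(out$recording)
      ms@regularityAd1
    }, numeric(1)))
  }
  rMc <- regOf("mountain_climber")
  for (ex in setdiff(exerciseNames(), "mountain_climber"))
    expect_lt(rMc, regOf(ex))
})

test_that("metric sets are reproducible bit for bit", {
  out <- generateRecording(exerciseTemplate("split_squat"),
                           defaultPerturbation("split_squat", seed = 13))
  m1 <- computeMetricSet(out$recording)
  m2 <- computeMetricSet(out$recording)
  expect_identical(as.data.frame(m1), as.data.frame(m2))
})

test_that("the half-squat template at its typical lab pace closes the loop", {
  out <- generateRecording(exerciseTemplate("half_squat", cycleDuration = 3.5),
                           defaultPerturbation("half_squat", seed = 21))
  ms <- computeMetricSet(out$recording)
  expect_equal(ms@cycleDuration, 3.5, tolerance = 0.05 * 3.5)
  expect_gt(ms@miMean, 0.95)
  expect_lt(ms@miMean, 1.05)
})
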