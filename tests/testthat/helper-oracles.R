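# Independent oracles and small signal builders shared across tests.
# These deliberately avoid the package's fast paths: the autocorrelation
# oracle is the direct O(N^2) summation, the DTW oracle enumerates every
# monotone warping path.

# direct biased autocorrelation, A(m) = (1/N) sum_{i=1}^{N-m} a_i a_{i+m}
autocorrDirect <- function(x, normalize = TRUE) {
  n <- length(x)
  a <- vapply(0:(n - 1L), function(m) {
    sum(x[seq_len(n - m)] * x[seq_len(n - m) + m]) / n
  }, numeric(1))
  if (normalize) a <- a / a[1]
  a
}

# exhaustive DTW: minimum accumulated |diff| cost over all monotone paths
dtwBruteCost <- function(a, b) {
  n <- length(a); m <- length(b)
  rec <- function(i, j) {
    c0 <- abs(a[i] - b[j])
    if (i == 1 && j == 1) return(c0)
    best <- Inf
    if (i > 1 && j > 1) best <- min(best, rec(i - 1, j - 1))
    if (i > 1) best <- min(best, rec(i - 1, j))
    if (j > 1) best <- min(best, rec(i, j - 1))
    c0 + best
  }
  rec(n, m)
}

# rest recording: gravity on +z only
restRecording <- function(n = 500, fs = 246) {
  IMURecording(accel = cbind(0, 0, rep(standardGravity(), n)),
               gyro = matrix(0, n, 3), fs = fs)
}

# random 3-D rotation matrix (orthonormal, det +1)
randomRotation <- function(seed = 1) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# exactly periodic zero-mean cycle repeated nReps times (integer period)
periodicSignal <- function(P = 200, nReps = 5) {
  tau <- seq_len(P) / P
  cycle <- sin(2 * pi * tau) + 0.3 * sin(4 * pi * tau)
  rep(cycle, nReps)
}

# amplitude of a sinusoidal component in the central half of a signal
midAmplitude <- function(x) {
  n <- length(x)
  mid <- x[floor(n / 4):ceiling(3 * n / 4)]
  sqrt(2) * sd(mid)
}
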