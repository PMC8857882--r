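# Shared numerical helpers and condition constructors.

.imuStop <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "imuRehabError")))
}

.imuWarn <- function(class, fmt, ...) {
  warning(warningCondition(sprintf(fmt, ...),
                           class = c(class, "imuRehabWarning")))
}

#' Centred moving standard deviation
#'
#' Rolling SD over a centred window, computed from cumulative sums; the
#' window is truncated at the edges. Used by the activity detector with a
#' 1 s window.
#'
#' @param x numeric vector.
#' @param width window width in samples (>= 2).
#' @return Numeric vector the length of `x`.
#' @keywords internal
movingSD <- function(x, width) {
  n <- length(x)
  width <- max(2L, as.integer(width))
  half <- width %/% 2L
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  m <- hi - lo + 1L
  s <- cs[hi + 1L] - cs[lo]
  s2 <- cs2[hi + 1L] - cs2[lo]
  v <- (s2 - s^2 / m) / (m - 1L)
  sqrt(pmax(v, 0))
}

#' Biased sample autocorrelation
#'
#' The biased (1/N-normalised) autocorrelation
#' \eqn{A(m) = (1/N) \sum_{i=1}^{N-m} a_i a_{i+m}} for lags `0..N-1`,
#' optionally normalised by `A(0)` so the zero-lag coefficient is 1.
#' Computed via FFT (O(N log N)); the direct O(N^2) summation is retained
#' in the test suite as an independent oracle.
#'
#' @param x numeric vector (use mean-removed input for movement
#'   regularity).
#' @param normalize divide by the zero-lag value?
#' @return Numeric vector of length `length(x)` (lags 0..N-1).
#' @export
autocorrBiased <- function(x, normalize = TRUE) {
  n <- length(x)
  if (n < 2L)
    .imuStop("degenerateInputError", "autocorrelation needs >= 2 samples")
  nfft <- stats::nextn(2L * n, 2L)
  f <- stats::fft(c(x, numeric(nfft - n)))
  a <- Re(stats::fft(f * Conj(f), inverse = TRUE))[seq_len(n)] / (nfft * n)
  if (normalize) {
    if (a[1] <= 0)
      .imuStop("degenerateInputError",
               "zero-variance signal: autocorrelation undefined")
    a <- a / a[1]
  }
  a
}

#' Local maxima with prominence and minimum separation
#'
#' Simple deterministic peak detector: strict local maxima (first sample of
#' a plateau), filtered by topographic prominence, then thinned greedily by
#' descending height under a minimum-separation constraint.
#'
#' @param x numeric vector.
#' @param minProminence minimum peak prominence (same units as `x`).
#' @param minSeparation minimum distance between retained peaks, samples.
#' @return Integer vector of peak indices, ascending.
#' @keywords internal
findPeaks <- function(x, minProminence = 0, minSeparation = 1L) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  sgn <- sign(diff(x))
  if (all(sgn == 0)) return(integer(0))
  if (any(sgn == 0)) {
    # carry the previous non-zero slope through plateaus so a flat top
    # counts once, at its last sample
    for (i in seq_along(sgn))
      if (sgn[i] == 0 && i > 1L) sgn[i] <- sgn[i - 1L]
  }
  cand <- which(diff(sgn) < 0 & sgn[-length(sgn)] > 0) + 1L
  if (length(cand) == 0L) return(integer(0))
  # thin by separation first (greedy, tallest wins), then vet the few
  # survivors by prominence; keeps the walk below O(n^2) on noisy input
  if (minSeparation > 1L && length(cand) > 1L) {
    ord <- cand[order(x[cand], cand, decreasing = c(TRUE, FALSE),
                      method = "radix")]
    kept <- integer(0)
    for (p in ord) {
      if (all(abs(p - kept) >= minSeparation)) kept <- c(kept, p)
    }
    cand <- sort(kept)
  }
  if (minProminence > 0 && length(cand) > 0L) {
    prom <- vapply(cand, function(p) {
      lmin <- x[p]; i <- p
      while (i > 1L && x[i - 1L] <= x[p]) {
        i <- i - 1L; lmin <- min(lmin, x[i])
      }
      rmin <- x[p]; i <- p
      while (i < n && x[i + 1L] <= x[p]) {
        i <- i + 1L; rmin <- min(rmin, x[i])
      }
      x[p] - max(lmin, rmin)
    }, numeric(1))
    cand <- cand[prom >= minProminence]
  }
  cand
}

#' Minimum-jerk unit displacement profile
#'
#' The classic fifth-order polynomial `10 t^3 - 15 t^4 + 6 t^5` on [0, 1]
#' and its first derivative; outside [0, 1] the profile saturates at 0/1.
#'
#' @param tau normalised time.
#' @return For `minJerkPos`, displacement in [0, 1]; for `minJerkVel`, the
#'   derivative with respect to `tau`.
#' @keywords internal
minJerkPos <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  tau^3 * (10 - 15 * tau + 6 * tau^2)
}

#' @rdname minJerkPos
#' @keywords internal
minJerkVel <- function(tau) {
  inside <- tau >= 0 & tau <= 1
  tau <- pmin(pmax(tau, 0), 1)
  v <- 30 * tau^2 - 60 * tau^3 + 30 * tau^4
  v[!inside] <- 0
  v
}

#' Trapezoidal integral on a uniform grid
#' @keywords internal
trapz <- function(y, dt) {
  n <- length(y)
  if (n < 2L) return(0)
  dt * (sum(y) - 0.5 * (y[1] + y[n]))
}

## slice indices of samples with time in [t1, t2]
.windowIndex <- function(time, t1, t2) {
  which(time >= t1 - 1e-12 & time <= t2 + 1e-12)
}
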