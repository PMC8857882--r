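#' @include utils.R
NULL

## forward-backward application of an ARMA filter with odd-reflection
## padding at both ends (pad length ~1 s, capped at N-1) so start-up
## transients decay outside the signal
.filtfiltPad <- function(filt, x, fs) {
  n <- length(x)
  pad <- min(n - 1L, max(12L, round(fs)))
  left <- 2 * x[1] - x[(pad + 1L):2L]
  right <- 2 * x[n] - x[(n - 1L):(n - pad)]
  xp <- c(left, x, right)
  y <- signal::filter(filt, xp)
  y <- rev(signal::filter(filt, rev(y)))
  y[(pad + 1L):(pad + n)]
}

#' Zero-phase low-pass Butterworth filter
#'
#' Second-order (by default) Butterworth low-pass applied forward and
#' backward so the net phase shift is zero and the effective magnitude
#' response is the square of the single-pass response. Used to suppress
#' measurement noise before jerk-based smoothness computation (cut-off
#' 6 Hz). DC gain is 1: a constant signal passes unchanged.
#'
#' @param x numeric vector or N x k matrix (filtered per column).
#' @param fs sampling rate, Hz; must exceed `2 * fc`.
#' @param fc cut-off frequency, Hz.
#' @param order filter order of the single pass.
#' @return Filtered signal, same shape as `x`.
#' @export
lowpassFilter <- function(x, fs, fc = 6, order = 2L) {
  if (fs <= 2 * fc)
    .imuStop("configError",
             "sampling rate %g Hz too low for a %g Hz cut-off", fs, fc)
  n <- if (is.matrix(x)) nrow(x) else length(x)
  if (n <= 6L * order)
    .imuStop("degenerateInputError",
             "signal too short to filter (%d samples)", n)
  bf <- signal::butter(order, fc / (fs / 2), type = "low")
  if (is.matrix(x)) {
    apply(x, 2L, function(col) .filtfiltPad(bf, col, fs))
  } else {
    .filtfiltPad(bf, x, fs)
  }
}

#' Zero-phase band-pass Butterworth filter
#'
#' Forward-backward band-pass used when ranking axes by movement-band
#' (0.1--6 Hz) variance.
#'
#' @param x numeric vector.
#' @param fs sampling rate, Hz.
#' @param band `c(low, high)` cut-offs, Hz.
#' @param order single-pass filter order.
#' @return Filtered vector.
#' @export
bandpassFilter <- function(x, fs, band = c(0.1, 6), order = 2L) {
  if (fs <= 2 * band[2])
    .imuStop("configError",
             "sampling rate %g Hz too low for a %g Hz band edge",
             fs, band[2])
  if (length(x) <= 6L * order)
    .imuStop("degenerateInputError", "signal too short to filter")
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  .filtfiltPad(bf, x, fs)
}
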