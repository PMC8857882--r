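#' @include utils.R
NULL

#' Dynamic time warping distance between two repetitions
#'
#' Aligns two 1-D acceleration sequences of possibly different lengths by
#' classic dynamic time warping: local cost is the absolute sample
#' difference, steps are the symmetric `{(1,0), (0,1), (1,1)}` pattern,
#' and no window constraint is applied. The normalised distance divides
#' the accumulated cost at the end point by the length (number of cells)
#' of the optimal warping path, making sequences of dissimilar length
#' comparable.
#'
#' @param a,b numeric vectors (length >= 2), m/s^2.
#' @return List with `cost` (accumulated, m/s^2 x samples), `pathLength`
#'   and `normalized` (cost / pathLength, m/s^2).
#' @examples
#' dtwDistance(c(0, 2, 0), c(0, 2, 2, 0))$normalized  # 0: warps onto itself
#' @export
dtwDistance <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    .imuStop("degenerateInputError",
             "DTW requires at least 2 samples per repetition")
  r <- dtw_pair_cpp(as.numeric(a), as.numeric(b))
  list(cost = r$cost, pathLength = r$pathLength,
       normalized = r$cost / r$pathLength)
}
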