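#' Sample from a triangular distribution
#'
#' Draws from the triangular distribution with lower limit `min`, mode `mode`
#' and upper limit `max` by inversion of the closed-form CDF. The degenerate
#' case `min == mode == max` returns the constant, which is how fixed
#' parameters (for example the phase-4 cost) are represented throughout the
#' package.
#'
#' @param n Number of draws.
#' @param min,mode,max Distribution limits and mode; each may be a scalar or a
#'   vector of length `n`, and must satisfy `min <= mode <= max`.
#' @return A numeric vector of length `n`.
#' @examples
#' set.seed(1)
#' mean(rtriangular(1e4, 0, 1, 2)) # close to (0 + 1 + 2) / 3
#' rtriangular(3, 5, 5, 5)         # degenerate: all 5
#' @export
rtriangular <- function(n, min, mode, max) {
  if (any(is.na(min) | is.na(mode) | is.na(max))) {
    stop("triangular parameters must not be NA", call. = FALSE)
  }
  if (any(min > mode | mode > max)) {
    stop("triangular parameters must satisfy min <= mode <= max", call. = FALSE)
  }
  min <- rep_len(min, n); mode <- rep_len(mode, n); max <- rep_len(max, n)
  out <- numeric(n)
  fixed <- min == max
  out[fixed] <- min[fixed]
  if (any(!fixed)) {
    i <- which(!fixed)
    u <- runif(length(i))
    a <- min[i]; m <- mode[i]; b <- max[i]
    fc <- (m - a) / (b - a)
    lo <- u < fc
    out[i] <- ifelse(lo,
      a + sqrt(u * (b - a) * (m - a)),
      b - sqrt((1 - u) * (b - a) * (b - m)))
  }
  out
}

# E[X] for a triangular(min, mode, max); used in tests and documentation.
triangular_mean <- function(min, mode, max) (min + mode + max) / 3
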