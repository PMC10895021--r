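# Local-maximum detection with topographic prominence.

#' Find peaks by topographic prominence
#'
#' Locates local maxima of a sequence and measures each peak's prominence:
#' walk outward from the peak on each side until a higher point (or the
#' signal edge) is reached, take the minimum value encountered on each walk,
#' and subtract the higher of the two minima from the peak height. Plateaus
#' count as a single peak at their centre. No minimum inter-peak distance is
#' imposed.
#'
#' @param x Numeric vector.
#' @param min_prominence Keep only peaks with prominence strictly greater
#'   than this (default 0: all local maxima).
#' @return A data.frame with columns `index`, `height`, `prominence`,
#'   ordered by index.
#' @export
find_peaks <- function(x, min_prominence = 0) {
  n <- length(x)
  if (n < 3L) {
    return(data.frame(index = integer(), height = numeric(),
                      prominence = numeric()))
  }
  # candidate maxima, collapsing plateaus to their centre
  d <- diff(x)
  rises <- which(d > 0)
  falls <- which(d < 0)
  peaks <- integer(0)
  for (r in rises) {
    nxt <- falls[falls > r]
    if (!length(nxt)) break
    f <- nxt[1L]
    if (!any(rises > r & rises < f)) {
      peaks <- c(peaks, as.integer(floor((r + 1L + f) / 2)))
    }
  }
  if (!length(peaks)) {
    return(data.frame(index = integer(), height = numeric(),
                      prominence = numeric()))
  }
  prom <- vapply(peaks, function(p) {
    h <- x[p]
    left <- if (p > 1L) x[1:(p - 1L)] else numeric(0)
    higher_l <- which(left > h)
    lo_l <- if (length(higher_l)) {
      min(left[(max(higher_l) + 1L):(p - 1L)])
    } else min(c(left, h))
    right <- if (p < n) x[(p + 1L):n] else numeric(0)
    higher_r <- which(right > h)
    lo_r <- if (length(higher_r)) {
      min(right[1:(min(higher_r) - 1L)])
    } else min(c(right, h))
    h - max(lo_l, lo_r)
  }, numeric(1))
  keep <- prom > min_prominence
  data.frame(index = peaks[keep], height = x[peaks[keep]],
             prominence = prom[keep])
}
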