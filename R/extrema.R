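#' Locate local extrema of a series with a prominence guard
#'
#' Extrema are strict sign changes of the first difference (plateaus resolved
#' to their first sample); by construction they alternate between maxima and
#' minima. A small prominence guard — by default 2% of the series'
#' interquartile range — then repeatedly removes the adjacent extremum pair
#' with the smallest swing until every consecutive swing is at least the
#' guard, so sensor noise does not inflate extrema counts while alternation is
#' preserved.
#'
#' @param x numeric series.
#' @param prominence_frac guard as a fraction of `IQR(x)`; 0 disables it.
#' @return integer vector of extremum sample indices (possibly empty).
#' @export
find_extrema <- function(x, prominence_frac = 0.02) {
  n <- length(x)
  if (n < 3) return(integer(0))
  d <- diff(x)
  nz <- which(d != 0)
  if (length(nz) < 2) return(integer(0))
  s <- sign(d[nz])
  turn <- which(s[-1] != s[-length(s)])
  cand <- nz[turn] + 1L   # first sample of a plateau, or the peak itself
  if (length(cand) < 2) return(cand)
  guard <- prominence_frac * stats::IQR(x)
  if (guard <= 0) return(cand)
  repeat {
    if (length(cand) < 2) break
    swings <- abs(diff(x[cand]))
    j <- which.min(swings)
    if (swings[j] >= guard) break
    cand <- cand[-c(j, j + 1L)]
  }
  cand
}
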