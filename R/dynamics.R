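#' Temporal variability indices of a measure series
#'
#' Summarises an ordered series of measures v_1..v_n (scalars, or 3D maps
#' applied elementwise) by:
#' \describe{
#'   \item{mean, sd}{sample mean and standard deviation;}
#'   \item{cov}{coefficient of variation, sd / mean;}
#'   \item{meanPointChange}{mean over t >= 2 of |1 - v_t / v_{t-1}|;}
#'   \item{meanRelativeRatio}{mean over t >= 2 of v_t / v_{t-1}.}
#' }
#' The ratio-based indices need strictly positive predecessors; where a
#' v_{t-1} is 0 those two indices are returned as NA (flagged) while the
#' others are still computed.
#'
#' @param series numeric vector of length >= 2, or a list of equal-shape
#'   3D arrays (e.g. sliding-window measure maps).
#' @return for a vector: named list of the five scalars plus
#'   \code{ratioFlagged}; for a list of maps: the same names, each a 3D
#'   array computed voxelwise.
#' @export
dynamicSeriesStats <- function(series) {
  if (is.list(series)) {
    if (length(series) < 2L) stop("series must have length >= 2")
    d <- dim(series[[1L]])
    M <- vapply(series, as.numeric, numeric(prod(d)))  # voxels x n
    res <- apply(M, 1L, function(v) {
      if (anyNA(v)) return(rep(NA_real_, 5L))
      s <- dynamicSeriesStats(v)
      c(s$mean, s$sd, s$cov,
        if (s$ratioFlagged) c(NA_real_, NA_real_) else
          c(s$meanPointChange, s$meanRelativeRatio))
    })
    pack <- function(r) array(res[r, ], dim = d)
    return(list(mean = pack(1L), sd = pack(2L), cov = pack(3L),
                meanPointChange = pack(4L), meanRelativeRatio = pack(5L)))
  }
  v <- as.numeric(series)
  if (length(v) < 2L) stop("series must have length >= 2")
  m <- mean(v)
  s <- stats::sd(v)
  prev <- v[-length(v)]; cur <- v[-1L]
  flagged <- any(prev == 0)
  list(mean = m, sd = s, cov = s / m,
       meanPointChange = if (flagged) NA_real_ else mean(abs(1 - cur / prev)),
       meanRelativeRatio = if (flagged) NA_real_ else mean(cur / prev),
       ratioFlagged = flagged)
}
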