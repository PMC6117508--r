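#' Spatio-temporal consistency of local BOLD activity
#'
#' A voxelwise measure in [0, 1] combining, over the 27-voxel cube
#' neighbourhood intersected with the mask (at least 9 members required):
#' \describe{
#'   \item{temporal consistency t_i}{mean pairwise Pearson correlation
#'     among the neighbourhood time series — homogeneity of local
#'     activity;}
#'   \item{spatial consistency s_i}{mean Pearson correlation between the
#'     neighbourhood's spatial value patterns at consecutive time points —
#'     stability of the local activity state.}
#' }
#' The default combiner is the rectified product
#' max(0, t_i) * max(0, s_i), which keeps the result in [0, 1]; any
#' function of (t, s) can be supplied instead. Neighbourhoods that are too
#' small or contain a zero-variance pattern get value 0 and are flagged.
#' The map is also divided by its in-mask mean (flagged voxels excluded
#' from the denominator).
#'
#' @param vol a \linkS4class{Volume4D} with at least 10 volumes.
#' @param mask a \linkS4class{BrainMask}.
#' @param combiner function(t, s) -> value; default rectified product.
#' @param minNeighbors minimum in-mask neighbourhood size (default 9).
#' @return a \linkS4class{FOCAMap}.
#' @export
computeFOCA <- function(vol, mask, combiner = NULL, minNeighbors = 9L) {
  requireTimeSeries(vol, minT = 10L)
  checkSameGrid(vol, mask)
  combinerTag <- "rectified_product"
  if (is.null(combiner)) {
    combiner <- function(t, s) max(0, t) * max(0, s)
  } else combinerTag <- "custom"

  Y <- maskSeries(vol, mask)                 # T x V
  T_ <- nrow(Y)
  adj <- maskAdjacency(mask, 26L)
  Z <- standardizeColumns(Y)                 # unit-norm, zero-mean columns
  zeroVar <- attr(Z, "zeroVariance")
  d3 <- dim(mask@flags)
  idx <- which(mask@flags)
  V <- length(idx)

  raw <- numeric(V); tcon <- rep(NA_real_, V); scon <- rep(NA_real_, V)
  flagged <- logical(V)
  for (i in seq_len(V)) {
    nb <- c(i, adj[[i]])
    if (length(nb) < minNeighbors || any(zeroVar[nb])) {
      flagged[i] <- TRUE
      next
    }
    Zi <- Z[, nb, drop = FALSE]
    n <- length(nb)
    ## mean pairwise temporal correlation: (sum(C) - n) / (n (n - 1))
    Csum <- sum(crossprod(Zi))
    ti <- (Csum - n) / (n * (n - 1))
    ## spatial pattern at each t: rows of the neighbourhood sub-matrix;
    ## correlate consecutive rows
    P <- Y[, nb, drop = FALSE]
    Pc <- P - rowMeans(P)
    ssq <- sqrt(rowSums(Pc^2))
    if (any(ssq < .Machine$double.eps^0.5)) {
      flagged[i] <- TRUE
      next
    }
    Pn <- Pc / ssq
    si <- mean(rowSums(Pn[-T_, , drop = FALSE] * Pn[-1L, , drop = FALSE]))
    tcon[i] <- ti; scon[i] <- si
    raw[i] <- combiner(ti, si)
  }
  ok <- !flagged
  den <- mean(raw[ok])
  pack <- function(v) { m <- array(NA_real_, d3); m[idx] <- v; m }
  new("FOCAMap", raw = pack(raw),
      normalized = pack(if (den != 0) raw / den else rep(NaN, V)),
      temporal = pack(tcon), spatial = pack(scon),
      flagged = { m <- array(FALSE, d3); m[idx] <- flagged; m },
      combinerTag = combinerTag)
}
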