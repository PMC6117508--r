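#' Functional connectivity density mapping
#'
#' For each correlation threshold theta, per in-mask voxel i:
#' \describe{
#'   \item{gFCD}{number of other in-mask voxels j with Pearson
#'     r(i, j) > theta (strict), self excluded;}
#'   \item{lFCD}{size minus one of the cluster grown from i by repeatedly
#'     adding voxels that are spatially adjacent (6/18/26 connectivity) to
#'     a current member and correlate with the seed above theta;}
#'   \item{lrFCD}{gFCD - lFCD, the long-range component.}
#' }
#' Each map is also divided by its in-mask mean (normalised variants) to
#' reduce between-subject scale differences. Zero-variance in-mask voxels
#' get measure 0, are flagged with a warning, and are excluded from the
#' normalisation denominator.
#'
#' @param vol a \linkS4class{Volume4D}.
#' @param mask a \linkS4class{BrainMask}.
#' @param thresholds strictly increasing correlation thresholds in (0, 1);
#'   default the conventional 0.2..0.8 vector.
#' @param connectivity spatial adjacency: 6, 18 or 26 (default 26, the
#'   full 27-voxel cube).
#' @return an \linkS4class{FCDMaps} object.
#' @export
computeFCD <- function(vol, mask, thresholds = seq(0.2, 0.8, by = 0.1),
                       connectivity = 26) {
  requireTimeSeries(vol, minT = 3L)
  checkSameGrid(vol, mask)
  if (any(thresholds <= 0) || any(thresholds >= 1) ||
      is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly increasing values in (0, 1)")
  connectivity <- as.integer(connectivity)

  Z <- standardizeColumns(maskSeries(vol, mask))
  zeroVar <- attr(Z, "zeroVariance")
  if (any(zeroVar))
    warning(sum(zeroVar), " in-mask voxel(s) have zero temporal variance; ",
            "their FCD is set to 0")
  V <- ncol(Z)
  adj <- maskAdjacency(mask, connectivity)
  d3 <- dim(mask@flags)
  blank <- array(NA_real_, dim = d3)
  idx <- which(mask@flags)

  R <- crossprod(Z)                 # V x V correlation matrix
  diag(R) <- 0
  R[zeroVar, ] <- 0; R[, zeroVar] <- 0

  maps <- vector("list", length(thresholds))
  for (ti in seq_along(thresholds)) {
    th <- thresholds[ti]
    A <- R > th
    g <- colSums(A)
    l <- integer(V)
    for (i in seq_len(V)) {
      if (zeroVar[i]) next
      ok <- A[, i]                  # seed-anchored suprathreshold voxels
      inClust <- logical(V)
      inClust[i] <- TRUE
      frontier <- i
      while (length(frontier)) {
        cand <- unique(unlist(adj[frontier], use.names = FALSE))
        cand <- cand[!inClust[cand] & ok[cand]]
        inClust[cand] <- TRUE
        frontier <- cand
      }
      l[i] <- sum(inClust) - 1L
    }
    g[zeroVar] <- 0L
    lr <- g - l
    pack <- function(v) { m <- blank; m[idx] <- v; m }
    norm_ <- function(v) {
      den <- mean(v[!zeroVar])
      if (den == 0) numeric(length(v)) else v / den
    }
    maps[[ti]] <- list(lfcd = pack(l), gfcd = pack(g), lrfcd = pack(lr),
                       nlfcd = pack(norm_(l)), ngfcd = pack(norm_(g)),
                       nlrfcd = pack(norm_(lr)))
  }
  new("FCDMaps", thresholds = as.numeric(thresholds), maps = maps,
      connectivity = connectivity, mask = mask)
}

#' Sliding-window (dynamic) FCD
#'
#' Static FCD recomputed on successive windows of the time series.
#' Windows start at volumes 0, step, 2 step, ...; the number of windows is
#' floor((T - window) / step) + 1.
#'
#' @inheritParams computeFCD
#' @param window window length in TRs (>= 10).
#' @param step step between window starts in TRs (default 1).
#' @return list with \code{starts} (0-based window start volumes) and
#'   \code{maps} (list of \linkS4class{FCDMaps}, one per window).
#' @export
computeDynamicFCD <- function(vol, mask,
                              thresholds = seq(0.2, 0.8, by = 0.1),
                              connectivity = 26, window = 40, step = 1) {
  T_ <- dim(vol@data)[4L]
  window <- as.integer(window); step <- as.integer(step)
  if (window > T_)
    stop("window (", window, " TRs) exceeds the run length (", T_, ")")
  if (window < 10L) stop("window must be at least 10 TRs")
  if (step < 1L) stop("step must be at least 1 TR")
  starts <- seq(0L, T_ - window, by = step)
  maps <- lapply(starts, function(s) {
    sub <- vol
    sub@data <- vol@data[, , , (s + 1L):(s + window), drop = FALSE]
    suppressWarnings(computeFCD(sub, mask, thresholds, connectivity))
  })
  list(starts = starts, maps = maps)
}
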