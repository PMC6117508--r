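#' Lock a feature series to the TR grid
#'
#' Onset features become per-TR event counts (impulse trains); TR-locked
#' power/amplitude series pass through with NA gaps linearly
#' interpolated; other series are binned by TR mean.
#'
#' @param feature a \linkS4class{FeatureSeries}.
#' @param tr repetition time in seconds.
#' @param nVols number of volumes.
#' @return numeric vector of length \code{nVols}.
#' @export
featureToTRSeries <- function(feature, tr, nVols) {
  if (feature@kind == "onsets") {
    e <- numeric(nVols)
    if (length(feature@times)) {
      b <- floor(feature@times / tr + 1e-9) + 1L
      if (any(b > nVols)) stop("onsets beyond the run")
      for (bi in b) e[bi] <- e[bi] + 1
    }
    return(e)
  }
  if (feature@trLocked && length(feature@values) == nVols) {
    v <- feature@values
  } else {
    b <- pmin(floor(feature@times / tr + 1e-9) + 1L, nVols)
    v <- rep(NA_real_, nVols)
    agg <- tapply(feature@values, b, mean, na.rm = TRUE)
    v[as.integer(names(agg))] <- agg
  }
  if (anyNA(v)) {
    ok <- which(!is.na(v))
    if (length(ok) < 2L) stop("too few non-missing feature values")
    v <- stats::approx(ok, v[ok], xout = seq_len(nVols), rule = 2L)$y
  }
  v
}

#' Lagged EEG feature matrix
#'
#' T x (L + 1) matrix whose column l (l = 0..L) is the TR-locked feature
#' series delayed by l volumes, zero-padded at the start. A causal-lag
#' basis: any finite impulse response over the lag grid is a linear
#' combination of the columns, which is what lets the local CCA estimate
#' a data-driven HRF.
#'
#' @param feature a \linkS4class{FeatureSeries} (locked to the grid via
#'   \code{\link{featureToTRSeries}}) or a plain numeric TR series.
#' @param tr repetition time in seconds.
#' @param nVols number of volumes.
#' @param maxLag maximum lag in TRs (default 6, i.e. 12 s at TR 2 s).
#' @return T x (maxLag + 1) matrix with columns lag0..lagL.
#' @export
buildLaggedMatrix <- function(feature, tr, nVols, maxLag = 6L) {
  maxLag <- as.integer(maxLag)
  if (maxLag >= nVols)
    stop("maxLag (", maxLag, ") must be smaller than nVols (", nVols, ")")
  e <- if (is(feature, "FeatureSeries"))
    featureToTRSeries(feature, tr, nVols) else as.numeric(feature)
  if (length(e) != nVols) stop("series length != nVols")
  X <- vapply(0:maxLag, function(l)
    c(numeric(l), e[seq_len(nVols - l)]), numeric(nVols))
  colnames(X) <- paste0("lag", 0:maxLag)
  X
}

## Drop linearly dependent columns (QR with pivoting); returns kept
## column indices.
independentColumns <- function(M, side) {
  q <- qr(M)
  r <- q$rank
  if (r < ncol(M)) {
    warning(side, " side is rank deficient; dropping ", ncol(M) - r,
            " dependent column(s)")
    sort(q$pivot[seq_len(r)])
  } else seq_len(ncol(M))
}

#' First canonical correlation
#'
#' Canonical correlation analysis between column-demeaned X (T x p) and
#' Y (T x q), returning the first canonical correlation, the weight
#' vectors (scaled so each variate has unit variance), all canonical
#' correlations, and a p-value for the overall association from Rao's F
#' approximation of Wilks' lambda (lambda = prod(1 - rho_i^2)); the
#' better-known Bartlett chi-square version of the same statistic is
#' measurably conservative at the dimensionalities the local fusion uses
#' (27-voxel neighbourhoods), so the F form is used throughout.
#' Rank-deficient sides are reduced by dropping dependent columns with a
#' warning; dropped columns get weight 0.
#'
#' @param X,Y numeric matrices with T rows; requires T > p + q.
#' @return list with rho, a, b, pValue, allRho, dfChi.
#' @export
ccaFirst <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  T_ <- nrow(X)
  if (nrow(Y) != T_) stop("X and Y must have equal row counts")
  p0 <- ncol(X); q0 <- ncol(Y)
  Xc <- sweep(X, 2L, colMeans(X))
  Yc <- sweep(Y, 2L, colMeans(Y))
  keepX <- independentColumns(Xc, "X")
  keepY <- independentColumns(Yc, "Y")
  Xc <- Xc[, keepX, drop = FALSE]; Yc <- Yc[, keepY, drop = FALSE]
  p <- ncol(Xc); q <- ncol(Yc)
  if (T_ <= p + q)
    stop("need T > p + q for CCA (T = ", T_, ", p + q = ", p + q,
         "); reduce the lag count or neighbourhood")
  sx <- svd(Xc); sy <- svd(Yc)
  sv <- svd(crossprod(sx$u, sy$u))
  rho <- pmin(pmax(sv$d, 0), 1)
  ## Xc (V D^-1 u1) = U u1, unit norm; scale so the variates have unit
  ## variance.
  aR <- sx$v %*% (sv$u[, 1L] / sx$d) * sqrt(T_ - 1)
  bR <- sy$v %*% (sv$v[, 1L] / sy$d) * sqrt(T_ - 1)
  a <- numeric(p0); a[keepX] <- as.numeric(aR)
  b <- numeric(q0); b[keepY] <- as.numeric(bR)
  pval <- wilksRaoP(rho, T_, p, q)
  list(rho = rho[1L], a = a, b = b, pValue = pval, allRho = rho,
       df = p * q)
}

## Rao's F approximation for Wilks' lambda of the full canonical system.
wilksRaoP <- function(rho, T_, p, q) {
  lam <- prod(pmax(1 - rho^2, 1e-300))
  m <- T_ - 1 - (p + q + 1) / 2
  s <- if (p^2 + q^2 - 5 > 0) sqrt((p^2 * q^2 - 4) / (p^2 + q^2 - 5)) else 1
  df1 <- p * q
  df2 <- m * s - p * q / 2 + 1
  if (df2 <= 0) return(NA_real_)
  Ls <- lam^(1 / s)
  Fv <- (1 - Ls) / Ls * df2 / df1
  stats::pf(Fv, df1, df2, lower.tail = FALSE)
}

#' Local multimodal serial analysis
#'
#' Per in-mask voxel i: the lagged EEG feature matrix is canonically
#' correlated with the time series of the voxel's 27-voxel neighbourhood
#' (intersected with the mask; at least \code{minNeighbors} members).
#' When the Bartlett test of the canonical correlation is significant at
#' \code{alpha}, the EEG-side canonical variate v_i (sign fixed so the
#' weight sum is non-negative) is taken as the data-driven prediction of
#' local neural activity and the voxel's own series is regressed on
#' [v_i, nuisance, intercept]; the reported statistic is the t of the
#' v_i coefficient. Non-significant voxels get t = 0, flagged. The
#' EEG-side weights over lags are the voxel's estimated HRF.
#'
#' @param vol a \linkS4class{Volume4D} (globally normalised first unless
#'   \code{normalize = FALSE}).
#' @param feature a \linkS4class{FeatureSeries} or numeric TR series.
#' @param mask a \linkS4class{BrainMask}.
#' @param maxLag maximum lag in TRs (default 6).
#' @param alpha significance level of the CCA gate (default 0.05).
#' @param nuisance optional \linkS4class{NuisanceDesign} entering the
#'   final regression.
#' @param minNeighbors minimum neighbourhood size (default 9).
#' @param neighborhood 27 (cube, default) or 1 (the voxel itself — the
#'   degenerate diagnostic mode in which LMSA reduces to a GLM).
#' @param normalize apply \code{\link{globalMeanNormalize}} first.
#' @return an \linkS4class{LMSAResult}.
#' @export
lmsaMap <- function(vol, feature, mask, maxLag = 6L, alpha = 0.05,
                    nuisance = NULL, minNeighbors = 9L, neighborhood = 27,
                    normalize = TRUE) {
  requireTimeSeries(vol)
  checkSameGrid(vol, mask)
  if (normalize) vol <- globalMeanNormalize(vol, mask)
  T_ <- dim(vol@data)[4L]
  X <- buildLaggedMatrix(feature, vol@tr, T_, maxLag)
  Y <- maskSeries(vol, mask)
  adj <- if (neighborhood == 27) maskAdjacency(mask, 26L) else NULL
  if (neighborhood == 1) minNeighbors <- 1L
  Z <- if (is.null(nuisance)) matrix(numeric(0), T_, 0L) else
    nuisance@matrix

  d3 <- dim(mask@flags); idx <- which(mask@flags); V <- length(idx)
  tv <- rep(NA_real_, V); rhov <- rep(NA_real_, V); pv <- rep(NA_real_, V)
  sig <- logical(V)
  W <- matrix(NA_real_, V, maxLag + 1L)
  for (i in seq_len(V)) {
    nb <- if (is.null(adj)) i else c(i, adj[[i]])
    if (length(nb) < minNeighbors) next
    Yl <- Y[, nb, drop = FALSE]
    cc <- tryCatch(suppressWarnings(ccaFirst(X, Yl)),
                   error = function(e) NULL)
    if (is.null(cc)) next
    rhov[i] <- cc$rho; pv[i] <- cc$pValue
    if (is.finite(cc$pValue) && cc$pValue < alpha) {
      a <- cc$a
      if (sum(a) < 0) a <- -a
      v <- sweep(X, 2L, colMeans(X)) %*% a
      des <- cbind(v = v, Z, intercept = 1)
      fit <- stats::lm.fit(des, Y[, i])
      dofRes <- T_ - fit$rank
      s2 <- sum(fit$residuals^2) / dofRes
      XtXinv <- MASS::ginv(crossprod(des))
      tv[i] <- fit$coefficients[1L] / sqrt(s2 * XtXinv[1L, 1L])
      sig[i] <- TRUE
      W[i, ] <- a
    } else tv[i] <- 0
  }
  pack <- function(v) { m <- array(NA_real_, d3); m[idx] <- v; m }
  sigArr <- array(FALSE, d3); sigArr[idx] <- sig
  keep <- which(sig)
  hw <- W[keep, , drop = FALSE]
  rownames(hw) <- as.character(idx[keep])
  new("LMSAResult", tMap = pack(tv), rhoMap = pack(rhov), pMap = pack(pv),
      sigMask = sigArr, hrfWeights = hw, lags = 0:maxLag, tr = vol@tr,
      alpha = alpha)
}

#' Estimated HRF of a significant LMSA voxel
#'
#' The EEG-side canonical weights over the lag grid, peak-normalised for
#' display; empty (with a message attribute) for non-significant voxels.
#'
#' @param result an \linkS4class{LMSAResult}.
#' @param voxel either a linear voxel index or an ijk triple.
#' @return data.frame with columns lag_s and weight (0 rows when the
#'   voxel is not significant; attribute "flag" explains why).
#' @export
estimatedHRF <- function(result, voxel) {
  if (length(voxel) == 3L)
    voxel <- voxel[1L] + (voxel[2L] - 1L) * dim(result@sigMask)[1L] +
      (voxel[3L] - 1L) * prod(dim(result@sigMask)[1:2])
  key <- as.character(voxel)
  if (!key %in% rownames(result@hrfWeights)) {
    out <- data.frame(lag_s = numeric(0), weight = numeric(0))
    attr(out, "flag") <- "voxel not significant (or outside mask)"
    return(out)
  }
  w <- result@hrfWeights[key, ]
  w <- w / max(abs(w))
  data.frame(lag_s = result@lags * result@tr, weight = as.numeric(w))
}
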