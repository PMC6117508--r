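## Shared voxelwise OLS machinery: fit Y (T x V) on X, return betas,
## residual variance and rank.
voxelOLS <- function(X, Y, labels = NULL) {
  T_ <- nrow(X)
  fit <- robustLS(X, Y, labels)
  r <- fit$rank
  if (T_ <= r) stop("model has no residual degrees of freedom (T = ",
                    T_, ", rank = ", r, ")")
  resid <- Y - X %*% fit$coef
  rss <- colSums(resid^2)
  list(beta = fit$coef, rss = rss, sigma2 = rss / (T_ - r), rank = r,
       dofRes = T_ - r)
}

#' Voxelwise general linear model
#'
#' Ordinary least squares per in-mask voxel. A numeric contrast vector c
#' gives the t map t = c'beta / sqrt(sigma2 c'(X'X)^-1 c); a contrast
#' matrix (or the name of a stored contrast, e.g. "F_interest") gives the
#' F map via the extra sum of squares between the full model and the
#' model with the contrasted columns dropped. Out-of-mask voxels are NA.
#' The volume is expected to be globally normalised and to carry its
#' drift regressors in the design.
#'
#' @param vol a \linkS4class{Volume4D}.
#' @param design a \linkS4class{DesignMatrix}.
#' @param mask a \linkS4class{BrainMask}.
#' @param contrast numeric vector (t), numeric matrix (F, rows = columns
#'   to test), or the name of one of the design's stored contrasts.
#'   Default: the t-contrast on the first interest column.
#' @return a \linkS4class{StatMap}.
#' @export
fitGLM <- function(vol, design, mask, contrast = NULL) {
  requireTimeSeries(vol)
  checkSameGrid(vol, mask)
  X <- design@matrix
  if (nrow(X) != dim(vol@data)[4L])
    stop("design rows (", nrow(X), ") != volume time points (",
         dim(vol@data)[4L], ")")
  if (is.null(contrast)) contrast <- design@contrasts[[1L]]
  if (is.character(contrast)) {
    if (!contrast %in% names(design@contrasts))
      stop("unknown contrast '", contrast, "'; stored: ",
           paste(names(design@contrasts), collapse = ", "))
    contrast <- design@contrasts[[contrast]]
  }
  Y <- maskSeries(vol, mask)
  full <- voxelOLS(X, Y, design@labels)
  d3 <- dim(mask@flags); idx <- which(mask@flags)
  pack <- function(v) { m <- array(NA_real_, d3); m[idx] <- v; m }

  if (is.null(dim(contrast))) {                       # t contrast
    cvec <- as.numeric(contrast)
    XtXinv <- MASS::ginv(crossprod(X))
    se2 <- drop(t(cvec) %*% XtXinv %*% cvec)
    tval <- drop(crossprod(cvec, full$beta)) / sqrt(full$sigma2 * se2)
    stat <- pack(tval); kind <- "t"; dof <- c(1, full$dofRes)
  } else {                                            # F via ESS
    Cm <- as.matrix(contrast)
    testCols <- which(colSums(abs(Cm)) > 0)
    Xr <- X[, -testCols, drop = FALSE]
    red <- voxelOLS(Xr, Y, design@labels[-testCols])
    df1 <- full$rank - red$rank
    if (df1 < 1L) stop("contrast does not add testable columns")
    Fval <- ((red$rss - full$rss) / df1) / full$sigma2
    stat <- pack(pmax(Fval, 0)); kind <- "F"; dof <- c(df1, full$dofRes)
  }
  betaArr <- array(NA_real_, c(d3, ncol(X)))
  for (j in seq_len(ncol(X))) {
    m <- array(NA_real_, d3); m[idx] <- full$beta[j, ]
    betaArr[, , , j] <- m
  }
  new("StatMap", stat = stat, kind = kind, dof = dof, beta = betaArr,
      resvar = pack(full$sigma2))
}

#' Multi-HRF maximum-T GLM
#'
#' The epilepsy-oriented variant: the EEG feature (typically discharge
#' onsets) is convolved with a single-gamma HRF once per peak latency
#' (default 3, 5, 7, 9 s), each regressor is fitted in its own GLM with
#' shared nuisance/drift confounds, and per voxel the maximal T across
#' peaks is retained together with the winning latency. A joint F map is
#' also computed from one model containing all peak regressors
#' simultaneously against the confound-only reduced model. The volume is
#' globally normalised before fitting unless \code{normalize = FALSE}.
#'
#' @param vol a \linkS4class{Volume4D}.
#' @param feature a \linkS4class{FeatureSeries} (e.g. onsets).
#' @param mask a \linkS4class{BrainMask}.
#' @param peaks HRF peak latencies in seconds (default c(3, 5, 7, 9)).
#' @param nuisance,drift optional \linkS4class{NuisanceDesign}s shared by
#'   all fits; drift defaults to the 128 s DCT basis.
#' @param normalize apply \code{\link{globalMeanNormalize}} first.
#' @param microtimeBins microtime bins per TR for the regressors.
#' @return a \linkS4class{GLM2Result}.
#' @export
fitGLM2 <- function(vol, feature, mask, peaks = c(3, 5, 7, 9),
                    nuisance = NULL, drift = NULL, normalize = TRUE,
                    microtimeBins = 16L) {
  if (!length(peaks)) stop("peaks must be non-empty")
  requireTimeSeries(vol)
  tr <- vol@tr
  T_ <- dim(vol@data)[4L]
  if (is.null(drift)) drift <- dctDriftBasis(T_, tr)
  if (normalize) vol <- globalMeanNormalize(vol, mask)

  regs <- vapply(peaks, function(p)
    buildRegressor(feature, hrfKernel("single_gamma", dt = tr / microtimeBins,
                                      peak = p),
                   tr, T_, microtimeBins), numeric(T_))
  regs <- matrix(regs, ncol = length(peaks))
  colnames(regs) <- paste0("hrf_peak", peaks)

  tMaps <- vector("list", length(peaks))
  dof <- NA_real_
  for (i in seq_along(peaks)) {
    des <- assembleDesign(regs[, i, drop = FALSE], nuisance, drift)
    sm <- fitGLM(vol, des, mask, des@contrasts[[1L]])
    tMaps[[i]] <- sm@stat
    dof <- sm@dof[2L]
  }
  names(tMaps) <- paste0("peak", peaks)

  stacked <- vapply(tMaps, as.numeric, numeric(prod(dim(mask@flags))))
  maxT <- apply(stacked, 1L, function(v)
    if (all(is.na(v))) NA_real_ else max(v))
  best <- apply(stacked, 1L, function(v)
    if (all(is.na(v))) NA_real_ else peaks[which.max(v)])
  d3 <- dim(mask@flags)

  jointDes <- assembleDesign(regs, nuisance, drift)
  condNum <- kappa(cbind(regs), exact = TRUE)
  if (condNum > 1e8)
    warning("peak regressors are nearly collinear (condition ",
            format(condNum, digits = 3), "); joint F uses a pseudoinverse")
  jointF <- fitGLM(vol, jointDes, mask, "F_interest")

  new("GLM2Result", peaks = as.numeric(peaks), tMaps = tMaps,
      maxT = array(maxT, d3), bestPeak = array(best, d3), jointF = jointF,
      dof = dof)
}
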