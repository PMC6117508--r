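#' @import methods
NULL

#' Masked 4D BOLD volume
#'
#' Container for a 4D BOLD grid indexed (x, y, z, t), its repetition time,
#' voxel geometry and affine. All fMRI measures in the package operate on
#' this class. Volumes read from 3D files carry \code{t = 1}; time-series
#' operations reject such volumes.
#'
#' @slot data numeric 4D array, (x, y, z, t).
#' @slot tr repetition time in seconds (> 0).
#' @slot voxelSize numeric length-3, voxel edge lengths in mm.
#' @slot affine 4x4 voxel-to-world matrix.
#' @slot spaceTag free-text space label (e.g. "native", "MNI").
#' @exportClass Volume4D
setClass("Volume4D",
  representation(data = "array", tr = "numeric", voxelSize = "numeric",
                 affine = "matrix", spaceTag = "character"),
  prototype(voxelSize = c(3, 3, 3), affine = diag(4), spaceTag = "native"))

setValidity("Volume4D", function(object) {
  d <- dim(object@data)
  if (length(d) != 4L) return("data must be a 4D array (x, y, z, t)")
  if (d[4L] < 1L) return("t-dimension must be >= 1")
  if (length(object@tr) != 1L || !is.finite(object@tr) || object@tr <= 0)
    return("tr must be a single positive number")
  if (!all(dim(object@affine) == c(4L, 4L))) return("affine must be 4x4")
  if (length(object@voxelSize) != 3L) return("voxelSize must have length 3")
  TRUE
})

#' Binary brain mask
#'
#' Logical 3D grid marking in-brain voxels; must match the spatial
#' dimensions of the volume it is paired with.
#'
#' @slot flags logical 3D array.
#' @exportClass BrainMask
setClass("BrainMask", representation(flags = "array"))

setValidity("BrainMask", function(object) {
  if (length(dim(object@flags)) != 3L) return("flags must be a 3D array")
  if (!is.logical(object@flags)) return("flags must be logical")
  if (sum(object@flags) < 1L) return("mask must contain at least one voxel")
  TRUE
})

#' Rigid-body head motion parameters
#'
#' T x 6 realignment series in the column order
#' [X, Y, Z, pitch, yaw, roll] (mm, mm, mm, rad, rad, rad).
#'
#' @slot series T x 6 numeric matrix.
#' @exportClass MotionParams
setClass("MotionParams", representation(series = "matrix"))

setValidity("MotionParams", function(object) {
  if (ncol(object@series) != 6L)
    return(sprintf("motion series must have 6 columns, found %d",
                   ncol(object@series)))
  if (!is.numeric(object@series)) return("motion series must be numeric")
  TRUE
})

#' Multichannel EEG recording
#'
#' Channels x samples matrix in microvolts with sampling rate, labels, an
#' event table (onset, duration, type; seconds from recording start), bad
#' blocks as half-open [start, end) intervals, and the current reference
#' state.
#'
#' @slot signals C x S numeric matrix, microvolts.
#' @slot srate sampling rate in Hz.
#' @slot channelLabels character vector of length C.
#' @slot events data.frame with columns onset, duration, type.
#' @slot badBlocks n x 2 numeric matrix of [start_s, end_s) intervals.
#' @slot reference reference tag: "original", "average" or a channel set.
#' @exportClass EEGRecording
setClass("EEGRecording",
  representation(signals = "matrix", srate = "numeric",
                 channelLabels = "character", events = "data.frame",
                 badBlocks = "matrix", reference = "character"),
  prototype(events = data.frame(onset = numeric(0), duration = numeric(0),
                                type = character(0),
                                stringsAsFactors = FALSE),
            badBlocks = matrix(numeric(0), ncol = 2L),
            reference = "original"))

setValidity("EEGRecording", function(object) {
  C <- nrow(object@signals)
  if (length(object@channelLabels) != C)
    return("channelLabels length must equal number of signal rows")
  if (length(object@srate) != 1L || object@srate <= 0)
    return("srate must be a single positive number")
  dur <- ncol(object@signals) / object@srate
  ev <- object@events
  if (!all(c("onset", "duration", "type") %in% names(ev)))
    return("events must have columns onset, duration, type")
  if (nrow(ev) && (any(ev$onset < 0) || any(ev$onset > dur)))
    return("event onsets must lie within the recording")
  if (nrow(ev) && is.unsorted(ev$onset))
    return("event onsets must be sorted non-decreasing")
  bb <- object@badBlocks
  if (ncol(bb) != 2L) return("badBlocks must have two columns")
  if (nrow(bb) && (any(bb[, 1L] < 0) || any(bb[, 2L] > dur + 1e-9) ||
                   any(bb[, 1L] >= bb[, 2L])))
    return("bad blocks must be non-empty intervals within [0, duration)")
  TRUE
})

#' Confound regressor design
#'
#' T x P matrix of nuisance regressors (motion expansions, tissue means,
#' trend, DCT drift) with one label per column.
#'
#' @slot matrix T x P numeric matrix.
#' @slot labels character vector of length P.
#' @slot schemeTag one of "6", "12", "24", "36", "custom".
#' @exportClass NuisanceDesign
setClass("NuisanceDesign",
  representation(matrix = "matrix", labels = "character",
                 schemeTag = "character"),
  prototype(schemeTag = "custom"))

setValidity("NuisanceDesign", function(object) {
  if (ncol(object@matrix) != length(object@labels))
    return("one label per column required")
  if (anyDuplicated(object@labels)) return("labels must be unique")
  TRUE
})

#' Event-onset / band-power / ERP-amplitude feature series
#'
#' EEG-derived scalar series used to build fMRI regressors. For kind
#' "onsets" the values are all 1; TR-locked series carry one value per
#' volume; missing values (bad blocks) are NA.
#'
#' @slot kind "onsets", "power" or "amplitude".
#' @slot times numeric, sorted times in seconds.
#' @slot values numeric, same length as times (NA = flagged missing).
#' @slot trLocked logical; TRUE when sampled once per TR.
#' @slot band optional length-2 numeric frequency band in Hz.
#' @exportClass FeatureSeries
setClass("FeatureSeries",
  representation(kind = "character", times = "numeric", values = "numeric",
                 trLocked = "logical", band = "numeric"),
  prototype(trLocked = FALSE, band = numeric(0)))

setValidity("FeatureSeries", function(object) {
  if (!object@kind %in% c("onsets", "power", "amplitude"))
    return("kind must be onsets, power or amplitude")
  if (length(object@times) != length(object@values))
    return("times and values must have equal length")
  if (length(object@times) > 1L && is.unsorted(object@times))
    return("times must be sorted")
  if (object@kind == "onsets" && length(object@values) &&
      any(object@values != 1))
    return("onset series must carry unit values")
  TRUE
})

#' Multi-threshold FCD map set
#'
#' Per correlation threshold: local, global and long-range functional
#' connectivity density count maps and their global-mean-normalised
#' variants. Out-of-mask voxels are NA.
#'
#' @slot thresholds strictly increasing correlation thresholds in (0, 1).
#' @slot maps list (one element per threshold) of lists with entries
#'   lfcd, gfcd, lrfcd, nlfcd, ngfcd, nlrfcd (3D arrays).
#' @slot connectivity 6, 18 or 26.
#' @slot mask the BrainMask used.
#' @exportClass FCDMaps
setClass("FCDMaps",
  representation(thresholds = "numeric", maps = "list",
                 connectivity = "integer", mask = "BrainMask"))

#' Spatio-temporal consistency (FOCA) map
#'
#' Voxelwise product of rectified temporal and spatial consistency of the
#' 27-voxel neighbourhood; raw values in [0, 1], plus the global-mean
#' normalised map and a flag map for degenerate neighbourhoods.
#'
#' @slot raw 3D array in [0, 1] (NA outside mask).
#' @slot normalized raw divided by its in-mask mean.
#' @slot temporal,spatial component consistency maps.
#' @slot flagged logical 3D array; TRUE where the neighbourhood was too
#'   small or degenerate and FOCA was set to 0.
#' @slot combinerTag description of the combining rule.
#' @exportClass FOCAMap
setClass("FOCAMap",
  representation(raw = "array", normalized = "array", temporal = "array",
                 spatial = "array", flagged = "array",
                 combinerTag = "character"))

#' Microtime-resolution HRF kernel
#'
#' Hemodynamic response sampled on [0, duration] at resolution dt and
#' scaled to peak magnitude 1.
#'
#' @slot samples numeric kernel values.
#' @slot dt microtime step in seconds.
#' @slot modelTag "single_gamma", "spm_canonical" or "glover".
#' @slot peak nominal peak latency in seconds.
#' @slot duration kernel support in seconds (default 32).
#' @exportClass HRFKernel
setClass("HRFKernel",
  representation(samples = "numeric", dt = "numeric", modelTag = "character",
                 peak = "numeric", duration = "numeric"))

setValidity("HRFKernel", function(object) {
  if (!all(is.finite(object@samples))) return("kernel must be finite")
  if (abs(max(abs(object@samples)) - 1) > 1e-8)
    return("kernel must be scaled to peak magnitude 1")
  TRUE
})

#' Partitioned GLM design matrix
#'
#' T x P design with columns partitioned into interest / nuisance / drift /
#' intercept blocks and default contrasts (one t per interest column, one F
#' over all of them).
#'
#' @slot matrix T x P numeric matrix.
#' @slot labels column labels.
#' @slot partition factor-like character vector over columns.
#' @slot contrasts named list of contrast vectors/matrices.
#' @exportClass DesignMatrix
setClass("DesignMatrix",
  representation(matrix = "matrix", labels = "character",
                 partition = "character", contrasts = "list"))

setValidity("DesignMatrix", function(object) {
  P <- ncol(object@matrix)
  if (length(object@labels) != P || length(object@partition) != P)
    return("labels and partition must have one entry per column")
  if (anyDuplicated(object@labels)) return("duplicate column labels")
  if (sum(object@partition == "intercept") != 1L)
    return("exactly one intercept column required")
  TRUE
})

#' Voxelwise statistic map
#'
#' One statistical parametric map (t or F) with degrees of freedom, beta
#' maps and the residual-variance map. Out-of-mask voxels are NA.
#'
#' @slot stat 3D array of the statistic.
#' @slot kind "t" or "F".
#' @slot dof numerator and denominator degrees of freedom.
#' @slot beta 4D array (x, y, z, coefficient).
#' @slot resvar 3D residual-variance map.
#' @exportClass StatMap
setClass("StatMap",
  representation(stat = "array", kind = "character", dof = "numeric",
                 beta = "array", resvar = "array"))

#' Multi-HRF (maximum-T) GLM result
#'
#' Per-peak-latency T maps, their voxelwise maximum, the winning peak
#' latency, and the joint F map over all peak regressors.
#'
#' @slot peaks HRF peak latencies in seconds (default 3, 5, 7, 9).
#' @slot tMaps list of 3D T maps, one per peak.
#' @slot maxT voxelwise maximum over the per-peak T maps.
#' @slot bestPeak 3D map of the winning latency (seconds).
#' @slot jointF StatMap of the joint F test over all peak regressors.
#' @slot dof denominator degrees of freedom of the per-peak fits.
#' @exportClass GLM2Result
setClass("GLM2Result",
  representation(peaks = "numeric", tMaps = "list", maxT = "array",
                 bestPeak = "array", jointF = "StatMap", dof = "numeric"))

#' Local multimodal serial analysis result
#'
#' Per-voxel regression T map gated by CCA significance, the canonical
#' correlation map, significance mask, and per-voxel estimated HRF weights
#' over the lag grid.
#'
#' @slot tMap 3D T map (0 where CCA not significant; NA outside mask).
#' @slot rhoMap 3D first-canonical-correlation map.
#' @slot pMap 3D map of CCA p-values.
#' @slot sigMask logical 3D array, TRUE where p < alpha.
#' @slot hrfWeights matrix (voxels x lags) of EEG-side weights, rownames =
#'   linear voxel index; only significant voxels are stored.
#' @slot lags integer lags in TRs (0..L).
#' @slot tr repetition time in seconds.
#' @slot alpha significance level of the CCA gate.
#' @exportClass LMSAResult
setClass("LMSAResult",
  representation(tMap = "array", rhoMap = "array", pMap = "array",
                 sigMask = "array", hrfWeights = "matrix", lags = "integer",
                 tr = "numeric", alpha = "numeric"))

#' Ground truth of a synthetic BOLD simulation
#'
#' Records hub memberships and target correlations, planted activation
#' voxels with their true HRF peak and amplitude, event onsets, the noise
#' model and the seed, so recovery tests can score estimates.
#'
#' @slot hubs list of integer matrices (voxel ijk rows), one per hub.
#' @slot hubR target within-hub pairwise correlations.
#' @slot activation integer matrix of activated voxel ijk rows.
#' @slot peak true HRF peak latency in seconds.
#' @slot beta true activation amplitude.
#' @slot onsets event onset times in seconds.
#' @slot ar1 AR(1) coefficient of the background noise.
#' @slot sigma noise standard deviation.
#' @slot seed RNG seed used.
#' @exportClass SimTruth
setClass("SimTruth",
  representation(hubs = "list", hubR = "numeric", activation = "matrix",
                 peak = "numeric", beta = "numeric", onsets = "numeric",
                 ar1 = "numeric", sigma = "numeric", seed = "integer"),
  prototype(hubs = list(), hubR = numeric(0),
            activation = matrix(integer(0), ncol = 3L), peak = 5,
            beta = 0, onsets = numeric(0), ar1 = 0.3, sigma = 1,
            seed = 1L))
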