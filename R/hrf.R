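#' Hemodynamic response function kernels
#'
#' Samples an HRF model on [0, duration] at microtime resolution
#' \code{dt} and scales it to peak magnitude 1:
#' \describe{
#'   \item{single_gamma}{gamma density with unit scale and shape
#'     \code{peak + 1}, so the mode sits exactly at \code{peak} seconds —
#'     the one-parameter family used by the multi-peak GLM (peaks 3, 5,
#'     7, 9 s);}
#'   \item{spm_canonical}{the canonical double-gamma: response gamma with
#'     delay 6 and dispersion 1 minus an undershoot gamma with delay 16,
#'     dispersion 1, at ratio 1/6;}
#'   \item{glover}{Glover's two-gamma fit (n1 = 6, t1 = 0.9 s, n2 = 12,
#'     t2 = 0.9 s, undershoot amplitude 0.35), peaking near 5.4 s.}
#' }
#'
#' @param model "single_gamma", "spm_canonical" or "glover".
#' @param dt microtime step in seconds.
#' @param peak peak latency in seconds (single_gamma only; required).
#' @param duration kernel support in seconds (default 32).
#' @return an \linkS4class{HRFKernel}.
#' @export
hrfKernel <- function(model = c("single_gamma", "spm_canonical", "glover"),
                      dt = 0.125, peak = NULL, duration = 32) {
  model <- match.arg(model)
  if (dt <= 0) stop("dt must be positive")
  t_ <- seq(0, duration, by = dt)
  if (model == "single_gamma") {
    if (is.null(peak)) stop("single_gamma needs a peak latency")
    if (peak <= 0) stop("peak must be positive")
    h <- stats::dgamma(t_, shape = peak + 1, scale = 1)
    nominalPeak <- peak
  } else if (model == "spm_canonical") {
    h <- stats::dgamma(t_, shape = 6, scale = 1) -
      stats::dgamma(t_, shape = 16, scale = 1) / 6
    nominalPeak <- 5
  } else {
    n1 <- 6; t1 <- 0.9; n2 <- 12; t2 <- 0.9; a2 <- 0.35
    h <- (t_ / (n1 * t1))^n1 * exp(-(t_ - n1 * t1) / t1) -
      a2 * (t_ / (n2 * t2))^n2 * exp(-(t_ - n2 * t2) / t2)
    nominalPeak <- n1 * t1
  }
  h <- h / max(abs(h))
  new("HRFKernel", samples = h, dt = dt, modelTag = model,
      peak = nominalPeak, duration = duration)
}
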