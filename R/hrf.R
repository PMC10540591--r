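#' Canonical double-gamma hemodynamic response function
#'
#' Samples the standard double-gamma impulse response (a positive gamma peak
#' around 5-6 s followed by a smaller, later undershoot) at the acquisition
#' rate. This is the delay/dispersion model used both to generate synthetic
#' BOLD responses and as the target of Wiener delay correction.
#'
#' The kernel is sampled at t = 0, TR, 2 TR, ..., giving
#' `ceiling(length_s / TR_s)` samples (22 samples for 32 s at TR 1.5 s). It is causal (zero before t = 0,
#' and exactly zero at t = 0) and normalized to unit sum so that convolving
#' a sustained boxcar yields a plateau at the boxcar's height.
#'
#' @param TR_s sampling interval in seconds (repetition time), > 0.
#' @param length_s kernel duration in seconds (default 32).
#' @param peak_delay_s delay of the positive response peak (default 6).
#' @param undershoot_delay_s delay of the undershoot (default 16).
#' @param undershoot_ratio peak:undershoot amplitude ratio (default 6).
#' @return An object of class `hrf_kernel`: list with `values` (numeric
#'   samples), `TR_s`, `times_s` and the shape parameters.
#' @examples
#' h <- double_gamma_hrf(1.5)
#' h$times_s[which.max(h$values)]  # near 5-6 s
#' @export
double_gamma_hrf <- function(TR_s, length_s = 32,
                             peak_delay_s = 6, undershoot_delay_s = 16,
                             undershoot_ratio = 6) {
  stopifnot(TR_s > 0, length_s > 0)
  n <- ceiling(length_s / TR_s)
  t <- (seq_len(n) - 1) * TR_s
  # gamma densities with scale 1 s; shape = delay gives mode at delay - 1
  a1 <- peak_delay_s
  a2 <- undershoot_delay_s
  h <- stats::dgamma(t, shape = a1, rate = 1) -
    stats::dgamma(t, shape = a2, rate = 1) / undershoot_ratio
  h[1] <- 0
  h <- h / sum(h)
  structure(list(values = h, TR_s = TR_s, times_s = t,
                 length_s = length_s, peak_delay_s = peak_delay_s,
                 undershoot_delay_s = undershoot_delay_s),
            class = "hrf_kernel")
}

# Causal convolution of a time series with an HRF kernel, truncated to the
# input length.
convolve_hrf <- function(x, hrf) {
  k <- hrf$values
  out <- stats::convolve(x, rev(k), type = "open")[seq_along(x)]
  out
}
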