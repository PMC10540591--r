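#' Expand per-report stress labels to per-frame labels
#'
#' Each report is taken as representative of the preceding report interval,
#' so report r's level is assigned to the `frames_per_report` frames leading
#' up to its cue (frames (r-1)*fpr + 1 ... r*fpr, 1-based).
#'
#' @param run_frames number of frames in the run.
#' @param report_labels integer stress levels (1-8), one per report, in
#'   report order.
#' @param frames_per_report frames per report interval (default 10, i.e.
#'   15 s at TR 1.5 s).
#' @return Integer vector of length `run_frames`.
#' @export
align_labels <- function(run_frames, report_labels, frames_per_report = 10) {
  n_rep <- length(report_labels)
  if (run_frames != n_rep * frames_per_report)
    stop(sprintf(
      "frame accounting mismatch: %d frames != %d reports x %d frames/report",
      run_frames, n_rep, frames_per_report))
  rep(as.integer(report_labels), each = frames_per_report)
}

#' Percent signal change normalization
#'
#' Expresses each feature's time course as percentage deviation from its
#' temporal mean within the run: x_t -> 100 (x_t / mean(x) - 1). Makes
#' features comparable across runs and sessions.
#'
#' @param X numeric matrix, frames x features (a vector is treated as one
#'   feature).
#' @return Matrix of the same shape; each column has exact zero mean.
#' @export
percent_signal_change <- function(X) {
  X <- as.matrix(X)
  m <- colMeans(X)
  zero <- abs(m) < 1e-12
  if (any(zero))
    stop(sprintf("zero temporal mean in feature(s): %s",
                 paste(utils::head(which(zero), 10), collapse = ", ")))
  100 * (sweep(X, 2, m, "/") - 1)
}

#' Regress nuisance structure out of a run
#'
#' Ordinary-least-squares projection of every feature onto the orthogonal
#' complement of the nuisance regressors (motion traces, HRF-convolved
#' button-press stick, intercept, ...). Collinear regressor columns are
#' pruned by pivoted QR at a documented tolerance before fitting; residuals
#' are orthogonal to every retained regressor. Applying the operation twice
#' equals applying it once.
#'
#' @param X numeric matrix, frames x features.
#' @param nuisance numeric matrix, frames x regressors.
#' @param keep_mean if TRUE, per-feature temporal means are added back to
#'   the residuals (useful before percent-signal-change).
#' @param tol relative pivoted-QR tolerance for pruning collinear columns
#'   (default 1e-10).
#' @return Residual matrix, same shape as `X`.
#' @export
regress_nuisance <- function(X, nuisance, keep_mean = FALSE, tol = 1e-10) {
  X <- as.matrix(X)
  N <- as.matrix(nuisance)
  stopifnot(nrow(N) == nrow(X))
  qrN <- qr(N, tol = tol)
  if (qrN$rank < ncol(N)) {
    keep <- qrN$pivot[seq_len(qrN$rank)]
    warning(sprintf("dropping %d collinear nuisance column(s)",
                    ncol(N) - qrN$rank))
    N <- N[, sort(keep), drop = FALSE]
    qrN <- qr(N, tol = tol)
    if (qrN$rank < ncol(N)) stop("nuisance matrix rank-deficient after pruning")
  }
  res <- qr.resid(qrN, X)
  if (keep_mean) res <- sweep(res, 2, colMeans(X), "+")
  res
}

# DCT-II basis columns k = 0 .. K-1 over T frames; column k has frequency
# k / (2 T TR) Hz.
dct_basis <- function(T_frames, K) {
  t <- seq_len(T_frames) - 1
  sapply(0:(K - 1), function(k) cos(pi * k * (t + 0.5) / T_frames))
}

#' Temporal high-pass filter by discrete-cosine drift regression
#'
#' Removes slow drift by regressing out the DCT-II basis functions with
#' frequency below `cutoff_hz` (including the constant term), the standard
#' fMRI drift model. Components at or above the cutoff are untouched up to
#' the (small) leakage of the regression.
#'
#' @param X numeric matrix, frames x features.
#' @param cutoff_hz cutoff frequency in Hz (default 0.01).
#' @param TR_s repetition time in seconds.
#' @param keep_mean if TRUE, per-feature temporal means are added back.
#' @return Filtered matrix, same shape.
#' @export
highpass_filter <- function(X, cutoff_hz = 0.01, TR_s = 1.5,
                            keep_mean = FALSE) {
  stopifnot(cutoff_hz > 0)
  X <- as.matrix(X)
  T_frames <- nrow(X)
  K <- ceiling(2 * T_frames * TR_s * cutoff_hz)   # k = 0 .. K-1 below cutoff
  K <- max(1, min(K, T_frames))
  B <- dct_basis(T_frames, K)
  res <- qr.resid(qr(B), X)
  if (keep_mean) res <- sweep(res, 2, colMeans(X), "+")
  res
}

#' Wiener deconvolution of the hemodynamic response
#'
#' Frequency-domain regularized inverse filtering used to undo the
#' hemodynamic delay: Xhat(f) = X(f) H*(f) / (|H(f)|^2 + 1 / snr_param),
#' with H the transfer function of the HRF kernel (zero-padded to the run
#' length; circular convolution convention). Large `snr_param` approaches
#' exact inversion; `snr_param -> 0` shrinks the output to zero.
#'
#' @param X numeric matrix, frames x features.
#' @param hrf an [double_gamma_hrf] kernel sampled at the run's TR.
#' @param snr_param signal-to-noise regularization parameter, > 0
#'   (default 100).
#' @return Delay-corrected matrix, same shape as `X`.
#' @export
wiener_deconvolve <- function(X, hrf, snr_param = 100) {
  stopifnot(snr_param > 0)
  X <- as.matrix(X)
  T_frames <- nrow(X)
  k <- hrf$values
  if (length(k) > T_frames) k <- k[seq_len(T_frames)]
  kp <- c(k, rep(0, T_frames - length(k)))
  H <- stats::fft(kp)
  G <- Conj(H) / (Mod(H)^2 + 1 / snr_param)
  apply(X, 2, function(x)
    Re(stats::fft(stats::fft(x) * G, inverse = TRUE)) / T_frames)
}

#' Average temporally adjacent frames into labeled block samples
#'
#' Within each report's frame window, keeps the LAST floor(fpr/BS)*BS frames
#' (the earliest remainder frames sit closest to the previous clip and carry
#' the most hemodynamic contamination) and averages non-overlapping
#' consecutive blocks of `BS` frames. Every block sample inherits its
#' report's label. With 10 frames per report, BS5 and BS4 yield 2 samples
#' per report and BS3 yields 3.
#'
#' @param X numeric matrix, frames x features, for one run.
#' @param report_labels integer levels, one per report, in order.
#' @param BS block size in frames (must be in 1 ... frames_per_report).
#' @param frames_per_report frames per report window (default 10).
#' @return A list: `X` (block-sample matrix), `label` (integer per sample),
#'   `report` (report index per sample, 1-based within run), `BS`.
#' @export
block_average <- function(X, report_labels, BS, frames_per_report = 10) {
  if (!(BS %in% seq_len(frames_per_report)))
    stop(sprintf("block size must be in 1..%d", frames_per_report))
  X <- as.matrix(X)
  n_rep <- length(report_labels)
  if (nrow(X) != n_rep * frames_per_report)
    stop("frame count does not match reports x frames_per_report")
  m <- frames_per_report %/% BS          # blocks per report
  drop0 <- frames_per_report - m * BS    # earliest frames discarded
  rows <- vector("list", n_rep * m)
  for (r in seq_len(n_rep)) {
    off <- (r - 1) * frames_per_report + drop0
    for (b in seq_len(m)) {
      idx <- off + (b - 1) * BS + seq_len(BS)
      rows[[(r - 1) * m + b]] <- colMeans(X[idx, , drop = FALSE])
    }
  }
  list(X = do.call(rbind, rows),
       label = rep(as.integer(report_labels), each = m),
       report = rep(seq_len(n_rep), each = m),
       BS = as.integer(BS))
}
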