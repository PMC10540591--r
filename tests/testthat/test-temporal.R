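test_that("label alignment assigns each report to its preceding frames", {
  lab <- align_labels(320, rep(1:8, 4))
  expect_length(lab, 320)
  expect_equal(lab[1:10], rep(1L, 10))       # frames before report 1's cue
  expect_equal(lab[311:320], rep(8L, 10))
  lab1 <- align_labels(10, 3)
  expect_equal(lab1, rep(3L, 10))
  expect_error(align_labels(25, c(1, 2)), "mismatch")
})

test_that("percent signal change is exact on known series", {
  expect_equal(as.numeric(percent_signal_change(cbind(rep(5, 4)))), rep(0, 4))
  expect_equal(as.numeric(percent_signal_change(cbind(c(90, 110)))),
               c(-10, 10))
  set.seed(2)
  X <- matrix(rnorm(40, mean = 100), 10, 4)
  expect_equal(colMeans(percent_signal_change(X)), rep(0, 4))
  expect_error(percent_signal_change(cbind(c(-1, 1))), "zero temporal mean")
})

test_that("nuisance regression residuals are orthogonal and match OLS", {
  set.seed(4)
  N <- cbind(1, rnorm(20), rnorm(20))
  X <- matrix(rnorm(20 * 3), 20, 3)
  res <- regress_nuisance(X, N)
  expect_lt(max(abs(t(N) %*% res)), 1e-10)
  # normal-equations oracle
  beta <- solve(t(N) %*% N, t(N) %*% X)
  expect_lt(max(abs(res - (X - N %*% beta))), 1e-10)
  # idempotent
  expect_lt(max(abs(regress_nuisance(res, N) - res)), 1e-10)
})

test_that("nuisance regression handles special structures", {
  # series equal to a regressor vanishes
  r <- rnorm(15)
  out <- regress_nuisance(cbind(r), cbind(1, r))
  expect_lt(max(abs(out)), 1e-10)
  # intercept-only nuisance demeans
  x <- rnorm(15, mean = 10)
  out <- regress_nuisance(cbind(x), cbind(rep(1, 15)))
  expect_equal(as.numeric(out), x - mean(x))
  # collinear columns are pruned with a warning
  expect_warning(regress_nuisance(cbind(x), cbind(1, r, 2 * r)), "collinear")
})

test_that("high-pass filtering removes drift and keeps fast components", {
  T_frames <- 320; TR <- 1.5
  t <- seq_len(T_frames) - 1
  # drift in the removed span: DCT k=1 half cosine
  drift <- 5 * cos(pi * (t + 0.5) / T_frames)
  out <- highpass_filter(cbind(drift), cutoff_hz = 0.01, TR_s = TR)
  expect_lt(max(abs(out)), 5 * 1e-8)
  # 0.1 Hz sine passes with amplitude preserved within 1%
  sine <- sin(2 * pi * 0.1 * t * TR)
  filt <- as.numeric(highpass_filter(cbind(sine), 0.01, TR))
  amp <- function(x) {
    sp <- Mod(fft(x)) / (length(x) / 2)
    max(sp[2:(length(x) / 2)])
  }
  expect_equal(amp(filt), amp(sine), tolerance = 0.01)
  # zero in, zero out
  expect_equal(as.numeric(highpass_filter(cbind(rep(0, 50)), 0.01, TR)),
               rep(0, 50))
})

test_that("Wiener deconvolution inverts the hemodynamic delay", {
  TR <- 1.5
  hrf <- double_gamma_hrf(TR)
  # unit impulse response: output equals input in the high-snr limit
  imp <- hrf
  imp$values <- c(1, rep(0, length(hrf$values) - 1))
  set.seed(5)
  x <- rnorm(64)
  out <- wiener_deconvolve(cbind(x), imp, snr_param = 1e9)
  expect_lt(max(abs(out - x)), 1e-6)
  # noiseless boxcar * HRF: deconvolution recovers zero lag
  box <- as.numeric(seq_len(128) %in% 30:60)
  y <- cortexstress:::convolve_hrf(box, hrf)
  lag_in <- ccf(y, box, lag.max = 20, plot = FALSE)
  expect_gt(lag_in$lag[which.max(lag_in$acf)], 0)   # HRF delays the input
  dec <- as.numeric(wiener_deconvolve(cbind(y), hrf, snr_param = 1e6))
  lag_out <- ccf(dec, box, lag.max = 20, plot = FALSE)
  expect_equal(lag_out$lag[which.max(lag_out$acf)], 0)
  # snr -> 0 shrinks everything to zero
  tiny <- wiener_deconvolve(cbind(x), hrf, snr_param = 1e-12)
  expect_lt(max(abs(tiny)), 1e-6 * max(abs(x)))
})

test_that("block averaging uses the tail frames of each report window", {
  X <- cbind(1:10)
  expect_equal(as.numeric(block_average(X, 4, BS = 5)$X), c(3, 8))
  expect_equal(as.numeric(block_average(X, 4, BS = 4)$X), c(4.5, 8.5))
  expect_equal(as.numeric(block_average(X, 4, BS = 3)$X), c(3, 6, 9))
  expect_error(block_average(X, 4, BS = 11), "block size")
})

test_that("block sample counts and labels follow the report structure", {
  set.seed(6)
  labels <- sample(1:8, 32, replace = TRUE)
  X <- matrix(rnorm(320 * 2), 320, 2)
  for (BS in c(3, 4, 5)) {
    ba <- block_average(X, labels, BS)
    m <- 10 %/% BS
    expect_equal(nrow(ba$X), 32 * m)
    expect_equal(ba$label, rep(labels, each = m))
    expect_equal(ba$report, rep(1:32, each = m))
  }
  # constant frames give constant samples
  const <- block_average(matrix(2.5, 10, 1), 7, BS = 3)
  expect_equal(as.numeric(const$X), rep(2.5, 3))
})

test_that("block averaging commutes with label lookup", {
  # labels are constant within a report, so averaging frames then attaching
  # the report label equals attaching per-frame labels then averaging blocks
  labels <- c(2, 5)
  frame_labels <- align_labels(20, labels)
  ba <- block_average(cbind(frame_labels), labels, BS = 5)
  expect_equal(as.numeric(ba$X), as.numeric(ba$label))
})
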