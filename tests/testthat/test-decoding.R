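test_that("rmse and accuracy match hand arithmetic", {
  expect_equal(rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse(c(1, 8), c(8, 1)), 7)
  expect_equal(rmse(c(2, 4), c(1, 2)), sqrt(2.5))
  expect_error(rmse(numeric(0), numeric(0)))
  expect_equal(accuracy(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(accuracy(c(1, 1, 1, 1), c(1, 2, 1, 2)), 0.5)
  # svr-style predictions: round half away from zero, clip to [1, 8]
  expect_equal(accuracy(4.5, 5), 1)
  expect_equal(accuracy(c(0.2, 8.9), c(1, 8)), 1)
  expect_error(accuracy(1:2, 1:3))
})

test_that("splits keep whole reports together and are stratified", {
  s <- toy_samples(n_reports = 40, block = 3, seed = 2)
  sp <- split_by_report(s, test_fraction = 0.2, seed = 1)
  # every sample of a report lands on exactly one side
  expect_length(intersect(s$report[sp$train], s$report[sp$test]), 0)
  expect_setequal(c(sp$train, sp$test), seq_len(nrow(s$X)))
  # block samples move as groups of 3
  expect_equal(length(sp$test) %% 3, 0)
})

test_that("10 reports at test fraction 0.2 give 2 test reports", {
  # two reports per level over 5 levels: round(0.2 * 2) = 0 per level would
  # starve the test side, so use one level with 10 reports
  X <- matrix(rnorm(20), 20, 1)
  s <- decoding_samples(X, rep(c(1, 5), each = 10),
                        rep(1:10, each = 2))
  sp <- split_by_report(s, test_fraction = 0.2, seed = 3)
  expect_length(sp$test_reports, 2)
  expect_length(sp$train_reports, 8)
})

test_that("different seeds give different partitions almost always", {
  s <- toy_samples(n_reports = 24, block = 2, seed = 5)
  keys <- vapply(1:100, function(seed) {
    sp <- split_by_report(s, 0.25, seed = seed)
    paste(sort(sp$test_reports), collapse = ",")
  }, character(1))
  expect_gte(length(unique(keys)), 95)
})

test_that("a single-report class stays in training with a warning", {
  X <- matrix(rnorm(22), 22, 1)
  lab <- c(rep(1, 10), rep(2, 10), rep(5, 2))
  s <- decoding_samples(X, lab, c(rep(1:5, each = 2), rep(6:10, each = 2),
                                  rep(11, 2)))
  expect_warning(sp <- split_by_report(s, 0.4, seed = 1), "single report")
  expect_false(11 %in% sp$test_reports)
})

test_that("decoders separate trivially separable classes", {
  # two classes at distinct constant feature values
  X <- cbind(rep(c(0, 10), each = 20), rep(c(5, -5), each = 20))
  lab <- rep(c(2, 7), each = 20)
  for (kind in c("svm", "mlp")) {
    cfg <- experiment_config(kind, mlp_epochs = 300)
    dec <- train_decoder(X, lab, cfg, seed = 1)
    expect_equal(predict(dec, X), lab)
  }
  expect_error(train_decoder(X, rep(3, 40), experiment_config("svm")),
               "single class")
})

test_that("svr recovers labels carried by a single feature", {
  s <- toy_samples(n_reports = 32, n_features = 1, n_informative = 1,
                   noise = 0, block = 2, seed = 8)
  cfg <- experiment_config("svr", n_iterations = 4, base_seed = 1,
                           cost = 10, epsilon = 0.01)
  res <- run_experiment(s, cfg)
  expect_lte(res$mean_rmse, 0.1)
  # svr predictions are unrounded but clipped to [1, 8]
  p <- unlist(lapply(res$predictions, `[[`, "pred"))
  expect_true(all(p >= 1 & p <= 8))
})

test_that("training and prediction are deterministic per seed", {
  s <- toy_samples(seed = 9)
  for (kind in c("svm", "svr", "mlp")) {
    cfg <- experiment_config(kind, n_iterations = 2, base_seed = 5,
                             mlp_epochs = 50)
    r1 <- run_experiment(s, cfg)
    r2 <- run_experiment(s, cfg)
    expect_identical(r1$rmse, r2$rmse)
    expect_identical(r1$predictions, r2$predictions)
  }
})

test_that("run_experiment returns one RMSE and accuracy per iteration", {
  s <- toy_samples(seed = 3)
  res <- run_experiment(s, experiment_config("svm", n_iterations = 6,
                                             base_seed = 2))
  expect_length(res$rmse, 6)
  expect_length(res$accuracy, 6)
  expect_true(all(res$rmse >= 0 & res$rmse <= 7))
  expect_true(all(res$accuracy >= 0 & res$accuracy <= 1))
})

test_that("perfectly separable samples decode with zero error", {
  s <- toy_samples(n_reports = 48, n_features = 5, n_informative = 5,
                   noise = 0, block = 2, seed = 4)
  res <- run_experiment(s, experiment_config("svm", n_iterations = 3,
                                             base_seed = 1))
  expect_equal(res$mean_rmse, 0)
  expect_equal(res$mean_accuracy, 1)
})

test_that("feature-count optimization prefers the informative subset", {
  s <- toy_samples(n_reports = 40, n_features = 20, n_informative = 5,
                   noise = 0.3, block = 2, seed = 1)
  cfg <- experiment_config("svm", n_iterations = 5, base_seed = 3)
  single <- optimize_feature_count(s, cfg, candidates = 7)
  expect_equal(single$best_K, 7)
  opt <- optimize_feature_count(s, cfg, candidates = c(5, 20))
  expect_equal(nrow(opt$table), 2)
  expect_equal(opt$best_K, 5)    # informative features are in the top 5
})

test_that("condition comparison uses an exact paired signed-rank test", {
  set.seed(12)
  base <- abs(rnorm(25)) + 1
  A <- list(rmse = base)
  # all-positive, distinct differences: one-sided-extreme statistic
  d <- runif(25, 0.5, 1.5)
  B <- list(rmse = base + d)
  cmp <- compare_conditions(A, B)
  expect_equal(cmp$p_value, 2 / 2^25)    # exact enumeration tail, V = 0
  expect_equal(cmp$direction, -1)        # A better (lower RMSE)
  swap <- compare_conditions(B, A)
  expect_equal(swap$p_value, cmp$p_value)
  expect_equal(swap$direction, 1)
  same <- compare_conditions(A, A)
  expect_equal(same$p_value, 1.0)
  expect_equal(same$direction, 0)
})

test_that("a canary feature encoding test labels does not leak", {
  # one canary among many features: a decoder that exploited it would gain
  # a lot, while its legitimate variance impact is negligible
  s <- toy_samples(n_reports = 60, n_features = 500, n_informative = 20,
                   noise = 0.5, block = 2, seed = 6)
  cfg <- experiment_config("svm", n_iterations = 1, base_seed = 11)
  sp <- split_by_report(s, cfg$test_fraction, seed = cfg$base_seed + 1)
  canary <- rnorm(nrow(s$X))
  # test labels (standardized so the feature's scale is unremarkable),
  # pure noise on train
  canary[sp$test] <- as.numeric(scale(s$label[sp$test]))
  s_canary <- decoding_samples(cbind(s$X, canary), s$label, s$report,
                               BS = s$BS)
  r_with <- run_experiment(s_canary, cfg)
  r_without <- run_experiment(s, cfg)
  expect_lt(abs(r_with$mean_rmse - r_without$mean_rmse), 0.05 + 1e-12)
})
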