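#' Labeled block-averaged samples ready for decoding
#'
#' Bundles a samples-by-features matrix with per-sample stress labels and
#' the report/run/session bookkeeping needed for leakage-safe splitting
#' (all block samples from one 15 s report share a group id and must land
#' on the same side of any split).
#'
#' @param X numeric matrix, samples x features.
#' @param label integer stress levels (1-8), one per row.
#' @param report group id per row (globally unique per report).
#' @param run,session optional per-row provenance.
#' @param BS block size used to build the samples.
#' @return An object of class `decoding_samples`.
#' @export
decoding_samples <- function(X, label, report, run = NULL, session = NULL,
                             BS = NA_integer_) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(label), length(label) == length(report),
            all(label %in% 1:8))
  structure(list(X = X, label = as.integer(label), report = report,
                 run = run, session = session, BS = BS),
            class = "decoding_samples")
}

#' @export
print.decoding_samples <- function(x, ...) {
  cat(sprintf("decoding_samples: %d samples x %d features, %d reports (BS=%s)\n",
              nrow(x$X), ncol(x$X), length(unique(x$report)),
              as.character(x$BS)))
  invisible(x)
}

#' Experiment configuration for a decoding run
#'
#' @param model_kind one of "svm" (RBF-kernel multi-class classifier),
#'   "svr" (RBF-kernel support-vector regression on the numeric label,
#'   predictions clipped to 1-8), "mlp" (feed-forward net, two hidden
#'   layers, softmax over 8 classes).
#' @param BS block size the samples were built with (bookkeeping).
#' @param K_sub number of ANOVA-F-selected features, or "all".
#' @param n_iterations number of randomized split iterations (default 25).
#' @param test_fraction fraction of reports held out per iteration
#'   (default 0.2).
#' @param base_seed iteration i uses seed `base_seed + i`.
#' @param cost,gamma,epsilon support-vector hyperparameters (gamma NULL =
#'   1 / n_features).
#' @param mlp_hidden,mlp_epochs,mlp_lr multilayer-perceptron hyperparameters.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(model_kind = c("svm", "svr", "mlp"), BS = 5,
                              K_sub = "all", n_iterations = 25,
                              test_fraction = 0.2, base_seed = 1,
                              cost = 1, gamma = NULL, epsilon = 0.1,
                              mlp_hidden = c(32, 16), mlp_epochs = 200,
                              mlp_lr = 1e-3) {
  model_kind <- match.arg(model_kind)
  stopifnot(n_iterations >= 1, test_fraction > 0, test_fraction < 1)
  structure(list(model_kind = model_kind, BS = BS, K_sub = K_sub,
                 n_iterations = as.integer(n_iterations),
                 test_fraction = test_fraction,
                 base_seed = as.integer(base_seed), cost = cost,
                 gamma = gamma, epsilon = epsilon, mlp_hidden = mlp_hidden,
                 mlp_epochs = mlp_epochs, mlp_lr = mlp_lr),
            class = "experiment_config")
}

#' Split samples into train and test sets at the report level
#'
#' The unit of splitting is the report: all block samples of one report go
#' to the same side, preventing temporally adjacent (autocorrelated) frames
#' from straddling the split. The split is stratified by stress level where
#' class counts permit; a level represented by a single report goes to the
#' training side with a warning. At least two training reports per level
#' are always retained.
#'
#' @param samples a [decoding_samples] object.
#' @param test_fraction fraction of reports per level held out.
#' @param seed integer seed (deterministic split per seed).
#' @return List with `train` and `test` (row indices into `samples$X`), and
#'   `train_reports` / `test_reports` (report ids).
#' @export
split_by_report <- function(samples, test_fraction = 0.2, seed = 1) {
  rep_ids <- unique(samples$report)
  rep_label <- samples$label[match(rep_ids, samples$report)]
  with_seed(seed, {
    test_reports <- list()
    for (lv in sort(unique(rep_label))) {
      ids <- rep_ids[rep_label == lv]
      n <- length(ids)
      if (n == 1) {
        warning(sprintf("stress level %d has a single report; kept in train",
                        lv))
        next
      }
      n_test <- min(round(test_fraction * n), n - 2)
      if (n_test > 0)
        test_reports[[as.character(lv)]] <- sample(ids, n_test)
    }
    test_reports <- unlist(test_reports, use.names = FALSE)
    if (length(test_reports) == 0)
      stop("no reports available for the test side; too few reports per level")
    test <- which(samples$report %in% test_reports)
    list(train = setdiff(seq_len(nrow(samples$X)), test), test = test,
         train_reports = setdiff(rep_ids, test_reports),
         test_reports = test_reports)
  })
}

#' Train a stress decoder
#'
#' Features are standardized with training-set statistics only (stored in
#' the fitted object and re-applied at prediction time). SVM and SVR use
#' RBF kernels via libsvm; the MLP is a two-hidden-layer softmax network
#' with seeded deterministic initialization.
#'
#' @param X training matrix, samples x features.
#' @param labels integer stress levels (1-8).
#' @param config an [experiment_config].
#' @param seed seed for stochastic initialization (mlp).
#' @return A `stress_decoder` object; use [predict.stress_decoder].
#' @export
train_decoder <- function(X, labels, config = experiment_config(),
                          seed = config$base_seed) {
  X <- as.matrix(X)
  if (length(unique(labels)) < 2) stop("training set has a single class")
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Z <- sweep(sweep(X, 2, mu, "-"), 2, sdv, "/")
  gamma <- if (is.null(config$gamma)) 1 / ncol(X) else config$gamma
  fit <- switch(config$model_kind,
    svm = e1071::svm(Z, factor(labels, levels = 1:8),
                     type = "C-classification", kernel = "radial",
                     cost = config$cost, gamma = gamma, scale = FALSE),
    svr = e1071::svm(Z, as.numeric(labels), type = "eps-regression",
                     kernel = "radial", cost = config$cost, gamma = gamma,
                     epsilon = config$epsilon, scale = FALSE),
    mlp = {
      cls <- 1:8
      Y <- matrix(0, nrow(Z), 8)
      Y[cbind(seq_len(nrow(Z)), labels)] <- 1
      list(par = mlp_train(Z, Y, hidden = config$mlp_hidden,
                           epochs = config$mlp_epochs, lr = config$mlp_lr,
                           seed = seed),
           classes = cls)
    })
  structure(list(kind = config$model_kind, fit = fit, mu = mu, sd = sdv),
            class = "stress_decoder")
}

#' Predict stress levels with a fitted decoder
#'
#' @param object a `stress_decoder`.
#' @param newdata matrix, samples x features (same columns as training).
#' @param ... unused.
#' @return Numeric predictions: integer class levels for svm/mlp; unrounded
#'   values clipped to [1, 8] for svr.
#' @export
predict.stress_decoder <- function(object, newdata, ...) {
  Z <- sweep(sweep(as.matrix(newdata), 2, object$mu, "-"), 2, object$sd, "/")
  switch(object$kind,
    svm = as.numeric(as.character(stats::predict(object$fit, Z))),
    svr = pmin(pmax(as.numeric(stats::predict(object$fit, Z)), 1), 8),
    mlp = as.numeric(mlp_predict(object$fit$par, Z, object$fit$classes)))
}

#' Root mean square error between predicted and true stress levels
#'
#' On ordinal labels RMSE penalizes distant confusions more than adjacent
#' ones, which is what makes it informative alongside exact-match accuracy.
#'
#' @param pred,true numeric vectors of equal, positive length.
#' @return sqrt(mean((pred - true)^2)).
#' @export
rmse <- function(pred, true) {
  if (length(pred) == 0 || length(pred) != length(true))
    stop("pred and true must have equal positive length")
  sqrt(mean((pred - true)^2))
}

# round-half-away-from-zero (R's round() rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Exact-match classification accuracy
#'
#' Non-integer predictions (support-vector regression output) are first
#' rounded to the nearest integer (halves away from zero) and clipped to
#' [1, 8].
#'
#' @param pred,true numeric vectors of equal, positive length.
#' @return Fraction of exact matches in [0, 1].
#' @export
accuracy <- function(pred, true) {
  if (length(pred) == 0 || length(pred) != length(true))
    stop("pred and true must have equal positive length")
  p <- pmin(pmax(round_half_away(pred), 1), 8)
  mean(p == true)
}

#' Run a repeated-split decoding experiment
#'
#' For iteration i (seed `base_seed + i`): split reports into train/test,
#' rank features by ANOVA F on the training rows and keep the top `K_sub`,
#' train the decoder, predict the held-out samples, and record RMSE and
#' accuracy. Feature selection and standardization never see test rows.
#'
#' @param samples a [decoding_samples] object.
#' @param config an [experiment_config].
#' @return A `decoding_result`: per-iteration `rmse`, `accuracy`,
#'   `predictions` (list of data.frames), means/SDs, and the config.
#' @export
run_experiment <- function(samples, config = experiment_config()) {
  n_it <- config$n_iterations
  rmse_v <- numeric(n_it); acc_v <- numeric(n_it)
  preds <- vector("list", n_it)
  for (i in seq_len(n_it)) {
    seed_i <- config$base_seed + i
    res <- tryCatch({
      sp <- split_by_report(samples, config$test_fraction, seed = seed_i)
      Xtr <- samples$X[sp$train, , drop = FALSE]
      ytr <- samples$label[sp$train]
      sel <- if (!identical(config$K_sub, "all") &&
                 config$K_sub < ncol(samples$X))
        select_features(Xtr, ytr, config$K_sub)
      else seq_len(ncol(samples$X))
      dec <- train_decoder(Xtr[, sel, drop = FALSE], ytr, config,
                           seed = seed_i)
      p <- predict(dec, samples$X[sp$test, sel, drop = FALSE])
      yte <- samples$label[sp$test]
      list(p = p, y = yte)
    }, error = function(e)
      stop(sprintf("iteration %d: %s", i, conditionMessage(e)), call. = FALSE))
    rmse_v[i] <- rmse(res$p, res$y)
    acc_v[i] <- accuracy(res$p, res$y)
    preds[[i]] <- data.frame(iteration = i, pred = res$p, true = res$y)
  }
  structure(list(rmse = rmse_v, accuracy = acc_v,
                 mean_rmse = mean(rmse_v), sd_rmse = stats::sd(rmse_v),
                 mean_accuracy = mean(acc_v), sd_accuracy = stats::sd(acc_v),
                 predictions = preds, config = config),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf(
    "decoding_result [%s, BS%s, K=%s]: RMSE %.3f (SD %.3f), accuracy %.1f%% over %d iterations\n",
    x$config$model_kind, as.character(x$config$BS),
    as.character(x$config$K_sub), x$mean_rmse, x$sd_rmse,
    100 * x$mean_accuracy, x$config$n_iterations))
  invisible(x)
}

#' Optimize the retained feature count
#'
#' Runs the same experiment (identical seed schedule, hence paired
#' iterations) for each candidate feature count and returns the candidate
#' with the lowest mean RMSE (ties broken toward the larger count).
#'
#' @param samples a [decoding_samples] object.
#' @param config an [experiment_config]; its `K_sub` is overridden.
#' @param candidates integer feature counts to try
#'   (default c(1600, 2400, 4700)).
#' @return List with `best_K`, `table` (one row per candidate: K, mean/sd
#'   RMSE, mean accuracy) and `results` (the per-candidate
#'   `decoding_result`s).
#' @export
optimize_feature_count <- function(samples, config = experiment_config(),
                                   candidates = c(1600, 2400, 4700)) {
  stopifnot(max(candidates) <= ncol(samples$X))
  results <- lapply(candidates, function(K) {
    cfg <- config; cfg$K_sub <- K
    run_experiment(samples, cfg)
  })
  tab <- data.frame(K_sub = candidates,
                    mean_rmse = vapply(results, `[[`, 0, "mean_rmse"),
                    sd_rmse = vapply(results, `[[`, 0, "sd_rmse"),
                    mean_accuracy = vapply(results, `[[`, 0, "mean_accuracy"))
  best <- candidates[order(tab$mean_rmse, -candidates)][1]
  list(best_K = best, table = tab, results = results)
}

#' Compare two matched decoding conditions
#'
#' Paired two-sided Wilcoxon signed-rank test on per-iteration RMSE (the
#' iterations must share a seed schedule so that pairs are matched). When
#' every paired difference is zero the p-value is 1 by convention.
#'
#' @param resultA,resultB `decoding_result`s with equal `n_iterations`.
#' @return List: `p_value`, `direction` (sign of the median difference
#'   RMSE_A - RMSE_B; negative means A better), `median_diff`.
#' @export
compare_conditions <- function(resultA, resultB) {
  stopifnot(length(resultA$rmse) == length(resultB$rmse))
  d <- resultA$rmse - resultB$rmse
  if (all(d == 0))
    return(list(p_value = 1.0, direction = 0, median_diff = 0))
  wt <- suppressWarnings(stats::wilcox.test(resultA$rmse, resultB$rmse,
                                            paired = TRUE))
  list(p_value = wt$p.value, direction = sign(stats::median(d)),
       median_diff = stats::median(d))
}
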