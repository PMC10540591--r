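#' Permute stress labels at the report level
#'
#' Randomly reassigns the per-report labels among reports; all block samples
#' of a report keep a common (permuted) label, so the multiset of report
#' labels is preserved and the block structure the split respects stays
#' intact. Sample-level permutation would leak within-report
#' autocorrelation into the null and make it anti-conservative.
#'
#' @param samples a [decoding_samples] object with >= 2 distinct labels.
#' @param seed integer seed (deterministic permutation per seed).
#' @return A [decoding_samples] object with permuted labels.
#' @export
permute_labels <- function(samples, seed = 1) {
  rep_ids <- unique(samples$report)
  rep_label <- samples$label[match(rep_ids, samples$report)]
  stopifnot(length(unique(rep_label)) >= 2)
  perm <- with_seed(seed, sample(length(rep_ids)))
  new_label <- rep_label[perm][match(samples$report, rep_ids)]
  out <- samples
  out$label <- as.integer(new_label)
  out
}

# Add-one permutation p-value: never zero, 1/(n+1) at best.
permutation_pvalue <- function(observed_mean, null_means) {
  (1 + sum(null_means <= observed_mean)) / (1 + length(null_means))
}

#' Permutation test of decoder performance
#'
#' Re-runs the full decoding experiment on label-permuted replicates of the
#' data to build a null distribution of mean RMSE, and compares the
#' observed mean RMSE against it with the add-one estimator
#' p = (1 + #\{null <= observed\}) / (1 + n_permutations). Also reports
#' whether the observed per-iteration RMSE distribution is disjoint from
#' the null (max observed < min null).
#'
#' @param samples a [decoding_samples] object.
#' @param config an [experiment_config] used for the observed run.
#' @param n_permutations number of label permutations (default 25).
#' @param null_iterations split iterations per null replicate (default:
#'   `config$n_iterations`; a smaller value trades null-replicate precision
#'   for speed — each null point is still a mean over that many splits).
#' @param observed optionally, a precomputed `decoding_result` for the true
#'   labels (must use `config`).
#' @return A `permutation_result`: `observed` (decoding_result),
#'   `null_rmse` (mean RMSE per permutation), `p_value`, `no_overlap`.
#' @export
permutation_test <- function(samples, config = experiment_config(),
                             n_permutations = 25,
                             null_iterations = config$n_iterations,
                             observed = NULL) {
  if (is.null(observed)) observed <- run_experiment(samples, config)
  null_cfg <- config
  null_cfg$n_iterations <- as.integer(null_iterations)
  null_rmse <- vapply(seq_len(n_permutations), function(j) {
    perm <- permute_labels(samples, seed = config$base_seed + 7919L * j)
    cfg_j <- null_cfg
    cfg_j$base_seed <- config$base_seed + 131L * j
    run_experiment(perm, cfg_j)$mean_rmse
  }, numeric(1))
  structure(list(observed = observed, null_rmse = null_rmse,
                 p_value = permutation_pvalue(observed$mean_rmse, null_rmse),
                 no_overlap = max(observed$rmse) < min(null_rmse),
                 n_permutations = n_permutations),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(paste0("permutation_result: observed mean RMSE %.3f vs null ",
                     "%.3f-%.3f (%d permutations), p = %.4f%s\n"),
              x$observed$mean_rmse, min(x$null_rmse), max(x$null_rmse),
              x$n_permutations, x$p_value,
              if (x$no_overlap) " [distributions disjoint]" else ""))
  invisible(x)
}
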