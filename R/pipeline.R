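# End-to-end driver: simulate (or load) -> sample onto the surface ->
# smooth along the manifold -> patch features -> temporal preprocessing ->
# block averaging -> decoding grid -> optional permutation test / ablation.

log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

# md5 of the canonical JSON rendering of a config list
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(as.character(jsonlite::toJSON(config, auto_unbox = TRUE,
                                           digits = 15, null = "null")), tf)
  unname(tools::md5sum(tf))
}

#' Extract patch features from the runs of one or more sessions
#'
#' Runs the spatial half of the pipeline: trilinear sampling of each 4D run
#' onto the mesh, graph-diffusion smoothing along the surface, and patch
#' averaging into the low-dimensional feature set (~5100 features at the
#' default `K_base` on a full-resolution mesh).
#'
#' @param sessions list of session objects, each with `runs` (list of
#'   `volume_ts`), `labels` (a `label_schedule`) and optionally `nuisance`
#'   (list of frames x regressor matrices), as returned by [simulate_bold].
#' @param mesh the [cortical_mesh] shared by all runs.
#' @param fwhm_mm smoothing extent along the manifold (default 6).
#' @param K_base number of patches (default 5100).
#' @param partition optionally a precomputed [build_patch_partition].
#' @return A list of class `subject_features`: `partition`, `runs` (one
#'   entry per run: `F` frames x K matrix, `report_labels`, `nuisance`,
#'   `session`, `run`, `TR_s`), `params` (fwhm, K).
#' @export
extract_subject_features <- function(sessions, mesh, fwhm_mm = 6,
                                     K_base = 5100, partition = NULL) {
  if (is.null(partition)) {
    log_stage("partition", "farthest-point sampling of %d patch centers", K_base)
    partition <- build_patch_partition(mesh, K_base)
  }
  runs <- list()
  for (s in seq_along(sessions)) {
    ses <- sessions[[s]]
    sched <- ses$labels
    for (r in seq_along(ses$runs)) {
      vol <- ses$runs[[r]]
      sts <- sample_volume_to_surface(vol, mesh)
      sts <- surface_smooth(sts, mesh, fwhm_mm)
      Fm <- patch_features(sts, partition)
      lab <- sched$stress_level[sched$run == r]
      log_stage("extract", "session %d run %d: %d frames x %d features",
                s, r, nrow(Fm), ncol(Fm))
      runs[[length(runs) + 1]] <- list(
        F = Fm, report_labels = lab,
        nuisance = if (!is.null(ses$nuisance)) ses$nuisance[[r]] else NULL,
        session = s, run = r, TR_s = vol$TR_s)
    }
  }
  structure(list(partition = partition, runs = runs,
                 params = list(fwhm_mm = fwhm_mm, K_base = partition$K)),
            class = "subject_features")
}

#' Temporal preprocessing of extracted features
#'
#' Applies, per run and in this fixed order: nuisance regression (motion
#' traces and HRF-convolved button-press stick, plus an intercept; feature
#' means restored afterwards), discrete-cosine high-pass filtering (means
#' restored), Wiener deconvolution of the hemodynamic delay, and finally
#' per-run percent-signal-change normalization. Every optional step is an
#' exact no-op when disabled; disabling all three reproduces the base case.
#'
#' @param sf a [extract_subject_features] result.
#' @param motion_regression,highpass,wiener logical toggles (all FALSE =
#'   base case).
#' @param cutoff_hz high-pass cutoff (default 0.01 Hz).
#' @param snr_param Wiener regularization (default 100).
#' @param hrf HRF kernel for the Wiener step (default double-gamma at the
#'   run TR).
#' @param normalize "psc" (percent signal change, default), "zscore", or
#'   "none".
#' @return A `subject_features` list with preprocessed `F` matrices and a
#'   `preproc` parameter record.
#' @export
preprocess_subject_features <- function(sf, motion_regression = FALSE,
                                        highpass = FALSE, wiener = FALSE,
                                        cutoff_hz = 0.01, snr_param = 100,
                                        hrf = NULL, normalize = "psc") {
  for (i in seq_along(sf$runs)) {
    ru <- sf$runs[[i]]
    Fm <- ru$F
    if (motion_regression) {
      if (is.null(ru$nuisance))
        stop("motion_regression requested but run has no nuisance traces")
      Fm <- regress_nuisance(Fm, cbind(intercept = 1, ru$nuisance),
                             keep_mean = TRUE)
    }
    if (highpass)
      Fm <- highpass_filter(Fm, cutoff_hz = cutoff_hz, TR_s = ru$TR_s,
                            keep_mean = TRUE)
    if (wiener) {
      h <- if (is.null(hrf)) double_gamma_hrf(ru$TR_s) else hrf
      Fm <- wiener_deconvolve(Fm, h, snr_param = snr_param)
    }
    Fm <- switch(normalize,
                 psc = percent_signal_change(Fm),
                 zscore = scale(Fm),
                 none = Fm)
    sf$runs[[i]]$F <- Fm
  }
  sf$preproc <- list(motion_regression = motion_regression,
                     highpass = highpass, wiener = wiener,
                     cutoff_hz = cutoff_hz, snr_param = snr_param,
                     normalize = normalize)
  sf
}

#' Block-average extracted features into decoding samples
#'
#' @param sf a (preprocessed) `subject_features` list.
#' @param BS block size in frames (3, 4 or 5 at the default 10 frames per
#'   report).
#' @param frames_per_report frames per report window (default 10).
#' @return A [decoding_samples] object with globally unique report ids.
#' @export
assemble_samples <- function(sf, BS = 5, frames_per_report = 10) {
  Xs <- list(); lab <- list(); rep_id <- list(); run_v <- list(); ses <- list()
  offset <- 0
  for (ru in sf$runs) {
    ba <- block_average(ru$F, ru$report_labels, BS, frames_per_report)
    Xs[[length(Xs) + 1]] <- ba$X
    lab[[length(lab) + 1]] <- ba$label
    rep_id[[length(rep_id) + 1]] <- ba$report + offset
    run_v[[length(run_v) + 1]] <- rep(ru$run, length(ba$label))
    ses[[length(ses) + 1]] <- rep(ru$session, length(ba$label))
    offset <- offset + length(ru$report_labels)
  }
  decoding_samples(do.call(rbind, Xs), unlist(lab), unlist(rep_id),
                   run = unlist(run_v), session = unlist(ses), BS = BS)
}

#' Simulate a complete synthetic subject
#'
#' Generates a spherical cortical mesh, one session design per session
#' (distinct seeds, shared clip grammar) and HRF-convolved noisy BOLD runs
#' with a common ordinal spatial encoding across sessions, mirroring a
#' 2-session acquisition.
#'
#' @param subdivision_level icosphere subdivision (default 5: 10242
#'   vertices).
#' @param radius_mm mesh radius (default 25).
#' @param n_sessions,n_runs sessions and runs per session (defaults 2, 5).
#' @param params a [simulation_params] (its seed controls everything).
#' @param run_duration_s run length (default 480 s).
#' @param level_pool levels to cover per session (default 1:8).
#' @return List: `mesh`, `sessions` (list of [simulate_bold] results),
#'   `designs`.
#' @export
simulate_subject <- function(subdivision_level = 5, radius_mm = 25,
                             n_sessions = 2, n_runs = 5,
                             params = simulation_params(),
                             run_duration_s = 480, level_pool = 1:8) {
  mesh <- make_synthetic_mesh(subdivision_level, radius_mm)
  designs <- lapply(seq_len(n_sessions), function(s)
    make_session_design(n_runs = n_runs, level_pool = level_pool,
                        seed = params$seed + 1000L * s,
                        run_duration_s = run_duration_s))
  hrf <- double_gamma_hrf(designs[[1]]$TR_s)
  # the spatial stress encoding depends on params$seed only and is shared
  # across sessions; noise streams are session-specific inside simulate_bold
  sessions <- lapply(seq_len(n_sessions), function(s)
    simulate_bold(mesh, designs[[s]], params, hrf, session = s))
  list(mesh = mesh, sessions = sessions, designs = designs)
}

#' Pipeline configuration
#'
#' Builds the configuration list consumed by [run_pipeline], either from
#' arguments or merged over the defaults from a YAML/JSON file.
#'
#' @param simulate list of simulation settings (`enabled`, mesh size,
#'   sessions/runs, [simulation_params] fields).
#' @param paths list of input paths used when `simulate$enabled` is FALSE:
#'   `volumes` (character vector), `run`, `session` (parallel integer
#'   vectors), `mesh` (OFF file), `events` (TSV).
#' @param features list: `fwhm_mm`, `K_base`.
#' @param preproc list: `motion_regression`, `highpass`, `wiener`,
#'   `cutoff_hz`, `snr_param`, `normalize`.
#' @param grid list: `models`, `BS`, `K_sub` (vectors; full cross product).
#' @param experiment list: `n_iterations`, `test_fraction`.
#' @param permutation list: `enabled`, `n_permutations`, `null_iterations`.
#' @param seed global seed.
#' @param out_dir output directory (NULL = no files written).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = list(), paths = list(),
                            features = list(), preproc = list(),
                            grid = list(), experiment = list(),
                            permutation = list(), seed = 1, out_dir = NULL) {
  merge_l <- function(def, user) { def[names(user)] <- user; def }
  cfg <- list(
    simulate = merge_l(list(enabled = TRUE, subdivision_level = 3,
                            radius_mm = 25, n_sessions = 2, n_runs = 2,
                            run_duration_s = 480,
                            effect_amplitude = 0.03, noise_sd = 0.02,
                            ordinal_overlap = 0.6, ar1_coef = 0.3,
                            drift_amplitude = 0.01,
                            pattern_smoothness_mm = 6,
                            baseline_intensity = 1000, voxel_size_mm = 2,
                            gm_thickness_mm = 2, motion_amplitude = 0,
                            button_amplitude = 0), simulate),
    paths = paths,
    features = merge_l(list(fwhm_mm = 6, K_base = 5100), features),
    preproc = merge_l(list(motion_regression = FALSE, highpass = FALSE,
                           wiener = FALSE, cutoff_hz = 0.01,
                           snr_param = 100, normalize = "psc"), preproc),
    grid = merge_l(list(models = "svm", BS = 5, K_sub = "all"), grid),
    experiment = merge_l(list(n_iterations = 25, test_fraction = 0.2),
                         experiment),
    permutation = merge_l(list(enabled = FALSE, n_permutations = 25,
                               null_iterations = NA), permutation),
    seed = as.integer(seed), out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from YAML or JSON
#'
#' @param path a `.yaml`/`.yml` or `.json` file whose top-level keys match
#'   the arguments of [pipeline_config].
#' @return A `pipeline_config` list (file values merged over defaults).
#' @export
load_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

# load input data per config: either simulate or read from disk
pipeline_load_data <- function(config) {
  if (isTRUE(config$simulate$enabled)) {
    sim_cfg <- config$simulate
    params <- simulation_params(
      effect_amplitude = sim_cfg$effect_amplitude,
      pattern_smoothness_mm = sim_cfg$pattern_smoothness_mm,
      ordinal_overlap = sim_cfg$ordinal_overlap,
      noise_sd = sim_cfg$noise_sd, ar1_coef = sim_cfg$ar1_coef,
      drift_amplitude = sim_cfg$drift_amplitude,
      baseline_intensity = sim_cfg$baseline_intensity,
      voxel_size_mm = sim_cfg$voxel_size_mm,
      gm_thickness_mm = sim_cfg$gm_thickness_mm,
      motion_amplitude = sim_cfg$motion_amplitude,
      button_amplitude = sim_cfg$button_amplitude,
      seed = config$seed)
    log_stage("simulate", "icosphere k=%d, %d session(s) x %d run(s)",
              sim_cfg$subdivision_level, sim_cfg$n_sessions, sim_cfg$n_runs)
    subj <- simulate_subject(sim_cfg$subdivision_level, sim_cfg$radius_mm,
                             sim_cfg$n_sessions, sim_cfg$n_runs, params,
                             sim_cfg$run_duration_s)
    list(mesh = subj$mesh, sessions = subj$sessions)
  } else {
    p <- config$paths
    stopifnot(!is.null(p$volumes), !is.null(p$mesh), !is.null(p$events))
    mesh <- read_mesh_off(p$mesh)
    sched <- read_events_tsv(p$events)
    ses_ids <- sort(unique(p$session))
    sessions <- lapply(ses_ids, function(s) {
      idx <- which(p$session == s)
      idx <- idx[order(p$run[idx])]
      list(runs = lapply(p$volumes[idx], read_bold_nifti),
           labels = sched[sched$session == s, ], nuisance = NULL)
    })
    log_stage("load", "%d volume(s) across %d session(s)",
              length(p$volumes), length(ses_ids))
    list(mesh = mesh, sessions = sessions)
  }
}

#' Run the full decoding pipeline
#'
#' Simulates (or loads) the data, extracts cortical patch features,
#' preprocesses them, and runs the decoding experiment for every cell of
#' the model x block-size x feature-count grid; optionally adds a
#' permutation test per grid cell. Results, an iteration-level TSV and a
#' summary JSON (carrying the config hash) are written to
#' `config$out_dir` when set.
#'
#' @param config a [pipeline_config].
#' @return A list of class `pipeline_result`: `grid` (data.frame summary),
#'   `results` (named list of `decoding_result`s), `permutations` (named
#'   list or NULL), `config`, `config_hash`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  # hash covers everything that affects the numbers (not the output path)
  hash <- config_hash(unclass(config)[setdiff(names(config), "out_dir")])
  dat <- pipeline_load_data(config)
  sf <- extract_subject_features(dat$sessions, dat$mesh,
                                 fwhm_mm = config$features$fwhm_mm,
                                 K_base = config$features$K_base)
  pp <- config$preproc
  sf <- preprocess_subject_features(sf,
    motion_regression = pp$motion_regression, highpass = pp$highpass,
    wiener = pp$wiener, cutoff_hz = pp$cutoff_hz,
    snr_param = pp$snr_param, normalize = pp$normalize)
  log_stage("preprocess", "motion=%s highpass=%s wiener=%s normalize=%s",
            pp$motion_regression, pp$highpass, pp$wiener, pp$normalize)

  cells <- expand.grid(model = config$grid$models, BS = config$grid$BS,
                       K_sub = config$grid$K_sub,
                       stringsAsFactors = FALSE)
  results <- list(); perms <- list()
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    samples <- assemble_samples(sf, BS = cell$BS)
    K_sub <- if (identical(cell$K_sub, "all")) "all" else
      min(as.numeric(cell$K_sub), ncol(samples$X))
    cfg <- experiment_config(model_kind = cell$model, BS = cell$BS,
                             K_sub = K_sub,
                             n_iterations = config$experiment$n_iterations,
                             test_fraction = config$experiment$test_fraction,
                             base_seed = config$seed)
    res <- run_experiment(samples, cfg)
    key <- sprintf("%s_BS%d_K%s", cell$model, cell$BS,
                   as.character(cell$K_sub))
    log_stage("decode", "%s: RMSE %.3f (SD %.3f), accuracy %.1f%%",
              key, res$mean_rmse, res$sd_rmse, 100 * res$mean_accuracy)
    results[[key]] <- res
    row <- data.frame(model = cell$model, BS = cell$BS,
                      K_sub = as.character(cell$K_sub),
                      mean_rmse = res$mean_rmse, sd_rmse = res$sd_rmse,
                      mean_accuracy = res$mean_accuracy)
    if (isTRUE(config$permutation$enabled)) {
      ni <- config$permutation$null_iterations
      pt <- permutation_test(samples, cfg,
        n_permutations = config$permutation$n_permutations,
        null_iterations = if (is.null(ni) || is.na(ni))
          cfg$n_iterations else ni,
        observed = res)
      perms[[key]] <- pt
      row$perm_p <- pt$p_value
      row$null_min <- min(pt$null_rmse)
      row$no_overlap <- pt$no_overlap
      log_stage("permute", "%s: p = %.4f, null %.3f-%.3f", key,
                pt$p_value, min(pt$null_rmse), max(pt$null_rmse))
    }
    rows[[i]] <- row
  }
  grid_tab <- do.call(rbind, rows)
  out <- structure(list(grid = grid_tab, results = results,
                        permutations = if (length(perms)) perms else NULL,
                        config = config, config_hash = hash),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_result(out, config$out_dir)
  out
}

# write grid TSV, iteration TSV and summary JSON into out_dir
write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(result$grid, file.path(out_dir, "grid_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  iters <- do.call(rbind, lapply(names(result$results), function(k) {
    r <- result$results[[k]]
    data.frame(cell = k, iteration = seq_along(r$rmse), rmse = r$rmse,
               accuracy = r$accuracy)
  }))
  utils::write.table(iters, file.path(out_dir, "iterations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(config_hash = result$config_hash,
                  config = unclass(result$config),
                  grid = result$grid)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       null = "null")
  invisible(out_dir)
}

#' Preprocessing ablation in the four-row layout
#'
#' Evaluates the same decoding configuration under four cumulative
#' preprocessing variants: none (base case); motion regression; high-pass
#' filtering + motion regression; high-pass filtering + motion regression +
#' Wiener filtering.
#'
#' @param sf an un-normalized [extract_subject_features] result whose runs
#'   carry nuisance traces (the function applies normalization itself).
#' @param config an [experiment_config] (typically svm at BS 5).
#' @param cutoff_hz,snr_param filter parameters.
#' @return A data.frame with one row per variant: `preprocessing`,
#'   `mean_rmse`, `sd_rmse`, `mean_accuracy`.
#' @export
run_ablation <- function(sf, config = experiment_config(model_kind = "svm",
                                                        BS = 5),
                         cutoff_hz = 0.01, snr_param = 100) {
  variants <- list(
    `None (base case)` = c(FALSE, FALSE, FALSE),
    `Motion regression` = c(TRUE, FALSE, FALSE),
    `High-pass filtering, motion regression` = c(TRUE, TRUE, FALSE),
    `High-pass filtering, motion regression, Wiener filtering` =
      c(TRUE, TRUE, TRUE))
  rows <- lapply(names(variants), function(nm) {
    v <- variants[[nm]]
    pf <- preprocess_subject_features(sf, motion_regression = v[1],
                                      highpass = v[2], wiener = v[3],
                                      cutoff_hz = cutoff_hz,
                                      snr_param = snr_param)
    res <- run_experiment(assemble_samples(pf, BS = config$BS), config)
    log_stage("ablate", "%s: RMSE %.3f (SD %.3f)", nm, res$mean_rmse,
              res$sd_rmse)
    data.frame(preprocessing = nm, mean_rmse = res$mean_rmse,
               sd_rmse = res$sd_rmse, mean_accuracy = res$mean_accuracy)
  })
  do.call(rbind, rows)
}
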