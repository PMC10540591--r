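# Shared fixtures, built in code and cached across test files.

.fixture_cache <- new.env(parent = emptyenv())

cache_get <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# regular tetrahedron: 4 vertices with 3 neighbors each
tetra_mesh <- function(scale = 1) {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) * scale
  f <- rbind(c(1, 2, 3), c(1, 3, 4), c(1, 4, 2), c(2, 4, 3))
  cortical_mesh(v, f)
}

# a small simulated subject shared by decoding/significance/pipeline tests:
# icosphere k=2 (162 vertices), 2 sessions x 2 runs of 4 min, default
# signal strength
small_subject <- function() {
  cache_get("small_subject", function() {
    simulate_subject(subdivision_level = 2, radius_mm = 12,
                     n_sessions = 2, n_runs = 2,
                     params = simulation_params(seed = 42),
                     run_duration_s = 240)
  })
}

small_subject_features <- function() {
  cache_get("small_subject_features", function() {
    subj <- small_subject()
    sf <- suppressMessages(
      extract_subject_features(subj$sessions, subj$mesh, fwhm_mm = 6,
                               K_base = 120))
    preprocess_subject_features(sf)
  })
}

small_samples <- function(BS = 5) {
  cache_get(paste0("small_samples_BS", BS), function() {
    assemble_samples(small_subject_features(), BS = BS)
  })
}

# synthetic decodable samples without any imaging: label-driven features
# plus noise, grouped into reports of `block` samples
toy_samples <- function(n_reports = 40, n_features = 20, n_informative = 5,
                        noise = 0.3, block = 2, seed = 1) {
  n_informative <- min(n_informative, n_features)
  set.seed(seed)
  lab_rep <- sample(rep(1:8, length.out = n_reports))
  lab <- rep(lab_rep, each = block)
  n <- length(lab)
  X <- matrix(rnorm(n * n_features), n, n_features)
  for (j in seq_len(n_informative))
    X[, j] <- lab + rnorm(n, sd = noise)
  decoding_samples(X, lab, rep(seq_len(n_reports), each = block), BS = block)
}

# mid-scale demo subject for signal-recovery and leakage checks: icosphere
# k=3 (642 vertices), 2 sessions x 2 runs of 8 min, 600 patches (the same
# ~0.92 top-K ratio as 4700 of 5100 features)
acceptance_features <- function() {
  cache_get("acceptance_features", function() {
    subj <- simulate_subject(subdivision_level = 3, radius_mm = 20,
                             n_sessions = 2, n_runs = 2,
                             params = simulation_params(seed = 7),
                             run_duration_s = 480)
    sf <- suppressMessages(
      extract_subject_features(subj$sessions, subj$mesh, fwhm_mm = 6,
                               K_base = 600))
    preprocess_subject_features(sf)
  })
}

acceptance_samples <- function() {
  cache_get("acceptance_samples", function()
    assemble_samples(acceptance_features(), BS = 5))
}

# tiny subject generator used by the null-behavior and block-size checks
tiny_subject_samples <- function(seed, n_sessions = 1, n_runs = 2,
                                 effect_amplitude = 0.03, noise_sd = 0.02,
                                 BS = 5, highpass = FALSE) {
  subj <- simulate_subject(subdivision_level = 2, radius_mm = 12,
                           n_sessions = n_sessions, n_runs = n_runs,
                           params = simulation_params(
                             seed = seed, effect_amplitude = effect_amplitude,
                             noise_sd = noise_sd),
                           run_duration_s = 240)
  sf <- suppressMessages(
    extract_subject_features(subj$sessions, subj$mesh, fwhm_mm = 6,
                             K_base = 120))
  sf <- preprocess_subject_features(sf, highpass = highpass)
  if (length(BS) == 1) return(assemble_samples(sf, BS = BS))
  lapply(BS, function(b) assemble_samples(sf, BS = b))
}
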