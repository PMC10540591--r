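#' Simulation parameters for synthetic BOLD generation
#'
#' Parameterizes the statistical stand-in for variably stressful stimuli:
#' each of the 8 stress levels is assigned a smooth spatial activation map
#' over gray-matter voxels, with adjacent levels sharing correlated maps so
#' that neighboring levels are confusable and distant levels are not. This
#' ordinal structure is what makes RMSE a meaningful error metric for the
#' decoders: their mistakes are predominantly +/- 1 level.
#'
#' @param n_levels number of stress levels (fixed at 8).
#' @param effect_amplitude fractional BOLD signal change per unit activation
#'   (default 0.03, i.e. ~3 percent at the plateau of a sustained stimulus).
#' @param pattern_smoothness_mm FWHM of the spatial activation maps (default 6).
#' @param ordinal_overlap correlation between the spatial maps of adjacent
#'   levels, in [0, 1) (default 0.6; level pairs at distance d correlate
#'   ~ overlap^d).
#' @param noise_sd fractional standard deviation of the AR(1) voxel noise
#'   (default 0.02).
#' @param ar1_coef lag-1 autocorrelation of the voxel noise, in [0, 1)
#'   (default 0.3).
#' @param drift_amplitude fractional amplitude of the per-run slow drift
#'   (linear plus half-cosine; default 0.01).
#' @param baseline_intensity mean image intensity (default 1000).
#' @param voxel_size_mm isotropic voxel edge (default 2).
#' @param gm_thickness_mm voxels whose center lies within this distance of
#'   the mesh carry stimulus signal (default 2).
#' @param ramp_frames_per_level emotional-inertia time constant: the
#'   internal stress state steps one level toward the current clip's target
#'   every this many frames (default 2, i.e. 3 s per level at TR 1.5 s);
#'   0 makes the state jump instantaneously with the clip.
#' @param motion_amplitude fractional amplitude of additive motion artifacts
#'   driven by 6 smooth motion traces (default 0 = off).
#' @param button_amplitude fractional amplitude of an additive button-press
#'   artifact (HRF-convolved stick at each report cue; default 0 = off).
#' @param seed integer seed; identical seeds reproduce outputs bit-for-bit.
#' @return A `simulation_params` list.
#' @export
simulation_params <- function(n_levels = 8, effect_amplitude = 0.03,
                              pattern_smoothness_mm = 6, ordinal_overlap = 0.6,
                              noise_sd = 0.02, ar1_coef = 0.3,
                              drift_amplitude = 0.01,
                              baseline_intensity = 1000,
                              voxel_size_mm = 2, gm_thickness_mm = 2,
                              ramp_frames_per_level = 2,
                              motion_amplitude = 0, button_amplitude = 0,
                              seed = 1) {
  stopifnot(noise_sd >= 0, ordinal_overlap >= 0, ordinal_overlap < 1,
            ar1_coef >= 0, ar1_coef < 1, effect_amplitude >= 0,
            baseline_intensity > 0, n_levels == 8)
  structure(list(n_levels = as.integer(n_levels),
                 effect_amplitude = effect_amplitude,
                 pattern_smoothness_mm = pattern_smoothness_mm,
                 ordinal_overlap = ordinal_overlap, noise_sd = noise_sd,
                 ar1_coef = ar1_coef, drift_amplitude = drift_amplitude,
                 baseline_intensity = baseline_intensity,
                 voxel_size_mm = voxel_size_mm,
                 gm_thickness_mm = gm_thickness_mm,
                 ramp_frames_per_level = as.integer(ramp_frames_per_level),
                 motion_amplitude = motion_amplitude,
                 button_amplitude = button_amplitude,
                 seed = as.integer(seed)),
            class = "simulation_params")
}

# Circular FFT smoothing of a 3D array with an isotropic Gaussian kernel.
gaussian_smooth_3d <- function(arr, sigma_vox) {
  if (sigma_vox <= 0) return(arr)
  dims <- dim(arr)
  k1 <- function(n) {
    x <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    w <- exp(-x^2 / (2 * sigma_vox^2))
    w / sum(w)
  }
  K <- outer(outer(k1(dims[1]), k1(dims[2])), k1(dims[3]))
  dim(K) <- dims
  Re(stats::fft(stats::fft(arr) * stats::fft(K), inverse = TRUE)) /
    prod(dims)
}

# Frame-level stimulus level for one run (level active at each frame's
# mid-acquisition time).
frame_levels <- function(clips, n_frames, TR_s) {
  mid <- (seq_len(n_frames) - 0.5) * TR_s
  clips$level[findInterval(mid, clips$onset_s)]
}

# Internal stress state: steps one level toward the current clip's target
# every `ramp_frames_per_level` frames (emotional inertia -- a subject
# shown a much more stressful scene passes through intermediate levels
# rather than jumping). ramp = 0 reproduces the instantaneous boxcar.
frame_states <- function(target, ramp_frames_per_level) {
  if (ramp_frames_per_level <= 0) return(target)
  state <- integer(length(target))
  state[1] <- target[1]
  hold <- 0
  for (t in 2:length(target)) {
    if (state[t - 1] == target[t]) {
      state[t] <- state[t - 1]; hold <- 0
    } else {
      hold <- hold + 1
      if (hold >= ramp_frames_per_level) {
        state[t] <- state[t - 1] + sign(target[t] - state[t - 1]); hold <- 0
      } else state[t] <- state[t - 1]
    }
  }
  state
}

# Six smooth motion traces (integrated white noise, lightly low-passed) and
# one HRF-convolved button-press stick train. Columns are unit-variance.
make_nuisance_traces <- function(n_frames, frames_per_report, hrf) {
  motion <- vapply(1:6, function(j) {
    x <- cumsum(stats::rnorm(n_frames))
    x <- stats::filter(c(rep(x[1], 4), x, rep(x[n_frames], 4)),
                       rep(1 / 5, 5), sides = 2)[5:(n_frames + 4)]
    as.numeric(scale(x))
  }, numeric(n_frames))
  stick <- numeric(n_frames)
  stick[seq(frames_per_report, n_frames, by = frames_per_report)] <- 1
  button <- convolve_hrf(stick, hrf)
  button <- button / stats::sd(button)
  m <- cbind(motion, button)
  colnames(m) <- c(paste0("motion", 1:6), "button")
  m
}

#' Simulate a session of 4D BOLD runs with ordinal stress encoding
#'
#' Voxels whose centers lie near the mesh surface (the gray-matter shell)
#' carry stimulus signal; all voxels carry baseline, AR(1) noise and slow
#' drift. The signal model per gray-matter voxel is
#' `baseline * (1 + effect_amplitude * sum_l beta(voxel, l) * (boxcar_l * hrf)(t))`,
#' where the per-level spatial maps `beta` are smooth unit-variance random
#' fields built as a level-wise AR(1) chain so that
#' `cor(beta_l, beta_{l+1}) ~ ordinal_overlap`.
#'
#' @param mesh a [cortical_mesh]; the voxel grid is derived from its
#'   bounding box plus a margin.
#' @param design a [make_session_design] result (one session).
#' @param params a [simulation_params] list.
#' @param hrf an [double_gamma_hrf] kernel (default: double-gamma at the
#'   design's TR).
#' @param session session index recorded in the label schedule.
#' @param margin_mm grid margin beyond the mesh bounding box (default 6).
#' @return A list of class `bold_simulation`:
#'   `runs` (list of `volume_ts`: 4D array `data`, 4x4 `affine`, `TR_s`),
#'   `labels` (a `label_schedule`), `beta_maps` (matrix gm-voxel x level),
#'   `gm_mask` (logical 3D array), `nuisance` (per-run frames x 7 matrix of
#'   motion and button traces), `params`.
#' @export
simulate_bold <- function(mesh, design, params = simulation_params(),
                          hrf = double_gamma_hrf(design$TR_s),
                          session = 1L, margin_mm = 6) {
  vox <- params$voxel_size_mm
  lo <- apply(mesh$vertices, 2, min) - margin_mm
  hi <- apply(mesh$vertices, 2, max) + margin_mm
  dims <- as.integer(ceiling((hi - lo) / vox)) + 1L
  origin <- lo
  affine <- diag(4)
  affine[1:3, 1:3] <- diag(rep(vox, 3))
  affine[1:3, 4] <- origin

  # voxel centers in world mm; gray-matter shell = near any mesh vertex
  cx <- origin[1] + (0:(dims[1] - 1)) * vox
  cy <- origin[2] + (0:(dims[2] - 1)) * vox
  cz <- origin[3] + (0:(dims[3] - 1)) * vox
  centers <- as.matrix(expand.grid(x = cx, y = cy, z = cz))
  nvox <- nrow(centers)
  v2 <- rowSums(mesh$vertices^2)
  mind2 <- rep(Inf, nvox)
  chunk <- 4096L
  for (s in seq(1, nvox, by = chunk)) {
    e <- min(s + chunk - 1L, nvox)
    d2 <- outer(rowSums(centers[s:e, , drop = FALSE]^2), v2, "+") -
      2 * centers[s:e, , drop = FALSE] %*% t(mesh$vertices)
    mind2[s:e] <- pmin(mind2[s:e], apply(d2, 1, min))
  }
  gm <- mind2 <= params$gm_thickness_mm^2
  gm_mask <- array(gm, dim = dims)

  n_frames <- design$n_frames_per_run
  n_runs <- length(design$runs)
  base <- params$baseline_intensity

  # per-level spatial maps are the subject's stable stress encoding: they
  # depend on params$seed only, so repeat sessions share the same maps
  beta <- with_seed(params$seed, {
    sigma_vox <- params$pattern_smoothness_mm / (2 * sqrt(2 * log(2))) / vox
    std_field <- function() {
      f <- gaussian_smooth_3d(array(stats::rnorm(nvox), dim = dims), sigma_vox)
      f <- as.numeric(f)[gm]
      (f - mean(f)) / stats::sd(f)
    }
    rho <- params$ordinal_overlap
    b <- matrix(0, nrow = sum(gm), ncol = params$n_levels)
    b[, 1] <- std_field()
    for (l in 2:params$n_levels) {
      g <- std_field()
      # empirical orthogonalization makes cor(b_l, b_{l+1}) exactly rho
      r <- stats::cor(g, b[, l - 1])
      g <- (g - r * b[, l - 1]) / sqrt(1 - r^2)
      g <- (g - mean(g)) / stats::sd(g)
      b[, l] <- rho * b[, l - 1] + sqrt(1 - rho^2) * g
    }
    b
  })

  # noise, drift and artifacts get a session-specific stream
  with_seed(params$seed + 100003L * as.integer(session), {
    runs <- vector("list", n_runs)
    nuisance <- vector("list", n_runs)
    reported <- vector("list", n_runs)
    fpr <- design$frames_per_report
    for (r in seq_len(n_runs)) {
      lev <- frame_states(frame_levels(design$runs[[r]], n_frames,
                                       design$TR_s),
                          params$ramp_frames_per_level)
      # HRF-convolved per-level boxcars (one boxcar per occupied level)
      act <- vapply(seq_len(params$n_levels), function(l)
        convolve_hrf(as.numeric(lev == l), hrf), numeric(n_frames))
      # the simulated self-report: the level whose hemodynamic response
      # dominates the preceding report window (at clip transitions the
      # previous clip's response still prevails, as it would for a subject
      # reporting the stress they felt over those 15 s)
      reported[[r]] <- vapply(seq_len(n_frames %/% fpr), function(i) {
        win <- ((i - 1) * fpr + 1):(i * fpr)
        which.max(colMeans(act[win, , drop = FALSE]))
      }, integer(1))
      # signal: gm voxels only
      dat <- matrix(base, nrow = nvox, ncol = n_frames)
      if (params$effect_amplitude > 0)
        dat[gm, ] <- base * (1 + params$effect_amplitude * beta %*% t(act))
      # AR(1) noise, stationary sd = noise_sd * baseline, all voxels
      if (params$noise_sd > 0) {
        sd_n <- params$noise_sd * base
        e <- stats::rnorm(nvox, sd = sd_n)
        dat[, 1] <- dat[, 1] + e
        innov_sd <- sd_n * sqrt(1 - params$ar1_coef^2)
        for (t in 2:n_frames) {
          e <- params$ar1_coef * e + stats::rnorm(nvox, sd = innov_sd)
          dat[, t] <- dat[, t] + e
        }
      }
      # slow drift: per-voxel random mix of linear and half-cosine
      if (params$drift_amplitude > 0) {
        tt <- seq_len(n_frames)
        b1 <- (tt - mean(tt)) / (n_frames - 1)            # linear, range 1
        b2 <- cos(pi * (tt - 0.5) / n_frames)             # half cosine
        cf <- matrix(stats::runif(2 * nvox, -1, 1), ncol = 2)
        dat <- dat + (params$drift_amplitude * base) * (cf %*% rbind(b1, b2))
      }
      nuis <- make_nuisance_traces(n_frames, design$frames_per_report, hrf)
      if (params$motion_amplitude > 0) {
        w <- matrix(stats::rnorm(nvox * 6, sd = params$motion_amplitude * base),
                    ncol = 6)
        dat <- dat + w %*% t(nuis[, 1:6])
      }
      if (params$button_amplitude > 0) {
        w <- stats::rnorm(nvox, sd = params$button_amplitude * base)
        dat <- dat + outer(w, nuis[, "button"])
      }
      dim(dat) <- c(dims, n_frames)
      runs[[r]] <- structure(list(data = dat, affine = affine,
                                  TR_s = design$TR_s),
                             class = "volume_ts")
      nuisance[[r]] <- nuis
    }
    # labels table rows are ordered by (run, report_index), matching the
    # concatenation order of `reported`
    labels <- design_label_schedule(design, session = session)
    labels$stress_level <- unlist(reported)
    structure(list(runs = runs, labels = labels,
                   beta_maps = beta, gm_mask = gm_mask, nuisance = nuisance,
                   params = params, design = design),
              class = "bold_simulation")
  })
}

#' Write a simulated run as NIfTI-1
#'
#' @param vol a `volume_ts` (from [simulate_bold]).
#' @param path output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_bold_nifti <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  vox <- vol$affine[1, 1]
  RNifti::pixdim(img) <- c(rep(vox, 3), vol$TR_s)
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 4D BOLD NIfTI into a `volume_ts`
#'
#' @param path NIfTI file path.
#' @param TR_s repetition time override; default taken from the header.
#' @return A `volume_ts` list: `data`, `affine`, `TR_s`.
#' @export
read_bold_nifti <- function(path, TR_s = NULL) {
  img <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(img))
  if (is.null(TR_s)) TR_s <- RNifti::pixdim(img)[4]
  structure(list(data = array(as.numeric(img), dim = dim(img)),
                 affine = aff, TR_s = TR_s),
            class = "volume_ts")
}
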