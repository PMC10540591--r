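# small geometry shared within this file
sim_mesh <- function() cache_get("sim_mesh_k2", function()
  make_synthetic_mesh(2, radius_mm = 12))
sim_design <- function() cache_get("sim_design_2x120", function()
  make_session_design(n_runs = 1, seed = 5, run_duration_s = 120))

test_that("pure-baseline simulation is constant at the baseline intensity", {
  p <- simulation_params(effect_amplitude = 0, noise_sd = 0,
                         drift_amplitude = 0, seed = 3)
  sim <- simulate_bold(sim_mesh(), sim_design(), p)
  expect_true(all(sim$runs[[1]]$data == p$baseline_intensity))
})

test_that("identical seeds reproduce the 4D data bit for bit", {
  p <- simulation_params(seed = 9)
  s1 <- simulate_bold(sim_mesh(), sim_design(), p)
  s2 <- simulate_bold(sim_mesh(), sim_design(), p)
  expect_identical(s1$runs[[1]]$data, s2$runs[[1]]$data)
  s3 <- simulate_bold(sim_mesh(), sim_design(), simulation_params(seed = 10))
  expect_false(identical(s1$runs[[1]]$data, s3$runs[[1]]$data))
})

test_that("adjacent-level spatial maps correlate at the requested overlap", {
  p <- simulation_params(ordinal_overlap = 0.6, seed = 21)
  sim <- simulate_bold(sim_mesh(), sim_design(), p)
  expect_gte(nrow(sim$beta_maps), 500)   # enough gray-matter voxels
  cc <- vapply(1:7, function(l)
    cor(sim$beta_maps[, l], sim$beta_maps[, l + 1]), numeric(1))
  expect_true(all(abs(cc - 0.6) <= 0.1))
  # distant levels decorrelate: |cor| well below the adjacent overlap
  far <- cor(sim$beta_maps[, 1], sim$beta_maps[, 8])
  expect_lt(abs(far), 0.35)
})

test_that("sessions share the spatial encoding but not the noise", {
  p <- simulation_params(seed = 4)
  s1 <- simulate_bold(sim_mesh(), sim_design(), p, session = 1)
  s2 <- simulate_bold(sim_mesh(), sim_design(), p, session = 2)
  expect_identical(s1$beta_maps, s2$beta_maps)
  expect_false(identical(s1$runs[[1]]$data, s2$runs[[1]]$data))
})

test_that("label schedule matches the frames-per-report accounting", {
  sim <- simulate_bold(sim_mesh(), sim_design(),
                       simulation_params(seed = 2))
  n_frames <- dim(sim$runs[[1]]$data)[4]
  expect_equal(nrow(sim$labels) * 10, n_frames)
  expect_true(all(sim$labels$stress_level %in% 1:8))
})

test_that("nuisance traces have the documented layout", {
  sim <- simulate_bold(sim_mesh(), sim_design(), simulation_params(seed = 2))
  nu <- sim$nuisance[[1]]
  expect_equal(dim(nu), c(80, 7))
  expect_equal(colnames(nu), c(paste0("motion", 1:6), "button"))
  expect_true(all(abs(apply(nu, 2, sd) - 1) < 1e-6))
})

test_that("NIfTI round trip preserves data, affine and TR", {
  sim <- simulate_bold(sim_mesh(), sim_design(), simulation_params(seed = 2))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_bold_nifti(sim$runs[[1]], path)
  vol <- read_bold_nifti(path)
  expect_equal(vol$data, sim$runs[[1]]$data, ignore_attr = TRUE)
  expect_equal(vol$affine, sim$runs[[1]]$affine, ignore_attr = TRUE)
  expect_equal(vol$TR_s, 1.5)
})
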