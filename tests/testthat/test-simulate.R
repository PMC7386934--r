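test_that("a silent phantom produces constant voxel time series", {
  atlas <- mini_atlas()
  protocol <- mini_protocol()
  truth <- ground_truth(atlas, amplitude = 0, center_z = 6, z_halfwidth = 3L)
  run <- simulate_run(atlas, protocol, truth, noise = noise_off(), seed = 1)
  v <- apply(run$data, 4, identity)
  expect_equal(max(abs(run$data - c(run$baseline_map))), 0)
})

test_that("the injected plateau matches the closed-form fractional change", {
  atlas <- mini_atlas()
  protocol <- mini_protocol()
  truth <- ground_truth(atlas, amplitude = 0.71, center_z = 6,
                        z_halfwidth = 3L)
  run <- simulate_run(atlas, protocol, truth, noise = noise_off(), seed = 1)
  idx <- which(truth$mask_left & !truth$mask_right)
  # oracle from the generator's own equation: peak fractional change is
  # amplitude/100 at the maximum of the normalized side regressor (= 1)
  for (v in idx[c(1, length(idx))]) {
    ijk <- arrayInd(v, atlas$dim)
    ts <- run$data[ijk[1], ijk[2], ijk[3], ]
    b <- run$baseline_map[v]
    expect_equal((max(ts) - b) / b, 0.0071, tolerance = 1e-9)
  }
})

test_that("runs are bit-identical under a fixed seed", {
  atlas <- mini_atlas()
  protocol <- mini_protocol()
  truth <- ground_truth(atlas, center_z = 6, z_halfwidth = 3L)
  r1 <- simulate_run(atlas, protocol, truth, seed = 5)
  r2 <- simulate_run(atlas, protocol, truth, seed = 5)
  expect_identical(r1$data, r2$data)
  expect_identical(r1$motion_params, r2$motion_params)
  r3 <- simulate_run(atlas, protocol, truth, seed = 6)
  expect_false(identical(r1$data, r3$data))
})

test_that("simulation does not disturb the caller's RNG stream", {
  atlas <- mini_atlas()
  protocol <- mini_protocol()
  truth <- ground_truth(atlas, center_z = 6, z_halfwidth = 3L)
  set.seed(123)
  a <- rnorm(3)
  set.seed(123)
  invisible(simulate_run(atlas, protocol, truth, seed = 5))
  b <- rnorm(3)
  expect_identical(a, b)
})

test_that("truth compartments must match the atlas grid", {
  atlas <- mini_atlas()
  other <- build_atlas(cord_phantom_spec(grid_shape = c(20L, 20L, 12L),
                                         n_volumes = 90L))
  truth <- ground_truth(other)
  expect_error(simulate_run(atlas, mini_protocol(), truth), "grid")
})

test_that("spike volumes offset whole volumes for DVARS to find", {
  atlas <- mini_atlas()
  protocol <- mini_protocol()
  truth <- ground_truth(atlas, amplitude = 0, center_z = 6, z_halfwidth = 3L)
  nz <- noise_spec(white_sd = 0.5, cardiac_pct = 0, resp_pct = 0,
                   drift_pct = 0, spike_volumes = 20L, spike_pct = 2)
  run <- simulate_run(atlas, protocol, truth, noise = nz, seed = 2)
  dv <- dvars_outliers(run$data, atlas$masks$cord)
  expect_true(all(c(20L, 21L) %in% dv$flags))
})

test_that("cohorts record per-subject truth and regenerate identically", {
  atlas <- mini_atlas()
  protocol <- mini_protocol()
  co <- generate_cohort(n_subjects = 24L, atlas = atlas,
                        protocol = protocol, lr_mean = 0.3, seed = 7)
  expect_equal(nrow(co$manifest), 24)
  expect_true(all(is.finite(co$manifest$true_lr_index)))
  expect_gt(mean(co$manifest$true_lr_index), 0)
  co2 <- generate_cohort(n_subjects = 24L, atlas = atlas,
                         protocol = protocol, lr_mean = 0.3, seed = 7)
  expect_identical(co$manifest, co2$manifest)
  # zero between-subject variance: identical subjects
  cz <- generate_cohort(n_subjects = 2L, atlas = atlas, protocol = protocol,
                        amplitude_sd = 0, lr_sd = 0, dv_sd = 0, cog_sd_z = 0,
                        seed = 1)
  expect_equal(cz$manifest$amplitude[1], cz$manifest$amplitude[2])
  expect_equal(cz$manifest$true_lr_index[1], cz$manifest$true_lr_index[2])
  expect_error(generate_cohort(n_subjects = 1L, atlas = atlas,
                               protocol = protocol), "at least 2")
})

test_that("a cohort written to disk has a stable manifest hash", {
  atlas <- build_atlas(cord_phantom_spec(grid_shape = c(12L, 12L, 6L),
                                         cord_radii = c(3.5, 3),
                                         segment_z_bounds = list(
                                           C5 = c(5, 6), C6 = c(3, 4),
                                           C7 = c(1, 2)),
                                         n_volumes = 45L))
  protocol <- generate_protocol(n_trials = 1L, block_s = 10, tr = 2,
                                seed = 1)
  co <- generate_cohort(n_subjects = 2L, atlas = atlas, protocol = protocol,
                        seed = 3)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(co, d1)
  write_cohort(co, d2)
  h1 <- unname(tools::md5sum(file.path(d1, "manifest.json")))
  h2 <- unname(tools::md5sum(file.path(d2, "manifest.json")))
  expect_identical(h1, h2)
  expect_true(file.exists(file.path(d1, "sub-01", "bold.nii.gz")))
  expect_true(file.exists(file.path(d1, "sub-01", "truth.json")))
  expect_true(file.exists(file.path(d1, "atlas", "mask_cord.nii.gz")))
  # the written BOLD round-trips through NIfTI
  img <- RNifti::readNifti(file.path(d1, "sub-01", "bold.nii.gz"))
  run <- subject_run(co, 1)
  expect_equal(dim(img), dim(run$data))
  expect_equal(max(abs(img - run$data)), 0, tolerance = 1e-6)
})

test_that("ground truth realizes its target laterality closely", {
  atlas <- build_atlas()
  for (lr in c(-0.5, 0, 0.3, 0.8)) {
    tr <- ground_truth(atlas, lr_index = lr)
    expect_lt(abs(tr$lr_index - lr), 0.08)
  }
  t1 <- ground_truth(atlas, lr_index = 1)
  expect_equal(t1$lr_index, 1)
})
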