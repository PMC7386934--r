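test_that("cardiac phase follows the within-cycle time fraction", {
  # constant-period 1 Hz cardiac trace
  ph <- simulate_physio(100, cardiac_rate_hz = 1, rate_jitter = 0, seed = 1)
  # three slices acquired at the peak, a quarter cycle, and mid-cycle
  pa <- assign_phases(ph, slice_times = c(0, 0.25, 0.5), tr = 2,
                      n_volumes = 40)
  expect_equal(pa$cardiac[1, ], rep(0, 40))
  expect_equal(pa$cardiac[2, ], rep(pi / 2, 40))
  expect_equal(pa$cardiac[3, ], rep(pi, 40))
})

test_that("phases are refused outside trace coverage", {
  ph <- simulate_physio(50, seed = 1)
  expect_error(assign_phases(ph, slice_times = c(0, 1), tr = 2,
                             n_volumes = 40), "coverage")
})

test_that("RETROICOR basis has 16 harmonic and 16 interaction columns", {
  ph <- simulate_physio(100, seed = 2)
  pa <- assign_phases(ph, slice_times = c(0, 0.5), tr = 2, n_volumes = 40)
  pb <- physio_basis(pa)
  expect_length(pb, 2)
  expect_equal(ncol(pb[[1]]), 32)
  expect_equal(sum(grepl("^(card|resp)_", colnames(pb[[1]]))), 16)
  expect_equal(sum(grepl("^int_", colnames(pb[[1]]))), 16)
})

test_that("zero phases give zero sine and unit cosine columns", {
  ph <- simulate_physio(100, seed = 2)
  pa <- assign_phases(ph, slice_times = 0, tr = 2, n_volumes = 40)
  pa$cardiac[] <- 0
  pa$respiratory[] <- 0
  pb <- physio_basis(pa)[[1]]
  sines <- grepl("sin", colnames(pb))
  expect_true(all(pb[, sines] == 0))
  expect_true(all(pb[, !sines] == 1))
})

test_that("CSF PCA recovers a shared canal time course", {
  set.seed(42)
  d <- c(8, 8, 2, 60)
  canal <- array(FALSE, d[1:3]); canal[3:6, 3:6, ] <- TRUE
  common <- sin(seq_len(d[4]) / 3)
  bold <- array(rnorm(prod(d), sd = 0.1), dim = d)
  for (s in 1:2) for (t in seq_len(d[4]))
    bold[, , s, t] <- bold[, , s, t] + canal[, , s] * common[t]
  cs <- csf_pca(bold, canal, n_comp = 5)
  expect_length(cs, 2)
  expect_equal(ncol(cs[[1]]), 5)
  expect_gt(abs(cor(cs[[1]][, 1], common)), 0.99)
  # orthogonality and unit norm
  g <- crossprod(cs[[1]])
  expect_equal(g, diag(5), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("slices with too few canal voxels reduce rank with a warning", {
  set.seed(1)
  d <- c(6, 6, 1, 30)
  canal <- array(FALSE, d[1:3]); canal[1:3, 1, 1] <- TRUE  # 3 voxels
  bold <- array(rnorm(prod(d)), dim = d)
  expect_warning(cs <- csf_pca(bold, canal, n_comp = 5), "reduced-rank")
  expect_equal(ncol(cs[[1]]), 3)
})

test_that("DVARS flags both volumes adjacent to a spike", {
  set.seed(7)
  d <- c(6, 6, 4, 200)
  mask <- array(TRUE, d[1:3])
  bold <- array(rnorm(prod(d)), dim = d)
  bold[, , , 100] <- bold[, , , 100] + 10
  dv <- dvars_outliers(bold, mask)
  expect_setequal(dv$flags, c(100L, 101L))
  # constant series: all-zero DVARS, no flags
  cz <- array(5, dim = d)
  dvz <- dvars_outliers(cz, mask)
  expect_true(all(dvz$dvars[-1] == 0))
  expect_length(dvz$flags, 0)
})

test_that("DVARS flags are scale- and offset-invariant", {
  set.seed(8)
  d <- c(5, 5, 3, 150)
  mask <- array(TRUE, d[1:3])
  bold <- array(rnorm(prod(d)), dim = d)
  bold[, , , c(40, 90)] <- bold[, , , c(40, 90)] + 8
  dv1 <- dvars_outliers(bold, mask)
  dv2 <- dvars_outliers(bold * 3 + 100, mask)
  expect_identical(dv1$flags, dv2$flags)
  expect_equal(dv2$dvars[-1], 3 * dv1$dvars[-1], tolerance = 1e-12)
})

test_that("high-pass keeps fast components, removes slow ones, preserves the mean", {
  tr <- 2; n <- 450
  t_s <- (seq_len(n) - 0.5) * tr
  const <- rep(4, n)
  expect_equal(highpass(const, 100, tr), const)
  fast <- sin(2 * pi * t_s / 50)
  slow <- sin(2 * pi * t_s / 400)
  hf <- highpass(fast, 100, tr)
  hs <- highpass(slow, 100, tr)
  amp <- function(x) sqrt(mean((x - mean(x))^2))   # oscillation RMS
  expect_gt(amp(hf) / amp(fast), 0.9)
  expect_lt(amp(hs) / amp(slow), 0.1)
  expect_equal(mean(hf), mean(fast), tolerance = 1e-10)
  expect_equal(mean(hs), mean(slow), tolerance = 1e-10)
})

test_that("nuisance regression removes exact and leaves orthogonal signals", {
  set.seed(3)
  d <- c(4, 4, 1, 80)
  mask <- array(TRUE, d[1:3])
  N <- cbind(sin(1:80 / 5), cos(1:80 / 7))
  bold <- array(0, dim = d)
  bold[1, 1, 1, ] <- 10 + 3 * N[, 1]          # exactly a nuisance column
  orth <- rnorm(80)
  orth <- as.numeric(residuals(lm(orth ~ N)))  # orthogonal to the block
  bold[2, 2, 1, ] <- 5 + orth
  out <- regress_nuisance(bold, list(N), mask)
  # a pure nuisance signal flattens to its own mean
  expect_equal(out[1, 1, 1, ], rep(mean(bold[1, 1, 1, ]), 80),
               tolerance = 1e-8)
  expect_equal(out[2, 2, 1, ], 5 + orth, tolerance = 1e-8)
})

test_that("phase-locked cardiac contamination is removed by its own basis", {
  atlas <- mini_atlas()
  protocol <- mini_protocol()
  truth <- ground_truth(atlas, amplitude = 0, center_z = 6, z_halfwidth = 3L)
  nz <- noise_spec(white_sd = 0.5, cardiac_pct = 1, resp_pct = 0.5,
                   drift_pct = 0, n_spikes = 0L)
  run <- simulate_run(atlas, protocol, truth, noise = nz, seed = 4)
  pa <- assign_phases(run$physio, run$slice_times, run$tr,
                      protocol$n_volumes)
  pb <- physio_basis(pa)
  out <- regress_nuisance(run$data, pb, atlas$masks$cord)
  # cardiac-band power at a mid-cord voxel before vs after
  v <- which(atlas$masks$cord & truth$mask_left, arr.ind = TRUE)[1, ]
  before <- run$data[v[1], v[2], v[3], ]
  after <- out[v[1], v[2], v[3], ]
  bandpow <- function(x, basis) {
    b <- qr.Q(qr(basis))
    sum((crossprod(b, x - mean(x)))^2)
  }
  basis <- pb[[v[3]]][, 1:8]                  # cardiac harmonics this slice
  expect_lt(bandpow(after, basis) / bandpow(before, basis), 0.05)
})

test_that("masked smoothing preserves uniform fields and raises TSNR", {
  atlas <- mini_atlas()
  mask <- atlas$masks$cord
  d <- c(atlas$dim, 3L)
  uni <- array(7, dim = d)
  sm <- smooth_bold(uni, mask, 2, atlas$voxel_size)
  expect_equal(sm, uni, tolerance = 1e-10)
  set.seed(5)
  noisy <- array(100 + rnorm(prod(c(atlas$dim, 40))), dim = c(atlas$dim, 40))
  t1 <- tsnr_map(noisy, mask)$mean_tsnr
  t2 <- tsnr_map(smooth_bold(noisy, mask, 2, atlas$voxel_size),
                 mask)$mean_tsnr
  expect_gt(t2, t1)
})

test_that("impulse response has ~2 mm in-plane full width at half maximum", {
  d3 <- c(21, 21, 3)
  mask <- array(TRUE, d3)
  imp <- array(0, dim = d3)
  imp[11, 11, 2] <- 1
  sm <- smooth_bold(imp, mask, 2, voxel_size = c(1, 1, 3))
  prof <- sm[, 11, 2] / max(sm[, 11, 2])
  # half-maximum crossings by linear interpolation, in voxel (= mm) units
  above <- which(prof >= 0.5)
  lo <- min(above); hi <- max(above)
  xlo <- lo - 1 + (0.5 - prof[lo - 1]) / (prof[lo] - prof[lo - 1])
  xhi <- hi + (prof[hi] - 0.5) / (prof[hi] - prof[hi + 1])
  expect_equal(xhi - xlo, 2, tolerance = 0.35)
})

test_that("TSNR reflects the mean/SD ratio and scales with noise", {
  set.seed(6)
  d <- c(6, 6, 2, 200)
  mask <- array(TRUE, d[1:3])
  bold <- array(100 + rnorm(prod(d), sd = 4), dim = d)
  ts <- tsnr_map(bold, mask)
  expect_equal(ts$mean_tsnr, 25, tolerance = 1.5)
  bold2 <- array(100 + rnorm(prod(d), sd = 8), dim = d)
  ts2 <- tsnr_map(bold2, mask)
  expect_equal(ts$mean_tsnr / ts2$mean_tsnr, 2, tolerance = 0.15)
  # noiseless voxels are excluded and counted
  boldz <- bold; boldz[1, 1, 1, ] <- 50
  tsz <- tsnr_map(boldz, mask)
  expect_equal(tsz$n_excluded, 1)
})

test_that("slice-timing correction aligns a linear ramp exactly", {
  # for a linear-in-time signal, linear interpolation to midpoint is exact
  d <- c(2, 2, 4, 30)
  st <- interleaved_slice_times(4, tr = 2)
  bold <- array(0, dim = d)
  for (s in 1:4) for (v in 1:30)
    bold[, , s, v] <- 5 * ((v - 1) * 2 + st[s])     # value = 5 * acq time
  out <- slice_timing_correct(bold, st, tr = 2)
  mid <- 5 * ((seq_len(30) - 0.5) * 2)
  for (s in 1:4)
    expect_equal(out[1, 1, s, 2:29], mid[2:29], tolerance = 1e-9)
})
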