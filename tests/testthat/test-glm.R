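# A tiny design shared by the GLM unit tests: 2 trials, 45 volumes.
glm_fixture <- function(seed = 1) {
  protocol <- mini_protocol(seed = seed)
  design <- build_design(protocol)
  list(protocol = protocol, design = design)
}

test_that("with white noise the prewhitened fit matches plain OLS", {
  fx <- glm_fixture()
  set.seed(10)
  d <- c(3, 3, 1, fx$protocol$n_volumes)
  mask <- array(TRUE, d[1:3])
  X <- fx$design$X
  bold <- array(rnorm(prod(d), sd = 0.05), dim = d)
  bold[1, 1, 1, ] <- bold[1, 1, 1, ] + 100 + 2 * X[, 1]
  fit_w <- cord_glm(bold, fx$design, mask, prewhiten = TRUE)
  fit_o <- cord_glm(bold, fx$design, mask, prewhiten = FALSE)
  expect_equal(fit_w$betas, fit_o$betas, tolerance = 1e-2)
  # near-noiseless regression recovers the injected coefficient
  expect_equal(unname(fit_o$betas["L01", 1]), 2, tolerance = 1e-2)
})

test_that("prewhitened fit equals the generalized least squares oracle", {
  # brute-force GLS on a 5-voxel, 60-volume instance: build Sigma^-1 from
  # the fitted AR coefficient and solve the normal equations directly
  p <- generate_protocol(n_trials = 2L, seed = 2)          # 90 volumes
  design <- build_design(p)
  nv <- p$n_volumes
  set.seed(11)
  d <- c(5, 1, 1, nv)
  mask <- array(TRUE, d[1:3])
  ar <- 0.4
  noise <- replicate(5, as.numeric(arima.sim(list(ar = ar), nv, sd = 1)))
  bold <- array(0, dim = d)
  for (v in 1:5) bold[v, 1, 1, ] <- 100 + 1.5 * design$X[, 1] + noise[, v]
  fit <- cord_glm(bold, design, mask, rho_bin = 1e-9)  # no quantization
  Xi <- cbind(1, design$X)
  for (v in 1:5) {
    rho <- fit$rho[v]
    n <- nv
    # exact AR(1) inverse-covariance (tridiagonal), unit innovation scale
    Sinv <- diag(c(1, rep(1 + rho^2, n - 2), 1))
    for (i in 1:(n - 1)) {
      Sinv[i, i + 1] <- -rho
      Sinv[i + 1, i] <- -rho
    }
    y <- bold[v, 1, 1, ]
    beta_gls <- solve(t(Xi) %*% Sinv %*% Xi, t(Xi) %*% Sinv %*% y)
    expect_equal(unname(fit$betas[, v]), as.numeric(beta_gls),
                 tolerance = 1e-8)
  }
})

test_that("contrasts behave linearly and antisymmetrically", {
  fx <- glm_fixture()
  set.seed(12)
  d <- c(4, 4, 1, fx$protocol$n_volumes)
  mask <- array(TRUE, d[1:3])
  bold <- array(100 + rnorm(prod(d)), dim = d)
  fit <- cord_glm(bold, fx$design, mask)
  zl <- contrast_z(fit, contrast_spec(fx$design, "L>R"))
  zr <- contrast_z(fit, contrast_spec(fx$design, "R>L"))
  expect_equal(zl$cope, -zr$cope, tolerance = 1e-10)
  z0 <- contrast_z(fit, rep(0, ncol(fx$design$X)))
  expect_true(all(z0$cope[mask] == 0))
})

test_that("the L contrast peaks inside a left-only activation", {
  atlas <- mini_atlas()
  protocol <- mini_protocol()
  truth <- ground_truth(atlas, amplitude = 2, lr_index = 0.9,
                        center_z = 6, z_halfwidth = 3L)
  run <- simulate_run(atlas, protocol, truth,
                      noise = noise_spec(n_spikes = 0L), seed = 3)
  design <- build_design(protocol, motion_params = run$motion_params)
  fit <- cord_glm(run$data, design, atlas$masks$cord)
  sm <- contrast_z(fit, contrast_spec(design, "L"))
  peak <- which(sm$z == max(sm$z, na.rm = TRUE), arr.ind = TRUE)[1, ]
  expect_true(truth$mask_left[peak[1], peak[2], peak[3]])
})

test_that("fixed-effects combination has its closed forms", {
  mask <- array(TRUE, c(2, 2, 1))
  cope <- array(3, dim = c(2, 2, 1))
  var1 <- array(2, dim = c(2, 2, 1))
  fe <- fixed_effects(list(cope, cope), list(var1, var1), mask)
  expect_equal(fe$cope[mask], rep(3, 4))
  expect_equal(fe$varcope[mask], rep(1, 4))         # v / 2
  one <- fixed_effects(list(cope), list(var1), mask)
  expect_equal(one$cope, cope, ignore_attr = TRUE)
  expect_equal(one$varcope, var1, ignore_attr = TRUE)
  # equal variances reduce to the arithmetic mean
  cope2 <- array(5, dim = c(2, 2, 1))
  fe2 <- fixed_effects(list(cope, cope2), list(var1, var1), mask)
  expect_equal(fe2$cope[mask], rep(4, 4))
  # permutation invariance
  fe3 <- fixed_effects(list(cope2, cope), list(var1, var1), mask)
  expect_equal(fe3$cope, fe2$cope)
  # zero variance input errors
  expect_error(fixed_effects(list(cope, cope2),
                             list(var1, array(0, dim = c(2, 2, 1))), mask),
               "positive")
})

test_that("trialwise mean equals the blockwise estimate on noise-free data", {
  fx <- glm_fixture()
  nv <- fx$protocol$n_volumes
  d <- c(2, 2, 1, nv)
  mask <- array(TRUE, d[1:3])
  union_l <- rowSums(fx$design$X[, fx$design$left_cols])
  bold <- array(0, dim = d)
  for (i in 1:2) for (j in 1:2)
    bold[i, j, 1, ] <- 100 + 0.8 * union_l
  fit <- cord_glm(bold, fx$design, mask, prewhiten = FALSE)
  cm <- contrast_z(fit, contrast_spec(fx$design, "L"))
  expect_equal(cm$cope[mask], rep(0.8, 4), tolerance = 1e-6)
})

test_that("rank-deficient designs error with column names", {
  fx <- glm_fixture()
  bad <- fx$design
  bad$X <- cbind(bad$X, dupL01 = bad$X[, 1])
  d <- c(2, 1, 1, fx$protocol$n_volumes)
  bold <- array(rnorm(prod(d)), dim = d)
  expect_error(cord_glm(bold, bad, array(TRUE, d[1:3])), "dupL01|L01")
})

test_that("percent signal change round-trips a noise-free injection", {
  atlas <- mini_atlas()
  protocol <- mini_protocol()
  truth <- ground_truth(atlas, amplitude = 0.71, lr_index = 0,
                        center_z = 6, z_halfwidth = 3L)
  run <- simulate_run(atlas, protocol, truth, noise = noise_off(), seed = 9)
  design <- build_design(protocol, motion_params = run$motion_params)
  fit <- cord_glm(run$data, design, atlas$masks$cord, prewhiten = FALSE)
  sm <- contrast_z(fit, contrast_spec(design, "L"))
  psc <- percent_signal_change(sm, design, run$baseline_map)
  expect_equal(mean(psc$map[truth$mask_left]), 0.71, tolerance = 0.01)
  # doubling the injected amplitude doubles the recovered change
  truth2 <- ground_truth(atlas, amplitude = 1.42, lr_index = 0,
                         center_z = 6, z_halfwidth = 3L)
  run2 <- simulate_run(atlas, protocol, truth2, noise = noise_off(), seed = 9)
  fit2 <- cord_glm(run2$data, design, atlas$masks$cord, prewhiten = FALSE)
  psc2 <- percent_signal_change(contrast_z(fit2, contrast_spec(design, "L")),
                                design, run2$baseline_map)
  expect_equal(mean(psc2$map[truth2$mask_left]) /
                 mean(psc$map[truth$mask_left]), 2, tolerance = 1e-6)
  # a zero contrast gives zero percent change
  z0 <- contrast_z(fit, rep(0, ncol(design$X)))
  psc0 <- percent_signal_change(z0, design, run$baseline_map, side = "left")
  expect_true(all(psc0$map[atlas$masks$cord] == 0))
})

test_that("task-term injection is linear in amplitude (noise off)", {
  atlas <- mini_atlas()
  protocol <- mini_protocol()
  t1 <- ground_truth(atlas, amplitude = 0.5, center_z = 6, z_halfwidth = 3L)
  t2 <- ground_truth(atlas, amplitude = 1.0, center_z = 6, z_halfwidth = 3L)
  r1 <- simulate_run(atlas, protocol, t1, noise = noise_off(), seed = 1)
  r2 <- simulate_run(atlas, protocol, t2, noise = noise_off(), seed = 1)
  d1 <- r1$data - c(r1$baseline_map)
  d2 <- r2$data - c(r2$baseline_map)
  expect_equal(d2, 2 * d1, tolerance = 1e-10)
})
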