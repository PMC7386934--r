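test_that("compartment counts match a voxel-by-voxel oracle", {
  atlas <- build_atlas()
  set.seed(30)
  cord_idx <- which(atlas$masks$cord)
  pick <- sample(cord_idx, 100)
  am <- array(FALSE, atlas$dim); am[pick] <- TRUE
  cnt <- compartment_counts(am, atlas)
  # independent oracle: loop over voxels, look each one up in every mask
  oracle <- c(left = 0, right = 0, dorsal = 0, ventral = 0,
              C5 = 0, C6 = 0, C7 = 0, gm = 0, wm = 0, total = 0)
  keymap <- c(left = "left_hemicord", right = "right_hemicord",
              dorsal = "dorsal_hemicord", ventral = "ventral_hemicord",
              C5 = "C5", C6 = "C6", C7 = "C7", gm = "gm", wm = "wm")
  for (v in pick) {
    oracle["total"] <- oracle["total"] + 1
    for (k in names(keymap))
      if (atlas$masks[[keymap[k]]][v]) oracle[k] <- oracle[k] + 1
  }
  expect_equal(as.integer(cnt), as.integer(oracle[names(cnt)]))
})

test_that("count edge cases: empty mask, one whole hemicord, outside voxels", {
  atlas <- build_atlas()
  empty <- array(FALSE, atlas$dim)
  cnt <- compartment_counts(empty, atlas)
  expect_true(all(as.integer(cnt) == 0))
  cl <- compartment_counts(atlas$masks$left_hemicord, atlas)
  expect_equal(cl[["left"]], cl[["total"]])
  expect_equal(cl[["right"]], 0L)
  bad <- array(FALSE, atlas$dim); bad[1, 1, 1] <- TRUE  # outside cord
  expect_error(compartment_counts(bad, atlas), "outside")
})

test_that("laterality indices hit their definitional boundaries", {
  atlas <- build_atlas()
  li <- laterality_indices(compartment_counts(atlas$masks$left_hemicord,
                                              atlas))
  expect_equal(li[["lr_index"]], 1)
  vi <- laterality_indices(compartment_counts(atlas$masks$ventral_hemicord,
                                              atlas))
  expect_equal(vi[["dv_index"]], -1)
  # left = 30, right = 10 -> 0.5
  cnt <- structure(c(30L, 10L, 20L, 20L, 0L, 40L, 0L, 10L, 30L, 40L),
                   names = c("left", "right", "dorsal", "ventral",
                             "C5", "C6", "C7", "gm", "wm", "total"),
                   class = "activation_counts")
  expect_equal(laterality_indices(cnt)[["lr_index"]], 0.5)
  # no active voxels -> undefined
  zero <- compartment_counts(array(FALSE, atlas$dim), atlas)
  expect_message(res <- laterality_indices(zero), "undefined")
  expect_true(all(is.na(res)))
})

test_that("mirror reflection negates LR and preserves DV and COG", {
  atlas <- build_atlas()
  set.seed(31)
  am <- array(FALSE, atlas$dim)
  am[which(atlas$masks$cord)[sample(sum(atlas$masks$cord), 200)]] <- TRUE
  cnt <- compartment_counts(am, atlas)
  li <- laterality_indices(cnt)
  amr <- mirror_x(am)
  cntr <- compartment_counts(amr, atlas)
  lir <- laterality_indices(cntr)
  expect_equal(lir[["lr_index"]], -li[["lr_index"]])
  expect_equal(lir[["dv_index"]], li[["dv_index"]])
  expect_equal(cog_z(amr), cog_z(am))
})

test_that("indices are stable in expectation under voxel subsampling", {
  atlas <- build_atlas()
  truth <- ground_truth(atlas, lr_index = 0.4)
  cnt <- compartment_counts(truth$mask_left, atlas)
  li0 <- laterality_indices(cnt)[["lr_index"]]
  set.seed(32)
  idx <- which(truth$mask_left)
  sub_lr <- replicate(200, {
    keep <- idx[runif(length(idx)) < 0.5]
    am <- array(FALSE, atlas$dim); am[keep] <- TRUE
    laterality_indices(compartment_counts(am, atlas))[["lr_index"]]
  })
  expect_equal(mean(sub_lr), li0, tolerance = 0.02)
})

test_that("COG is the Z-weighted mean of active-voxel z coordinates", {
  dim3 <- c(4, 4, 60)
  mk <- function(zs, zvals) {
    z <- array(NA_real_, dim3)
    am <- array(FALSE, dim3)
    mask <- array(TRUE, dim3)
    for (i in seq_along(zs)) { am[1, 1, zs[i]] <- TRUE; z[1, 1, zs[i]] <- zvals[i] }
    structure(list(z = z, mask = mask, dim = dim3, active_mask = am),
              class = "stat_map")
  }
  expect_equal(cog_z(mk(40, 3)), 40)
  expect_equal(cog_z(mk(c(40, 50), c(2, 2))), 45)
  expect_equal(cog_z(mk(c(40, 50), c(2.4, 4.8))), 46.667, tolerance = 1e-3)
  expect_equal(cog_z(mk(c(40, 50), c(2.4, 4.8)), weighted = FALSE), 45)
  empty <- mk(40, 3); empty$active_mask[] <- FALSE
  expect_message(res <- cog_z(empty), "undefined")
  expect_true(is.na(res))
})

test_that("GM/WM ratio reproduces the printed percentage arithmetic", {
  expect_equal(round(activation_ratio(34.8, 24.9), 2), 1.40)
  expect_equal(round(activation_ratio(20.2, 17.1), 2), 1.18)
  atlas <- build_atlas()
  # uniform activation of the whole cord -> exactly 1
  full <- compartment_counts(atlas$masks$cord, atlas)
  expect_equal(gmwm_ratio(full, atlas), 1)
  # no WM activation -> undefined
  gm_only <- compartment_counts(atlas$masks$gm, atlas)
  expect_message(r <- gmwm_ratio(gm_only, atlas), "undefined")
  expect_true(is.na(r))
})

test_that("consistency maps count overlapping subjects", {
  atlas <- build_atlas()
  base <- atlas$masks$gm
  same <- replicate(24, base, simplify = FALSE)
  cm <- consistency_map(same)
  expect_equal(cm$max_overlap, 24)
  expect_equal(max(cm$overlap), 24)
  # disjoint masks never overlap
  a <- array(FALSE, atlas$dim); a[10, 10, 1] <- TRUE
  b <- array(FALSE, atlas$dim); b[10, 10, 2] <- TRUE
  expect_equal(consistency_map(list(a, b))$max_overlap, 1)
  expect_error(consistency_map(list(a, array(FALSE, c(2, 2, 2)))), "grid")
})

test_that("wilcoxon signed-rank: exact small-sample enumeration", {
  # six values all above the hypothesized median: one-sided 1/64 -> 1/32
  w <- wilcoxon_median(c(1.2, 0.8, 2.1, 1.7, 0.4, 3.0), 0)
  expect_equal(w$p, 1 / 32)
  expect_equal(w$method, "exact")
  expect_gt(w$z_stat, 0)
  # symmetric values around the median -> p near 1
  ws <- wilcoxon_median(c(-2, -1, -0.5, 0.5, 1, 2), 0)
  expect_gt(ws$p, 0.8)
  expect_error(wilcoxon_median(c(1, 1, 1), 1), "tie")
})

test_that("wilcoxon exact and normal paths agree on random data", {
  set.seed(33)
  for (i in 1:20) {
    x <- rnorm(12, mean = 0.4)
    we <- wilcoxon_median(x, 0, exact_max = 12)
    wn <- wilcoxon_median(x, 0, exact_max = 0)
    expect_lt(abs(we$p - wn$p), 0.02)
  }
})

test_that("wilcoxon agrees with the base implementation", {
  set.seed(34)
  x <- rnorm(30, 0.3)
  ours <- wilcoxon_median(x, 0, exact_max = 0)
  ref <- wilcox.test(x, mu = 0, exact = FALSE, correct = TRUE)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  xe <- rnorm(10, 0.3)
  oe <- wilcoxon_median(xe, 0)
  re <- wilcox.test(xe, mu = 0, exact = TRUE)
  expect_equal(oe$p, re$p.value, tolerance = 1e-10)
})

test_that("paired t and Pearson r match the textbook formulas", {
  a <- c(5.1, 6.2, 4.8, 7.0, 5.5)
  b <- c(4.9, 5.8, 5.1, 6.4, 5.2)
  pc <- paired_compare(a, b)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(pc$t, t_hand, tolerance = 1e-10)
  expect_equal(pc$df, 4)
  same <- paired_compare(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  x <- c(1, 2, 3, 4, 5)
  expect_equal(correlate(x, 2 * x)$r, 1)
  r_hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(correlate(a, b)$r, r_hand, tolerance = 1e-10)
})
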