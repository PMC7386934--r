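#' Activation ground truth for a phantom run
#'
#' Selects the voxels that respond to left- and right-sided stimulation,
#' with controlled left-right and dorsal-ventral lateralization.  Active
#' voxels form compact in-plane foci (nearest the centroid of each
#' hemicord quadrant, same footprint on every slice) spanning a z window
#' centered at \code{center_z}; the voxel budget per quadrant is set so
#' the realized LR index of the left-responding mask approximates
#' \code{lr_index} (the right-responding mask is its mirror, LR index
#' \code{-lr_index}) and both masks share the DV index.  Given the
#' geometry the construction is deterministic; \code{seed} is retained
#' for bookkeeping.
#'
#' @param atlas a \code{cord_atlas}.
#' @param amplitude peak signal change at the HRF plateau, percent of
#'   baseline (default 0.71).
#' @param lr_index target LR laterality of the left-responding mask, in
#'   (-1, 1).
#' @param dv_index target DV laterality, in (-1, 1).
#' @param center_z center of the active region, voxel z; default the
#'   middle of the C6 segment.
#' @param z_halfwidth half-extent of the active region along z, voxels.
#' @param frac_active fraction of the cord cross-section activated.
#' @param seed integer seed for the voxel sampling.
#' @return An object of class \code{ground_truth}: logical masks
#'   \code{mask_left} and \code{mask_right}, the realized
#'   \code{lr_index}, \code{dv_index} and \code{cog_z} of the
#'   left-responding mask, \code{amplitude}, and bookkeeping fields.
#' @export
ground_truth <- function(atlas, amplitude = 0.71, lr_index = 0.3,
                         dv_index = 0, center_z = NULL, z_halfwidth = 8L,
                         frac_active = 0.5, seed = 1L) {
  stopifnot(inherits(atlas, "cord_atlas"), amplitude >= 0,
            abs(lr_index) < 1 || lr_index %in% c(-1, 1),
            abs(dv_index) <= 1)
  m <- atlas$masks
  if (is.null(center_z)) {
    b <- atlas$spec$segment_z_bounds$C6
    center_z <- round(mean(b))
  }
  nz <- atlas$dim[3L]
  zlo <- max(1L, round(center_z) - z_halfwidth)
  zhi <- min(nz, round(center_z) + z_halfwidth)
  zwin <- array(FALSE, dim = atlas$dim)
  zwin[, , zlo:zhi] <- TRUE

  # Active regions are spatially compact: within each hemicord quadrant
  # the budgeted voxels closest (in-plane) to the cord center are taken,
  # with the same 2D footprint on every slice of the z window.  The four
  # quadrant picks abut at the center, so each side's region is a single
  # coherent focus (its left/right split sets the LR index) rather than
  # salt-and-pepper voxels, and spatial smoothing does not dilute the
  # plateau amplitude in the region interior.
  mid_z <- round((zlo + zhi) / 2)
  ctr <- c((atlas$dim[1L] + 1) / 2, (atlas$dim[2L] + 1) / 2)
  quad2d <- function(lr, dv) {
    (if (lr > 0) m$left_hemicord else m$right_hemicord)[, , mid_z] &
      (if (dv > 0) m$dorsal_hemicord else m$ventral_hemicord)[, , mid_z]
  }
  pick2d <- function(q2d, n) {
    idx <- which(q2d, arr.ind = TRUE)
    n <- min(n, nrow(idx))
    if (n <= 0) return(idx[0, , drop = FALSE])
    d2 <- (idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2
    idx[order(d2, idx[, 1], idx[, 2])[seq_len(n)], , drop = FALSE]
  }
  n2d <- sum(m$cord[, , mid_z])
  build_mask <- function(lr) {
    p_left <- (1 + lr) / 2
    p_dorsal <- (1 + dv_index) / 2
    budget <- round(frac_active * n2d)
    counts <- round(budget * c(LD = p_left * p_dorsal,
                               LV = p_left * (1 - p_dorsal),
                               RD = (1 - p_left) * p_dorsal,
                               RV = (1 - p_left) * (1 - p_dorsal)))
    foot <- rbind(pick2d(quad2d(+1, +1), counts["LD"]),
                  pick2d(quad2d(+1, -1), counts["LV"]),
                  pick2d(quad2d(-1, +1), counts["RD"]),
                  pick2d(quad2d(-1, -1), counts["RV"]))
    out <- array(FALSE, dim = atlas$dim)
    for (z in zlo:zhi) out[cbind(foot, z)] <- TRUE
    out
  }
  mask_left <- build_mask(lr_index)
  mask_right <- build_mask(-lr_index)
  counts <- function(mask) c(l = sum(mask & m$left_hemicord),
                             r = sum(mask & m$right_hemicord),
                             d = sum(mask & m$dorsal_hemicord),
                             v = sum(mask & m$ventral_hemicord))
  cl <- counts(mask_left)
  zidx <- which(mask_left, arr.ind = TRUE)[, 3L]
  structure(list(mask_left = mask_left, mask_right = mask_right,
                 amplitude = amplitude,
                 lr_index = unname((cl["l"] - cl["r"]) / (cl["l"] + cl["r"])),
                 dv_index = unname((cl["d"] - cl["v"]) / (cl["d"] + cl["v"])),
                 cog_z = mean(zidx),
                 target_lr_index = lr_index, target_dv_index = dv_index,
                 center_z = center_z, z_halfwidth = z_halfwidth,
                 frac_active = frac_active, seed = as.integer(seed)),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("Ground truth: amplitude %.2f%%, %d left- / %d right-responding voxels\n",
              x$amplitude, sum(x$mask_left), sum(x$mask_right)))
  cat(sprintf("  realized LR %.3f (target %.3f), DV %.3f, COG z %.2f\n",
              x$lr_index, x$target_lr_index, x$dv_index, x$cog_z))
  invisible(x)
}

#' Noise specification for the phantom
#'
#' Amplitudes are stated as percent of baseline for structured components
#' and intensity units for white noise.  The white-noise default is
#' calibrated so that, at the reference 0.71% block amplitude, the
#' subject-level pipeline yields an active-voxel mean Z near 3.7 -- the
#' operating point reported for cervical spinal cord tactile fMRI at
#' 3 T.  (On this coarse phantom grid the raw-TSNR and activation-Z
#' anchors cannot both be matched; the activation statistics drive every
#' downstream spatial measure, so they take precedence.  See the methods
#' vignette.)
#'
#' @param white_sd white-noise SD, intensity units.
#' @param cardiac_pct cardiac oscillation amplitude in the cord, percent
#'   of baseline.
#' @param resp_pct respiratory amplitude in the cord, percent of baseline.
#' @param canal_boost multiplier on physiological amplitudes in the CSF
#'   canal (pulsatile CSF dominates near the canal).
#' @param drift_pct amplitude of the slow drift component, percent.
#' @param n_spikes number of spike (bulk-motion) volumes inserted.
#' @param spike_pct whole-volume intensity offset of a spike, percent of
#'   baseline.
#' @param spike_volumes explicit spike volume indices, or \code{NULL} to
#'   draw them from the seed.
#' @return A list of class \code{noise_spec}.
#' @export
noise_spec <- function(white_sd = 3, cardiac_pct = 0.4, resp_pct = 0.3,
                       canal_boost = 3, drift_pct = 0.5, n_spikes = 3L,
                       spike_pct = 3, spike_volumes = NULL) {
  structure(list(white_sd = white_sd, cardiac_pct = cardiac_pct,
                 resp_pct = resp_pct, canal_boost = canal_boost,
                 drift_pct = drift_pct, n_spikes = as.integer(n_spikes),
                 spike_pct = spike_pct, spike_volumes = spike_volumes),
            class = "noise_spec")
}

#' Silence all phantom noise sources
#' @return A \code{noise_spec} with every component zeroed.
#' @export
noise_off <- function() {
  noise_spec(white_sd = 0, cardiac_pct = 0, resp_pct = 0, drift_pct = 0,
             n_spikes = 0L, spike_pct = 0)
}

#' Simulate a phantom BOLD run
#'
#' Builds a 4D BOLD series on the atlas grid:
#' \code{data = baseline * (1 + task + physio + drift) + white noise},
#' plus whole-volume spike offsets.  The task term is the per-side sum of
#' HRF-convolved trial boxcars, normalized to unit peak and scaled by the
#' ground-truth amplitude, restricted to the truth masks.  The
#' physiological term is phase-locked to the cardiac and respiratory
#' traces through the same slicewise phase model used for denoising, with
#' amplitude boosted in the CSF canal; each voxel carries a fixed random
#' phase offset.  Baselines: WM 100, GM 105, canal CSF 120, other tissue
#' 10.
#'
#' @param atlas a \code{cord_atlas}.
#' @param protocol a \code{stim_protocol} on the same TR as the phantom grid.
#' @param truth a \code{\link{ground_truth}} on the same atlas.
#' @param physio output of \code{\link{simulate_physio}} covering the run,
#'   or \code{NULL} to simulate it from the seed.
#' @param noise a \code{\link{noise_spec}}.
#' @param hrf an \code{hrf_kernel}.
#' @param seed integer seed (whole run reproducible given identical
#'   arguments).
#' @return An object of class \code{bold_run}: \code{data} (4D),
#'   \code{tr}, \code{slice_times}, \code{slice_order}, \code{protocol},
#'   \code{physio}, \code{motion_params} (synthetic random-walk rigid
#'   parameters), \code{baseline_map}, \code{truth}, \code{noise},
#'   \code{atlas_dim}, \code{seed}.
#' @export
simulate_run <- function(atlas, protocol, truth, physio = NULL,
                         noise = noise_spec(), hrf = gamma_hrf(),
                         seed = 1L) {
  stopifnot(inherits(atlas, "cord_atlas"), inherits(protocol, "stim_protocol"),
            inherits(truth, "ground_truth"))
  if (!identical(dim(truth$mask_left), atlas$dim))
    stop("ground truth grid does not match atlas grid")
  d <- atlas$dim
  nv <- protocol$n_volumes
  tr <- protocol$tr
  if (is.null(physio))
    physio <- simulate_physio(duration_s = protocol$duration_s + tr,
                              seed = seed + 1000L)
  if (max(physio$cardiac$time_s) < protocol$duration_s)
    stop("physio traces do not cover the run")
  rng <- local_rng(seed)
  m <- atlas$masks

  baseline <- array(10, dim = d)
  baseline[m$wm] <- 100
  baseline[m$gm] <- 105
  baseline[m$canal_csf] <- 120

  # task term at volume midpoints, per side, unit peak
  evL <- trial_evs(protocol$left_onset_s, protocol$block_s, hrf, tr, nv)
  evR <- trial_evs(protocol$right_onset_s, protocol$block_s, hrf, tr, nv)
  sL <- rowSums(evL); sL <- sL / max(sL)
  sR <- rowSums(evR); sR <- sR / max(sR)

  nvox <- prod(d)
  amp <- truth$amplitude / 100
  task <- matrix(0, nvox, nv)
  if (amp > 0) {
    task[as.vector(truth$mask_left), ] <-
      task[as.vector(truth$mask_left), , drop = FALSE] +
      matrix(amp * sL, sum(truth$mask_left), nv, byrow = TRUE)
    task[as.vector(truth$mask_right), ] <-
      task[as.vector(truth$mask_right), , drop = FALSE] +
      matrix(amp * sR, sum(truth$mask_right), nv, byrow = TRUE)
  }

  slice_times <- interleaved_slice_times(d[3L], tr)
  physio_term <- matrix(0, nvox, nv)
  if (noise$cardiac_pct > 0 || noise$resp_pct > 0) {
    ph <- assign_phases(physio, slice_times, tr, nv)
    tissue <- m$cord | m$canal_csf
    boost <- array(0, dim = d)
    boost[m$cord] <- 1
    boost[m$canal_csf] <- noise$canal_boost
    theta_c <- array(2 * pi * rng$runif(nvox), dim = d)
    theta_r <- array(2 * pi * rng$runif(nvox), dim = d)
    for (s in seq_len(d[3L])) {
      sl <- which(tissue[, , s])
      if (!length(sl)) next
      base_idx <- (s - 1L) * prod(d[1:2]) + sl
      phc <- ph$cardiac[s, ]
      phr <- ph$respiratory[s, ]
      bc <- boost[, , s][sl]
      ac <- noise$cardiac_pct / 100 * bc
      ar <- noise$resp_pct / 100 * bc
      tc <- theta_c[, , s][sl]
      trr <- theta_r[, , s][sl]
      physio_term[base_idx, ] <-
        ac * cos(outer(tc, phc, "+")) + ar * cos(outer(trr, phr, "+"))
    }
  }

  drift <- matrix(0, nvox, nv)
  if (noise$drift_pct > 0) {
    t_mid <- (seq_len(nv) - 0.5) * tr
    slope <- (rng$runif(nvox) * 2 - 1) * noise$drift_pct / 100
    common <- cos(2 * pi * t_mid / 600)
    drift <- outer(slope, (t_mid - mean(t_mid)) / (max(t_mid) / 2)) +
      (noise$drift_pct / 200) * matrix(common, nvox, nv, byrow = TRUE)
  }

  data <- as.vector(baseline) * (1 + task + physio_term + drift)
  if (noise$white_sd > 0)
    data <- data + noise$white_sd * matrix(rng$rnorm(nvox * nv), nvox, nv)

  spikes <- noise$spike_volumes
  if (is.null(spikes) && noise$n_spikes > 0L)
    spikes <- sort(rng$sample(10:(nv - 10), noise$n_spikes))
  if (length(spikes) && noise$spike_pct > 0)
    data[, spikes] <- data[, spikes] +
      as.vector(baseline) * noise$spike_pct / 100

  motion <- matrix(0, nv, 6,
                   dimnames = list(NULL, c("tx", "ty", "tz", "rx", "ry", "rz")))
  mscale <- c(0.02, 0.02, 0.03, 0.001, 0.001, 0.001)
  for (j in 1:6) motion[, j] <- cumsum(rng$rnorm(nv, 0, mscale[j]))

  structure(list(data = array(data, dim = c(d, nv)), tr = tr,
                 slice_times = slice_times, slice_order = "interleaved",
                 protocol = protocol, physio = physio,
                 motion_params = motion, baseline_map = baseline,
                 truth = truth, noise = noise,
                 spike_volumes = if (length(spikes)) spikes else integer(0),
                 atlas_dim = d, seed = as.integer(seed)),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Phantom BOLD run: %d x %d x %d x %d, TR %g s (%s slices)\n",
              d[1], d[2], d[3], d[4], x$tr, x$slice_order))
  cat(sprintf("  amplitude %.2f%%, white SD %.2g, %d spike volume(s)\n",
              x$truth$amplitude, x$noise$white_sd, length(x$spike_volumes)))
  invisible(x)
}

#' Define a phantom cohort
#'
#' Draws per-subject ground-truth parameters (amplitude, LR laterality,
#' active-region center) from stated between-subject distributions and
#' records them in a manifest.  Subject runs are materialized lazily with
#' \code{\link{subject_run}} (in memory) or written to disk with
#' \code{\link{write_cohort}}, so a large cohort never has to be resident
#' at once.
#'
#' @param n_subjects cohort size (>= 2; default 24).
#' @param atlas a \code{cord_atlas} shared by all subjects.
#' @param protocol a \code{stim_protocol} shared by all subjects.
#' @param amplitude_mean,amplitude_sd percent-signal-change distribution
#'   across subjects (defaults 0.71 and 0.1).
#' @param lr_mean,lr_sd LR-index distribution of the left-responding mask
#'   (defaults 0.3 and 0.15).
#' @param dv_mean,dv_sd DV-index distribution (defaults 0).
#' @param cog_sd_z between-subject SD of the active-region center along z,
#'   voxels (default 2).
#' @param noise a \code{\link{noise_spec}} shared by all subjects.
#' @param seed cohort seed; per-subject seeds are derived from it.
#' @return An object of class \code{cord_cohort}: list with
#'   \code{subjects} (per-subject parameter list incl. \code{truth}),
#'   \code{manifest} (data frame), \code{atlas}, \code{protocol},
#'   \code{noise}, \code{seed}.
#' @export
generate_cohort <- function(n_subjects = 24L, atlas = build_atlas(),
                            protocol = generate_protocol(),
                            amplitude_mean = 0.71, amplitude_sd = 0.1,
                            lr_mean = 0.3, lr_sd = 0.15,
                            dv_mean = 0, dv_sd = 0,
                            cog_sd_z = 2, noise = noise_spec(),
                            seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 2L) stop("a cohort needs at least 2 subjects")
  rng <- local_rng(seed)
  b <- atlas$spec$segment_z_bounds$C6
  base_cog <- round(mean(b))
  subjects <- vector("list", n_subjects)
  rows <- list()
  for (i in seq_len(n_subjects)) {
    amp <- max(0.05, amplitude_mean +
                 (if (amplitude_sd > 0) amplitude_sd * rng$rnorm(1) else 0))
    lr <- max(-0.95, min(0.95, lr_mean +
                           (if (lr_sd > 0) lr_sd * rng$rnorm(1) else 0)))
    dv <- max(-0.95, min(0.95, dv_mean +
                           (if (dv_sd > 0) dv_sd * rng$rnorm(1) else 0)))
    cz <- base_cog + (if (cog_sd_z > 0) round(cog_sd_z * rng$rnorm(1)) else 0)
    cz <- max(1 + 4, min(atlas$dim[3L] - 4, cz))
    sseed <- seed * 1000L + i
    truth <- ground_truth(atlas, amplitude = amp, lr_index = lr,
                          dv_index = dv, center_z = cz, seed = sseed)
    subjects[[i]] <- list(id = sprintf("sub-%02d", i), seed = sseed,
                          truth = truth)
    rows[[i]] <- data.frame(id = subjects[[i]]$id, seed = sseed,
                            amplitude = amp,
                            true_lr_index = truth$lr_index,
                            true_dv_index = truth$dv_index,
                            true_cog_z = truth$cog_z)
  }
  structure(list(subjects = subjects, manifest = do.call(rbind, rows),
                 atlas = atlas, protocol = protocol, noise = noise,
                 seed = as.integer(seed)),
            class = "cord_cohort")
}

#' @export
print.cord_cohort <- function(x, ...) {
  cat(sprintf("Phantom cohort: %d subjects, seed %d\n",
              length(x$subjects), x$seed))
  cat(sprintf("  true LR index: mean %.3f (range %.3f..%.3f)\n",
              mean(x$manifest$true_lr_index), min(x$manifest$true_lr_index),
              max(x$manifest$true_lr_index)))
  invisible(x)
}

#' Materialize one subject's BOLD run from a cohort
#'
#' @param cohort a \code{cord_cohort}.
#' @param i subject index.
#' @return A \code{bold_run}.
#' @export
subject_run <- function(cohort, i) {
  s <- cohort$subjects[[i]]
  simulate_run(cohort$atlas, cohort$protocol, s$truth, physio = NULL,
               noise = cohort$noise, seed = s$seed)
}

#' Write a cohort to disk
#'
#' Writes, per subject, the BOLD run (NIfTI), physiological traces (TSV +
#' JSON), motion parameters (TSV) and ground truth (JSON); the shared
#' atlas masks and protocol; and a cohort manifest JSON.
#'
#' @param cohort a \code{cord_cohort}.
#' @param dir output directory.
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_atlas(cohort$atlas, file.path(dir, "atlas"))
  write_protocol(cohort$protocol, file.path(dir, "protocol.json"))
  entries <- list()
  for (i in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[i]]
    sdir <- file.path(dir, s$id)
    if (!dir.exists(sdir)) dir.create(sdir)
    run <- subject_run(cohort, i)
    RNifti::writeNifti(RNifti::asNifti(run$data,
                                       pixdim = c(cohort$atlas$voxel_size,
                                                  run$tr)),
                       file.path(sdir, "bold.nii.gz"))
    write_physio(run$physio$cardiac, file.path(sdir, "cardiac.tsv"))
    write_physio(run$physio$respiratory, file.path(sdir, "respiratory.tsv"))
    utils::write.table(run$motion_params, file.path(sdir, "motion.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    tr <- s$truth
    jsonlite::write_json(list(id = s$id, seed = s$seed,
                              amplitude = tr$amplitude,
                              lr_index = tr$lr_index, dv_index = tr$dv_index,
                              cog_z = tr$cog_z,
                              n_left = sum(tr$mask_left),
                              n_right = sum(tr$mask_right)),
                         file.path(sdir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    entries[[i]] <- list(id = s$id, seed = s$seed, dir = s$id,
                         amplitude = tr$amplitude, true_lr_index = tr$lr_index,
                         true_dv_index = tr$dv_index, true_cog_z = tr$cog_z)
  }
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(n_subjects = length(cohort$subjects),
                            seed = cohort$seed, subjects = entries),
                       mpath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(mpath)
}
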