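#' Analyze one subject's run end to end
#'
#' Runs the full per-subject pipeline on a BOLD run: DVARS outlier
#' detection on the raw series; slicewise physiological phase assignment,
#' RETROICOR basis and CSF principal components; high-pass filtering of
#' data and nuisance regressors (identically); slicewise nuisance
#' regression; slice-timing correction; masked Gaussian smoothing; TSNR
#' QC before and after smoothing; the trialwise prewhitened GLM; the four
#' standard contrasts thresholded at the subject level (uncorrected); the
#' percent-signal-change maps for the single-side contrasts; and the
#' per-side trial-set series for the habituation analysis.
#'
#' @param run a \code{bold_run} (or an equivalent list with fields
#'   \code{data}, \code{tr}, \code{slice_times}, \code{protocol},
#'   \code{physio}, \code{motion_params}, \code{baseline_map}).
#' @param atlas the \code{cord_atlas} for the run's grid.
#' @param subject subject identifier used in summaries.
#' @param z_thresh subject-level uncorrected threshold (default 2.3).
#' @param hp_cutoff_s high-pass cutoff, seconds (default 100).
#' @param fwhm_mm smoothing kernel FWHM, mm (default 2).
#' @param n_harmonics RETROICOR harmonics (default 4: 16 + 16 columns).
#' @param n_csf CSF principal components per slice (default 5).
#' @param prewhiten AR(1) prewhitening on/off.
#' @param with_trial_sets compute the per-side trial-set series (default
#'   TRUE; turn off for noise-free reference runs, whose zero trial
#'   variances make the fixed-effects set combination undefined).
#' @param n_sets number of consecutive trial sets for the habituation
#'   series (default 5, the published grouping for 20-trial runs).
#'   Skipped with a message when the trial count is not divisible.
#' @param out_dir optional directory; when given, the design, the
#'   nuisance matrices, the DVARS series, the QC report, the activation
#'   summaries and the stat maps are written there.
#' @return An object of class \code{subject_bundle}: stat maps and
#'   summaries per contrast, trial series per side, PSC results, QC, and
#'   the fitted \code{cord_glm}'s metadata.
#' @export
run_subject <- function(run, atlas, subject = "sub-01", z_thresh = 2.3,
                        hp_cutoff_s = 100, fwhm_mm = 2, n_harmonics = 4L,
                        n_csf = 5L, prewhiten = TRUE,
                        with_trial_sets = TRUE, n_sets = 5L,
                        out_dir = NULL) {
  stopifnot(inherits(atlas, "cord_atlas"))
  if (is.null(run$physio))
    stop("physio stage: no physiological traces attached to the run")
  if (is.null(run$data)) stop("input stage: run has no data")
  d <- dim(run$data)
  if (!identical(d[1:3], atlas$dim))
    stop("input stage: run grid does not match atlas grid")
  nv <- d[4L]
  protocol <- run$protocol
  if (nv != protocol$n_volumes)
    stop("input stage: volume count does not match protocol")
  cord <- atlas$masks$cord

  dv <- dvars_outliers(run$data, cord)

  phases <- assign_phases(run$physio, run$slice_times, run$tr, nv)
  pb <- physio_basis(phases, n_harmonics = n_harmonics)
  cb <- csf_pca(run$data, atlas$masks$canal_csf, n_comp = n_csf)
  nuis <- lapply(seq_len(d[3L]), function(s) {
    N <- cbind(pb[[s]], cb[[s]])
    highpass(N, hp_cutoff_s, run$tr)
  })

  bold <- run$data
  vox <- which(cord | atlas$masks$canal_csf)
  ymat <- matrix(bold, nrow = prod(d[1:3]))
  ymat[vox, ] <- t(highpass(t(ymat[vox, , drop = FALSE]), hp_cutoff_s,
                            run$tr))
  bold <- array(ymat, dim = d)
  bold <- regress_nuisance(bold, nuis, cord)
  bold <- slice_timing_correct(bold, run$slice_times, run$tr)
  tsnr_pre <- tsnr_map(bold, cord)
  bold <- smooth_bold(bold, cord, fwhm_mm, atlas$voxel_size)
  tsnr_post <- tsnr_map(bold, cord)

  design <- build_design(protocol, hrf = gamma_hrf(),
                         motion_params = run$motion_params,
                         outlier_flags = dv$flags)
  # the model must see the same temporal filter as the data; outlier
  # one-hot columns stay crisp so flagged volumes are removed exactly
  smoothcols <- design$groups != "outlier"
  design$X[, smoothcols] <- highpass(design$X[, smoothcols, drop = FALSE],
                                     hp_cutoff_s, run$tr)
  fit <- cord_glm(bold, design, cord, prewhiten = prewhiten)

  contrasts <- c("L", "R", "L>R", "R>L")
  maps <- list(); summaries <- list()
  for (cn in contrasts) {
    sm <- threshold_z(contrast_z(fit, contrast_spec(design, cn)), z_thresh)
    maps[[cn]] <- sm
    summaries[[cn]] <- activation_summary(sm, atlas, subject, cn)
  }
  psc <- list(
    L = percent_signal_change(maps[["L"]], design, run$baseline_map,
                              active_mask = maps[["L"]]$active_mask),
    R = percent_signal_change(maps[["R"]], design, run$baseline_map,
                              active_mask = maps[["R"]]$active_mask))

  sets <- NULL
  if (with_trial_sets && protocol$n_trials %% n_sets != 0L) {
    message("trial count not divisible into ", n_sets,
            " sets; skipping the trial-set series")
    with_trial_sets <- FALSE
  }
  if (with_trial_sets) {
    trial_maps <- function(cols) {
      lapply(cols, function(j) {
        w <- numeric(nrow(fit$betas)); w[1L + j] <- 1
        cz <- contrast_z(fit, w)
        list(cope = cz$cope, varcope = cz$varcope)
      })
    }
    tl <- trial_maps(design$left_cols)
    tr_ <- trial_maps(design$right_cols)
    sets <- list(
      L = trial_sets(lapply(tl, `[[`, "cope"), lapply(tl, `[[`, "varcope"),
                     cord, n_sets = n_sets, z_thresh = z_thresh),
      R = trial_sets(lapply(tr_, `[[`, "cope"), lapply(tr_, `[[`, "varcope"),
                     cord, n_sets = n_sets, z_thresh = z_thresh))
  }

  bundle <- structure(list(
    subject = subject, maps = maps,
    summary = do.call(rbind, summaries), psc = psc, trial_sets = sets,
    dvars = dv, tsnr_pre = tsnr_pre, tsnr_post = tsnr_post,
    design_cols = ncol(design$X), dof = fit$dof,
    resid_fwhm_vox = fit$resid_fwhm_vox,
    motion_abs_mm = mean(sqrt(rowSums(run$motion_params[, 1:3]^2))),
    params = list(z_thresh = z_thresh, hp_cutoff_s = hp_cutoff_s,
                  fwhm_mm = fwhm_mm, n_harmonics = n_harmonics,
                  n_csf = n_csf, prewhiten = prewhiten)),
    class = "subject_bundle")
  if (!is.null(out_dir)) write_bundle(bundle, design, nuis, out_dir)
  bundle
}

#' @export
print.subject_bundle <- function(x, ...) {
  cat(sprintf("Subject bundle %s: %d contrasts, %d design columns, dof %d\n",
              x$subject, nrow(x$summary), x$design_cols, x$dof))
  cat(sprintf("  TSNR %.1f (pre-smoothing) / %.1f (post); %d DVARS outlier(s)\n",
              x$tsnr_pre$mean_tsnr, x$tsnr_post$mean_tsnr,
              length(x$dvars$flags)))
  print(x$summary[, c("subject", "contrast", "total", "lr_index",
                      "dv_index", "cog_z", "gmwm_ratio", "mean_z")])
  invisible(x)
}

write_bundle <- function(bundle, design, nuis, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_design(design, file.path(out_dir, "design.tsv"))
  for (s in seq_along(nuis))
    utils::write.table(round(nuis[[s]], 10),
                       file.path(out_dir, sprintf("nuisance_slice%02d.tsv", s)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(data.frame(volume = seq_along(bundle$dvars$dvars),
                                dvars = round(bundle$dvars$dvars, 8)),
                     file.path(out_dir, "dvars.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(format(bundle$summary, digits = 10),
                     file.path(out_dir, "activation_summary.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(subject = bundle$subject,
                            tsnr_pre = bundle$tsnr_pre$mean_tsnr,
                            tsnr_post = bundle$tsnr_post$mean_tsnr,
                            dvars_outliers = bundle$dvars$flags,
                            dvars_threshold = bundle$dvars$threshold,
                            motion_abs_mm = bundle$motion_abs_mm,
                            params = bundle$params),
                       file.path(out_dir, "qc.json"), auto_unbox = TRUE,
                       digits = NA)
  for (cn in names(bundle$maps))
    write_stat_map(bundle$maps[[cn]],
                   file.path(out_dir, gsub("[^A-Za-z]", "", cn)))
  invisible(out_dir)
}

#' Analyze a whole phantom cohort
#'
#' Materializes and analyzes each subject of a cohort in turn (one run in
#' memory at a time) with \code{\link{run_subject}}.
#'
#' @param cohort a \code{cord_cohort}.
#' @param ... passed to \code{\link{run_subject}}.
#' @param progress print one line per subject.
#' @return List of \code{subject_bundle}s.
#' @export
run_cohort <- function(cohort, ..., progress = FALSE) {
  lapply(seq_along(cohort$subjects), function(i) {
    if (progress)
      message(sprintf("analyzing %s (%d/%d)", cohort$subjects[[i]]$id, i,
                      length(cohort$subjects)))
    run <- subject_run(cohort, i)
    run_subject(run, cohort$atlas, subject = cohort$subjects[[i]]$id, ...)
  })
}

#' Group-level analysis across subject bundles
#'
#' Combines subject contrast maps by fixed effects, applies Monte-Carlo
#' cluster-extent correction to the group maps, and assembles the group
#' report: per-contrast group activation summaries with GM/WM ratios,
#' the per-subject laterality-index statistics (median, IQR, Wilcoxon
#' signed-rank against 0), GM/WM ratio statistics (Wilcoxon against 1),
#' consistency maps, and the linear habituation trend across trial sets.
#'
#' @param bundles list of \code{subject_bundle}s (>= 2) on a shared grid.
#' @param atlas the shared \code{cord_atlas}.
#' @param z_thresh voxelwise threshold for the group maps (default 2.3).
#' @param alpha cluster significance level (default 0.05).
#' @param n_null Monte-Carlo null simulations for the cluster correction.
#' @param seed seed for the null simulation.
#' @return An object of class \code{group_report}: cluster-corrected
#'   group \code{maps}, \code{group_summary} (per-contrast counts and
#'   ratios), \code{index_stats} (per-contrast LR/DV medians, IQRs,
#'   Wilcoxon Z and p), \code{gmwm_stats}, \code{consistency},
#'   \code{trend} (per side and measure), \code{psc} means.
#' @export
run_group <- function(bundles, atlas, z_thresh = 2.3, alpha = 0.05,
                      n_null = 500L, seed = 1L) {
  if (length(bundles) < 2L)
    stop("group analysis needs at least 2 subjects; got ", length(bundles))
  cord <- atlas$masks$cord
  for (b in bundles)
    if (!identical(dim(b$maps[[1L]]$mask), dim(cord)))
      stop("subject maps are on different grids")
  contrasts <- names(bundles[[1L]]$maps)

  fwhm <- rowMeans(vapply(bundles, function(b) b$resid_fwhm_vox, numeric(3)))
  null_max <- null_cluster_distribution(cord, fwhm, z_thresh,
                                        n_null = n_null, seed = seed)
  maps <- list(); gsum <- list(); cons <- list()
  for (cn in contrasts) {
    fe <- fixed_effects(lapply(bundles, function(b) b$maps[[cn]]$cope),
                        lapply(bundles, function(b) b$maps[[cn]]$varcope),
                        cord)
    fe$contrast <- cn
    fe <- cluster_threshold(fe, z_thresh = z_thresh, alpha = alpha,
                            null_max = null_max)
    maps[[cn]] <- fe
    gsum[[cn]] <- activation_summary(fe, atlas, "group", cn)
    cons[[cn]] <- consistency_map(lapply(bundles,
                                         function(b) b$maps[[cn]]$active_mask))
  }

  subj_stat <- function(col) {
    sapply(contrasts, function(cn) {
      vapply(bundles, function(b) {
        r <- b$summary[b$summary$contrast == cn, ]
        as.numeric(r[[col]])
      }, numeric(1))
    })
  }
  lr <- subj_stat("lr_index"); dv <- subj_stat("dv_index")
  ratio <- subj_stat("gmwm_ratio")
  wilcox_or_na <- function(v, h0) {
    if (length(v) >= 5L) wilcoxon_median(v, h0)
    else list(z_stat = NA_real_, p = NA_real_)
  }
  index_stats <- do.call(rbind, lapply(contrasts, function(cn) {
    v <- lr[, cn]; v <- v[!is.na(v)]
    w <- wilcox_or_na(v, 0)
    vd <- dv[, cn]; vd <- vd[!is.na(vd)]
    wd <- wilcox_or_na(vd, 0)
    data.frame(contrast = cn,
               n_lr_positive = sum(v > 0), median_lr = stats::median(v),
               iqr_lr = stats::IQR(v), z_lr = w$z_stat, p_lr = w$p,
               median_dv = stats::median(vd), iqr_dv = stats::IQR(vd),
               z_dv = wd$z_stat, p_dv = wd$p)
  }))
  gmwm_stats <- do.call(rbind, lapply(contrasts, function(cn) {
    v <- ratio[, cn]; v <- v[!is.na(v)]
    w <- wilcox_or_na(v, 1)
    data.frame(contrast = cn, n = length(v), median_ratio = stats::median(v),
               iqr = stats::IQR(v), z = w$z_stat, p = w$p)
  }))

  trend <- list()
  have_sets <- !vapply(bundles, function(b) is.null(b$trial_sets),
                       logical(1))
  if (all(have_sets) &&
      nrow(bundles[[1L]]$trial_sets$L) >= 3L) for (side in c("L", "R")) {
    na_mat <- t(vapply(bundles,
                       function(b) b$trial_sets[[side]]$n_active,
                       numeric(nrow(bundles[[1L]]$trial_sets[[side]]))))
    mz_mat <- t(vapply(bundles,
                       function(b) b$trial_sets[[side]]$mean_z,
                       numeric(nrow(bundles[[1L]]$trial_sets[[side]]))))
    trend[[side]] <- list(n_active = linear_trend(na_mat),
                          mean_z = if (!anyNA(mz_mat))
                            linear_trend(mz_mat) else NULL)
  }

  psc_mean <- c(L = mean(vapply(bundles, function(b) b$psc$L$mean_psc,
                                numeric(1)), na.rm = TRUE),
                R = mean(vapply(bundles, function(b) b$psc$R$mean_psc,
                                numeric(1)), na.rm = TRUE))

  structure(list(maps = maps, group_summary = do.call(rbind, gsum),
                 index_stats = index_stats, gmwm_stats = gmwm_stats,
                 consistency = cons, trend = trend, psc_mean = psc_mean,
                 n_subjects = length(bundles),
                 params = list(z_thresh = z_thresh, alpha = alpha,
                               n_null = n_null, fwhm_vox = fwhm)),
            class = "group_report")
}

#' @export
print.group_report <- function(x, ...) {
  cat(sprintf("Group report over %d subjects (fixed effects, Z > %.2f, cluster p < %.2f)\n",
              x$n_subjects, x$params$z_thresh, x$params$alpha))
  cat("\nGroup activation (cluster-corrected):\n")
  print(x$group_summary[, c("contrast", "total", "lr_index", "dv_index",
                            "cog_z", "gmwm_ratio")])
  cat("\nSubject-level laterality (Wilcoxon vs 0):\n")
  print(x$index_stats, digits = 3)
  cat("\nGM/WM ratio (Wilcoxon vs 1):\n")
  print(x$gmwm_stats, digits = 3)
  cat(sprintf("\nMean percent signal change: L %.3f%%, R %.3f%%\n",
              x$psc_mean["L"], x$psc_mean["R"]))
  for (side in names(x$trend))
    cat(sprintf("Trend (%s, n_active): t = %.3f, p = %.4g\n", side,
                x$trend[[side]]$n_active$t, x$trend[[side]]$n_active$p))
  invisible(x)
}

#' Write a group report's tables and maps
#'
#' @param report a \code{group_report}.
#' @param dir output directory.
#' @return Invisibly, \code{dir}.
#' @export
write_group_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.table(format(report$group_summary, digits = 10),
                     file.path(dir, "group_summary.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(index_stats = report$index_stats,
                            gmwm_stats = report$gmwm_stats,
                            psc_mean = as.list(report$psc_mean),
                            trend = lapply(report$trend, function(tt)
                              list(n_active = tt$n_active[c("t", "df", "p")])),
                            params = report$params),
                       file.path(dir, "group_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (cn in names(report$maps))
    write_stat_map(report$maps[[cn]],
                   file.path(dir, paste0("group_", gsub("[^A-Za-z]", "", cn))))
  invisible(dir)
}
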