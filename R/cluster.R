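# 26-connected neighbor offsets in 3D.
neighbor_offsets_26 <- function() {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
}

#' Label connected components of a 3D mask
#'
#' Connected-component labelling with 26-neighborhood connectivity by
#' iterative minimum-label propagation (labels flood across touching
#' voxels until stable).
#'
#' @param mask 3D logical array.
#' @return Integer array of the same shape: 0 outside the mask, cluster
#'   labels 1..k (relabelled consecutively, largest cluster first) inside.
#' @export
label_clusters <- function(mask) {
  d <- dim(mask)
  stopifnot(length(d) == 3L)
  lab <- array(Inf, dim = d)
  lab[mask] <- seq_len(sum(mask))
  if (!any(mask)) return(array(0L, dim = d))
  offs <- neighbor_offsets_26()
  repeat {
    old <- lab
    for (i in seq_len(nrow(offs))) {
      sh <- shift_inf(old, offs$dx[i], offs$dy[i], offs$dz[i])
      lab <- pmin(lab, sh)
    }
    lab[!mask] <- Inf   # labels must not travel through non-mask voxels
    if (identical(lab, old)) break
  }
  ids <- lab[mask]
  tab <- sort(table(ids), decreasing = TRUE)
  relab <- stats::setNames(seq_along(tab), names(tab))
  out <- array(0L, dim = d)
  out[mask] <- as.integer(relab[as.character(ids)])
  out
}

# shift with Inf padding (so pmin propagation ignores borders)
shift_inf <- function(a, dx, dy, dz) {
  d <- dim(a)
  out <- array(Inf, dim = d)
  xs <- intersect(seq_len(d[1]), seq_len(d[1]) - dx)
  ys <- intersect(seq_len(d[2]), seq_len(d[2]) - dy)
  zs <- intersect(seq_len(d[3]), seq_len(d[3]) - dz)
  out[xs + dx, ys + dy, zs + dz] <- a[xs, ys, zs]
  out
}

#' Null distribution of the maximum cluster extent
#'
#' Simulates smoothness-matched Gaussian null Z maps on the analysis mask
#' (white noise smoothed to the given per-axis FWHM, standardized within
#' the mask), thresholds them, and records the largest 26-connected
#' suprathreshold cluster extent of each.
#'
#' @param mask 3D logical analysis mask.
#' @param fwhm_vox numeric(3), residual smoothness FWHM in voxels.
#' @param z_thresh cluster-forming threshold.
#' @param n_null number of null simulations (>= 100).
#' @param seed integer seed.
#' @return Integer vector of maximum cluster extents, length
#'   \code{n_null}, with attributes recording the parameters.
#' @export
null_cluster_distribution <- function(mask, fwhm_vox, z_thresh = 2.3,
                                      n_null = 1000L, seed = 1L) {
  if (n_null < 100L) stop("n_null < 100 gives an unstable null; refuse")
  d <- dim(mask)
  sigma <- fwhm_vox / (2 * sqrt(2 * log(2)))
  rng <- local_rng(seed)
  maxes <- integer(n_null)
  nm <- sum(mask)
  for (i in seq_len(n_null)) {
    e <- array(rng$rnorm(prod(d)), dim = d)
    e <- gaussian_smooth_array(e, sigma)
    v <- e[mask]
    z <- (v - mean(v)) / stats::sd(v)
    supra <- array(FALSE, dim = d)
    supra[mask] <- z > z_thresh
    if (!any(supra)) { maxes[i] <- 0L; next }
    lab <- label_clusters(supra)
    maxes[i] <- max(tabulate(lab[supra]))
  }
  attr(maxes, "z_thresh") <- z_thresh
  attr(maxes, "fwhm_vox") <- fwhm_vox
  maxes
}

#' Cluster-extent thresholding by Monte-Carlo null simulation
#'
#' Retains suprathreshold (Z > \code{z_thresh}) 26-connected clusters
#' whose extent is exceeded by the maximum null cluster extent with
#' probability below \code{alpha}, where the null is the distribution of
#' the largest cluster in smoothness-matched Gaussian maps
#' (\code{\link{null_cluster_distribution}}).  Cluster p-values use the
#' add-one permutation convention \code{(1 + #{null >= obs})/(n + 1)}.
#'
#' @param statmap a \code{stat_map} (its \code{resid_fwhm_vox} is used for
#'   smoothness matching unless \code{fwhm_vox} is given).
#' @param z_thresh cluster-forming threshold (default 2.3).
#' @param alpha cluster significance level (default 0.05).
#' @param n_null number of null simulations (default 1000, minimum 100).
#' @param fwhm_vox optional numeric(3) smoothness override.
#' @param null_max optional precomputed null vector from
#'   \code{\link{null_cluster_distribution}} (reused across maps sharing a
#'   mask and smoothness).
#' @param seed seed for the null simulation.
#' @return The stat map with \code{active_mask} (corrected), a
#'   \code{clusters} data frame (label, extent, max Z, p), and threshold
#'   metadata.
#' @export
cluster_threshold <- function(statmap, z_thresh = 2.3, alpha = 0.05,
                              n_null = 1000L, fwhm_vox = NULL,
                              null_max = NULL, seed = 1L) {
  stopifnot(inherits(statmap, "stat_map"))
  if (is.null(null_max)) {
    if (is.null(fwhm_vox)) fwhm_vox <- statmap$resid_fwhm_vox
    if (is.null(fwhm_vox))
      stop("no residual smoothness available; pass fwhm_vox or null_max")
    null_max <- null_cluster_distribution(statmap$mask, fwhm_vox, z_thresh,
                                          n_null, seed)
  }
  n_null <- length(null_max)
  supra <- statmap$mask & !is.na(statmap$z) & statmap$z > z_thresh
  active <- array(FALSE, dim = statmap$dim)
  clusters <- data.frame(label = integer(0), extent = integer(0),
                         max_z = numeric(0), p = numeric(0))
  if (any(supra)) {
    lab <- label_clusters(supra)
    ext <- tabulate(lab[supra])
    for (k in seq_along(ext)) {
      pk <- (1 + sum(null_max >= ext[k])) / (n_null + 1)
      keep <- pk < alpha
      if (keep) active[lab == k] <- TRUE
      clusters <- rbind(clusters,
                        data.frame(label = k, extent = ext[k],
                                   max_z = max(statmap$z[lab == k]), p = pk))
    }
  }
  statmap$active_mask <- active
  statmap$clusters <- clusters
  statmap$z_thresh <- z_thresh
  statmap$cluster_alpha <- alpha
  statmap$correction <- "cluster_extent_monte_carlo"
  statmap$null_max <- null_max
  statmap
}

#' Percent signal change of a contrast
#'
#' Converts contrast estimates to percent signal change:
#' \code{100 * cope * peak / baseline}, where \code{peak} is the maximum
#' of the summed task explanatory variable for the contrast's side (the
#' height, in regressor units, of a full-amplitude response), and
#' \code{baseline} is the voxel's baseline intensity.  When an active
#' mask is supplied the summary averages over active voxels.
#'
#' @param statmap a \code{stat_map} from \code{\link{contrast_z}} for the
#'   \code{"L"} or \code{"R"} contrast.
#' @param design the \code{cord_design} used for the fit.
#' @param baseline_map 3D array of baseline intensities (positive on the
#'   mask; nonpositive voxels are excluded and counted).
#' @param side \code{"left"} or \code{"right"}; default inferred from the
#'   contrast name.
#' @param active_mask optional 3D logical mask over which to summarize.
#' @return List of class \code{psc_result}: \code{map} (3D, %),
#'   \code{mean_psc} (over active mask if given, else over all mask
#'   voxels), \code{n_excluded}.
#' @export
percent_signal_change <- function(statmap, design, baseline_map,
                                  side = NULL, active_mask = NULL) {
  stopifnot(inherits(statmap, "stat_map"), inherits(design, "cord_design"))
  if (is.null(side))
    side <- switch(statmap$contrast, L = "left", R = "right",
                   stop("cannot infer side from contrast '",
                        statmap$contrast, "'; pass side="))
  peak <- design$peak_height[[side]]
  ok <- statmap$mask & !is.na(baseline_map) & baseline_map > 0
  n_excluded <- sum(statmap$mask) - sum(ok)
  map <- array(NA_real_, dim = statmap$dim)
  map[ok] <- 100 * statmap$cope[ok] * peak / baseline_map[ok]
  sel <- if (is.null(active_mask)) ok else ok & active_mask
  structure(list(map = map,
                 mean_psc = if (any(sel)) mean(map[sel]) else NA_real_,
                 n_excluded = n_excluded, side = side),
            class = "psc_result")
}

#' @export
print.psc_result <- function(x, ...) {
  cat(sprintf("Percent signal change (%s): mean %.3f%% (%d voxels excluded)\n",
              x$side, x$mean_psc, x$n_excluded))
  invisible(x)
}

#' Write a stat map's volumes as NIfTI
#'
#' @param statmap a \code{stat_map}.
#' @param prefix output path prefix; writes \code{<prefix>_z.nii.gz},
#'   \code{_cope}, \code{_varcope} and, if present, \code{_active}.
#' @param voxel_size numeric(3) voxel size for the header.
#' @return Invisibly, the paths written.
#' @export
write_stat_map <- function(statmap, prefix, voxel_size = c(1, 1, 3)) {
  wr <- function(a, suffix, int = FALSE) {
    a[is.na(a)] <- 0
    if (int) a <- array(as.integer(a), dim = dim(a))
    p <- paste0(prefix, "_", suffix, ".nii.gz")
    RNifti::writeNifti(RNifti::asNifti(a, pixdim = voxel_size), p)
    p
  }
  paths <- c(wr(statmap$z, "z"), wr(statmap$cope, "cope"),
             wr(statmap$varcope, "varcope"))
  if (!is.null(statmap$active_mask))
    paths <- c(paths, wr(statmap$active_mask + 0L, "active", int = TRUE))
  invisible(paths)
}
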