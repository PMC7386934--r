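#' Count active voxels per atlas compartment
#'
#' Counts the active voxels falling in each hemicord, segment and tissue
#' compartment.  The four partition identities (left + right =
#' dorsal + ventral = C5 + C6 + C7 = GM + WM = total) hold by
#' construction and are asserted.
#'
#' @param active_mask 3D logical array of active voxels; every active
#'   voxel must lie inside the atlas cord mask.
#' @param atlas a \code{cord_atlas}.
#' @return A named integer vector of class \code{activation_counts} with
#'   elements \code{left}, \code{right}, \code{dorsal}, \code{ventral},
#'   \code{C5}, \code{C6}, \code{C7}, \code{gm}, \code{wm}, \code{total}.
#' @export
compartment_counts <- function(active_mask, atlas) {
  stopifnot(inherits(atlas, "cord_atlas"),
            identical(dim(active_mask), atlas$dim))
  m <- atlas$masks
  if (any(active_mask & !m$cord))
    stop("active voxels outside the cord mask: ",
         sum(active_mask & !m$cord))
  cnt <- c(left = sum(active_mask & m$left_hemicord),
           right = sum(active_mask & m$right_hemicord),
           dorsal = sum(active_mask & m$dorsal_hemicord),
           ventral = sum(active_mask & m$ventral_hemicord),
           C5 = sum(active_mask & m$C5),
           C6 = sum(active_mask & m$C6),
           C7 = sum(active_mask & m$C7),
           gm = sum(active_mask & m$gm),
           wm = sum(active_mask & m$wm),
           total = sum(active_mask))
  stopifnot(cnt["left"] + cnt["right"] == cnt["total"],
            cnt["dorsal"] + cnt["ventral"] == cnt["total"],
            cnt["C5"] + cnt["C6"] + cnt["C7"] == cnt["total"],
            cnt["gm"] + cnt["wm"] == cnt["total"])
  structure(as.integer(cnt), names = names(cnt),
            class = "activation_counts")
}

#' @export
print.activation_counts <- function(x, ...) {
  cat("Active voxel counts per compartment:\n")
  print(stats::setNames(as.integer(x), names(x)))
  invisible(x)
}

#' Left-right and dorsal-ventral laterality indices
#'
#' \code{LR = (left - right) / (left + right)} and
#' \code{DV = (dorsal - ventral) / (dorsal + ventral)}.  +1 means all
#' active voxels in the left (resp. dorsal) hemicord, -1 all in the right
#' (resp. ventral) hemicord.  With no active voxels both indices are
#' undefined and returned as \code{NA} with a message (such subjects are
#' excluded from group tests).
#'
#' @param counts an \code{activation_counts} vector.
#' @return Named numeric vector \code{c(lr_index, dv_index)}.
#' @export
laterality_indices <- function(counts) {
  cnt <- as.integer(counts)
  names(cnt) <- names(counts)
  if (cnt["total"] == 0L) {
    message("no active voxels: laterality indices undefined (NA)")
    return(c(lr_index = NA_real_, dv_index = NA_real_))
  }
  c(lr_index = unname((cnt["left"] - cnt["right"]) /
                        (cnt["left"] + cnt["right"])),
    dv_index = unname((cnt["dorsal"] - cnt["ventral"]) /
                        (cnt["dorsal"] + cnt["ventral"])))
}

#' Superior-inferior center of gravity of activation
#'
#' Z-score-weighted mean voxel-z coordinate of the active voxels:
#' \code{sum(z_i * Z_i) / sum(Z_i)}.  Greater values are more superior.
#' An unweighted centroid over the binary active mask is available with
#' \code{weighted = FALSE}.
#'
#' @param statmap a \code{stat_map} with an \code{active_mask} (from
#'   \code{\link{threshold_z}} or \code{\link{cluster_threshold}}), or a
#'   3D logical mask (then necessarily unweighted).
#' @param weighted use Z weights (default) or the plain centroid.
#' @return The COG in voxel-z units, or \code{NA} if no voxels are active.
#' @export
cog_z <- function(statmap, weighted = TRUE) {
  if (is.array(statmap) && is.logical(statmap)) {
    am <- statmap
    zval <- NULL
  } else {
    stopifnot(inherits(statmap, "stat_map"))
    am <- statmap$active_mask
    if (is.null(am)) stop("stat map has no active_mask; threshold it first")
    zval <- statmap$z
  }
  if (!any(am)) {
    message("empty active mask: COG undefined (NA)")
    return(NA_real_)
  }
  zidx <- which(am, arr.ind = TRUE)[, 3L]
  if (weighted && !is.null(zval)) {
    w <- zval[am]
    sum(zidx * w) / sum(w)
  } else {
    mean(zidx)
  }
}

#' Gray/white matter activation ratio
#'
#' The percentage of gray matter activated divided by the percentage of
#' white matter activated,
#' \code{(gm_active/gm_total) / (wm_active/wm_total)}, which corrects the
#' raw count ratio for the white matter's more than threefold larger
#' volume.  Undefined (NA, with a message) when no WM voxels are active.
#'
#' @param counts an \code{activation_counts} vector.
#' @param atlas the \code{cord_atlas} supplying compartment volumes.
#' @return The ratio (full precision; display rounds to 2 decimals).
#' @export
gmwm_ratio <- function(counts, atlas) {
  stopifnot(inherits(atlas, "cord_atlas"))
  gm_total <- sum(atlas$masks$gm)
  wm_total <- sum(atlas$masks$wm)
  if (gm_total == 0L || wm_total == 0L) stop("empty GM or WM compartment")
  cnt <- as.integer(counts); names(cnt) <- names(counts)
  if (cnt["wm"] == 0L) {
    message("no active WM voxels: GM/WM ratio undefined (NA)")
    return(NA_real_)
  }
  activation_ratio(100 * cnt["gm"] / gm_total, 100 * cnt["wm"] / wm_total)
}

#' Ratio of two activation percentages
#'
#' @param pct_gm percent of gray matter activated.
#' @param pct_wm percent of white matter activated (> 0).
#' @return \code{pct_gm / pct_wm}, unrounded.
#' @export
activation_ratio <- function(pct_gm, pct_wm) {
  stopifnot(pct_wm > 0)
  unname(pct_gm / pct_wm)
}

#' Across-subject consistency map
#'
#' Voxelwise count of subjects whose binarized activation includes the
#' voxel.
#'
#' @param subject_masks list of 3D logical arrays on a shared grid.
#' @return An object of class \code{consistency_map}: \code{overlap} (3D
#'   integer array), \code{n_subjects}, \code{max_overlap} and the voxel
#'   index (arr.ind) of the maximum.
#' @export
consistency_map <- function(subject_masks) {
  stopifnot(length(subject_masks) >= 1L)
  d <- dim(subject_masks[[1L]])
  for (mk in subject_masks)
    if (!identical(dim(mk), d)) stop("subject masks are on different grids")
  ov <- Reduce(`+`, lapply(subject_masks, function(mk) array(as.integer(mk), d)))
  mx <- max(ov)
  at <- which(ov == mx, arr.ind = TRUE)
  structure(list(overlap = ov, n_subjects = length(subject_masks),
                 max_overlap = mx, max_at = at[1L, , drop = TRUE]),
            class = "consistency_map")
}

#' @export
print.consistency_map <- function(x, ...) {
  cat(sprintf("Consistency map over %d subjects: max overlap %d of %d at voxel (%d, %d, %d)\n",
              x$n_subjects, x$max_overlap, x$n_subjects,
              x$max_at[1], x$max_at[2], x$max_at[3]))
  invisible(x)
}

#' Wilcoxon signed-rank test against a hypothesized median
#'
#' Signed-rank test of the median of \code{values} against
#' \code{h0_median}.  Exact ties with the hypothesized median are dropped
#' before ranking.  For n <= 12 the null distribution of the positive
#' rank sum is enumerated exactly over all 2^n sign patterns (using the
#' observed midranks, so ties among magnitudes are handled); for larger n
#' the normal approximation with tie and continuity corrections is used.
#' The reported Z statistic is always the corrected normal deviate,
#' signed so that values above the hypothesized median give positive Z.
#'
#' @param values numeric sample.
#' @param h0_median hypothesized median (default 0).
#' @param exact_max largest n for which the exact enumeration is used.
#' @return List of class \code{wilcoxon_median}: \code{z_stat}, \code{p}
#'   (two-sided), \code{n} (after dropping ties with h0), \code{W}
#'   (positive rank sum), \code{method}.
#' @export
wilcoxon_median <- function(values, h0_median = 0, exact_max = 12L) {
  d <- values[!is.na(values)] - h0_median
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all values tie with the hypothesized median")
  if (n < 5L)
    warning("fewer than 5 non-tied values; the test has almost no power")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  # continuity-corrected normal deviate
  cc <- sign(W - mu) * min(0.5, abs(W - mu))
  z <- if (sig2 > 0) (W - mu - cc) / sqrt(sig2) else 0
  if (n <= exact_max) {
    # enumerate all sign assignments of the observed midranks
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Wnull <- as.vector(signs %*% r)
    p_ge <- mean(Wnull >= W - 1e-9)
    p_le <- mean(Wnull <= W + 1e-9)
    p <- min(1, 2 * min(p_ge, p_le))
    method <- "exact"
  } else {
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal_approx"
  }
  structure(list(z_stat = z, p = p, n = n, W = W, method = method,
                 h0_median = h0_median),
            class = "wilcoxon_median")
}

#' @export
print.wilcoxon_median <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank vs median %g: Z = %.3f, p = %.4g (n = %d, %s)\n",
              x$h0_median, x$z_stat, x$p, x$n, x$method))
  invisible(x)
}

#' Paired t-test and Pearson correlation helpers
#'
#' Thin wrappers around the standard two-tailed paired t-test and Pearson
#' correlation used for site/side comparisons and motion-vs-activation
#' checks, returning bare statistic/p pairs.  Subjects with missing
#' values in either member are dropped pairwise.
#'
#' @param a,b paired numeric vectors (equal length, n >= 3 after
#'   dropping incomplete pairs).
#' @return \code{paired_compare}: list with \code{t}, \code{p}, \code{df},
#'   \code{mean_diff}.
#' @export
paired_compare <- function(a, b) {
  ok <- stats::complete.cases(a, b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(a - b) == 0 && mean(a - b) == 0)
    return(list(t = 0, p = 1, df = length(a) - 1L, mean_diff = 0))
  if (stats::sd(a - b) == 0) stop("zero variance of paired differences")
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_diff = unname(tt$estimate))
}

#' @rdname paired_compare
#' @param x,y numeric vectors for the correlation.
#' @return \code{correlate}: list with \code{r}, \code{p}, \code{n}.
#' @export
correlate <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Summarize a subject-level activation map
#'
#' Bundles the compartment counts, laterality indices, COG and GM/WM
#' ratio for one thresholded contrast map into one row of the per-subject
#' summary table.
#'
#' @param statmap a thresholded \code{stat_map} (must carry
#'   \code{active_mask}).
#' @param atlas the \code{cord_atlas}.
#' @param subject subject identifier.
#' @param contrast contrast name (defaults to the map's).
#' @return An object of class \code{activation_summary}: one-row data
#'   frame with counts, indices, \code{cog_z}, \code{gmwm_ratio},
#'   \code{mean_z} and \code{max_z} of active voxels.
#' @export
activation_summary <- function(statmap, atlas, subject = "sub-01",
                               contrast = NULL) {
  stopifnot(inherits(statmap, "stat_map"))
  if (is.null(statmap$active_mask))
    stop("stat map has no active_mask; threshold it first")
  if (is.null(contrast)) contrast <- statmap$contrast
  cnt <- compartment_counts(statmap$active_mask & atlas$masks$cord, atlas)
  idx <- suppressMessages(laterality_indices(cnt))
  ratio <- suppressMessages(gmwm_ratio(cnt, atlas))
  cz <- suppressMessages(cog_z(statmap))
  zv <- statmap$z[statmap$active_mask]
  out <- data.frame(subject = subject, contrast = contrast,
                    t(as.integer(cnt)),
                    lr_index = idx[["lr_index"]], dv_index = idx[["dv_index"]],
                    cog_z = cz, gmwm_ratio = ratio,
                    mean_z = if (length(zv)) mean(zv) else NA_real_,
                    max_z = if (length(zv)) max(zv) else NA_real_)
  names(out)[3:12] <- names(cnt)
  class(out) <- c("activation_summary", "data.frame")
  out
}
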