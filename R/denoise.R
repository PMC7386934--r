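#' Assign cardiac and respiratory phases to each slice acquisition
#'
#' Retrospective physiological correction needs a cardiac and a
#' respiratory phase for every slice of every volume.  The cardiac phase
#' is linear time within the current cardiac cycle,
#' \code{2*pi*(t - prev_peak)/(next_peak - prev_peak)}.  The respiratory
#' phase uses the histogram-equalized amplitude transform: the amplitude
#' at time t is mapped through the empirical amplitude distribution of the
#' whole trace and signed by the amplitude derivative (inhale vs exhale),
#' then wrapped to [0, 2*pi).
#'
#' @param physio list with \code{cardiac} and \code{respiratory}
#'   \code{physio_trace} objects (as from \code{\link{simulate_physio}}).
#' @param slice_times acquisition time offset of each z slice within the
#'   TR, seconds (length = number of slices).
#' @param tr repetition time, seconds.
#' @param n_volumes number of volumes.
#' @param n_bins histogram bins for the respiratory amplitude transform.
#' @return An object of class \code{phase_assignment}: list of two
#'   \code{n_slices x n_volumes} matrices \code{cardiac} and
#'   \code{respiratory}, phases in [0, 2*pi).
#' @export
assign_phases <- function(physio, slice_times, tr, n_volumes, n_bins = 100L) {
  card <- physio$cardiac
  resp <- physio$respiratory
  stopifnot(inherits(card, "physio_trace"), inherits(resp, "physio_trace"))
  peaks <- attr(card, "extended_peaks")
  if (is.null(peaks)) peaks <- card$peak_times
  if (length(peaks) < 2L) stop("need at least two cardiac peaks")
  ns <- length(slice_times)
  acq <- outer(slice_times, (seq_len(n_volumes) - 1) * tr, "+") # ns x nv
  if (min(acq) < peaks[1L] || max(acq) >= peaks[length(peaks)])
    stop("slice acquisition times fall outside cardiac peak coverage")
  if (min(acq) < min(resp$time_s) || max(acq) > max(resp$time_s))
    stop("slice acquisition times fall outside respiratory trace coverage")
  idx <- findInterval(as.vector(acq), peaks)
  t0 <- peaks[idx]
  t1 <- peaks[idx + 1L]
  cphase <- 2 * pi * (as.vector(acq) - t0) / (t1 - t0)

  # respiratory: histogram-equalized amplitude with derivative sign
  amp <- resp$samples
  damp <- c(diff(amp), 0) * resp$sampling_rate
  brks <- seq(min(amp), max(amp), length.out = n_bins + 1L)
  h <- tabulate(findInterval(amp, brks, all.inside = TRUE), nbins = n_bins)
  cum <- cumsum(h) / sum(h)
  a_acq <- stats::approx(resp$time_s, amp, xout = as.vector(acq), rule = 2)$y
  d_acq <- stats::approx(resp$time_s, damp, xout = as.vector(acq), rule = 2)$y
  bin <- findInterval(a_acq, brks, all.inside = TRUE)
  rphase <- pi * cum[bin] * sign(ifelse(d_acq == 0, 1, d_acq))
  rphase <- rphase %% (2 * pi)

  structure(list(cardiac = matrix(cphase %% (2 * pi), ns, n_volumes),
                 respiratory = matrix(rphase, ns, n_volumes),
                 slice_times = slice_times, tr = tr),
            class = "phase_assignment")
}

#' RETROICOR harmonic and interaction regressor basis
#'
#' For each slice, builds the 16 harmonic regressors
#' \code{sin(k*phi_c), cos(k*phi_c), sin(k*phi_r), cos(k*phi_r)} for
#' harmonics k = 1..4, plus 16 cardiorespiratory interaction regressors
#' \code{sin(k*phi_c + phi_r), cos(k*phi_c + phi_r),
#' sin(k*phi_c - phi_r), cos(k*phi_c - phi_r)} for k = 1..4.
#'
#' @param phases a \code{phase_assignment}.
#' @param n_harmonics harmonics per signal (default 4, giving 16 + 16
#'   columns).
#' @param interaction form of the interaction block:
#'   \code{"sum_difference"} (sum/difference-of-phase terms, default) or
#'   \code{"product"} (elementwise products of cardiac and respiratory
#'   first-harmonic terms with harmonic cardiac phase).
#' @return A list of per-slice matrices (volumes x 32 columns, named),
#'   with attribute \code{"labels"}.
#' @export
physio_basis <- function(phases, n_harmonics = 4L,
                         interaction = c("sum_difference", "product")) {
  stopifnot(inherits(phases, "phase_assignment"))
  interaction <- match.arg(interaction)
  ns <- nrow(phases$cardiac)
  lapply(seq_len(ns), function(s) {
    pc <- phases$cardiac[s, ]
    pr <- phases$respiratory[s, ]
    cols <- list()
    for (k in seq_len(n_harmonics)) {
      cols[[sprintf("card_sin%d", k)]] <- sin(k * pc)
      cols[[sprintf("card_cos%d", k)]] <- cos(k * pc)
      cols[[sprintf("resp_sin%d", k)]] <- sin(k * pr)
      cols[[sprintf("resp_cos%d", k)]] <- cos(k * pr)
    }
    for (k in seq_len(n_harmonics)) {
      if (interaction == "sum_difference") {
        cols[[sprintf("int_sin%d_plus", k)]] <- sin(k * pc + pr)
        cols[[sprintf("int_cos%d_plus", k)]] <- cos(k * pc + pr)
        cols[[sprintf("int_sin%d_minus", k)]] <- sin(k * pc - pr)
        cols[[sprintf("int_cos%d_minus", k)]] <- cos(k * pc - pr)
      } else {
        cols[[sprintf("int_ss%d", k)]] <- sin(k * pc) * sin(pr)
        cols[[sprintf("int_sc%d", k)]] <- sin(k * pc) * cos(pr)
        cols[[sprintf("int_cs%d", k)]] <- cos(k * pc) * sin(pr)
        cols[[sprintf("int_cc%d", k)]] <- cos(k * pc) * cos(pr)
      }
    }
    do.call(cbind, cols)
  })
}

#' Slicewise CSF principal components
#'
#' Extracts, per axial slice, the leading principal-component time courses
#' of the voxel time series inside the spinal canal CSF mask.  Components
#' are mean-centered, unit-normed and ordered by explained variance.
#'
#' @param bold 4D array (x, y, z, t).
#' @param canal_mask 3D logical array of canal CSF voxels.
#' @param n_comp components per slice (default 5).
#' @return List of per-slice matrices (volumes x up to \code{n_comp}).
#'   Slices with fewer canal voxels than components return fewer columns
#'   with a warning; slices with no canal voxels return a zero-column
#'   matrix.
#' @export
csf_pca <- function(bold, canal_mask, n_comp = 5L) {
  d <- dim(bold)
  stopifnot(length(d) == 4L, identical(dim(canal_mask), d[1:3]))
  nv <- d[4L]
  short <- integer(0)
  out <- lapply(seq_len(d[3L]), function(s) {
    m <- canal_mask[, , s]
    if (!any(m)) return(matrix(0, nv, 0))
    x <- matrix(bold[, , s, ][rep(m, nv)], nrow = sum(m))  # vox x t
    x <- t(x)                                              # t x vox
    x <- sweep(x, 2, colMeans(x))
    k <- min(n_comp, ncol(x), nv - 1L)
    if (k < n_comp) short <<- c(short, s)
    if (k == 0L) return(matrix(0, nv, 0))
    p <- stats::prcomp(x, center = FALSE)
    pcs <- p$x[, seq_len(min(k, ncol(p$x))), drop = FALSE]
    pcs <- sweep(pcs, 2, colMeans(pcs))
    nrm <- sqrt(colSums(pcs^2))
    nrm[nrm == 0] <- 1
    pcs <- sweep(pcs, 2, nrm, "/")
    colnames(pcs) <- sprintf("csf_pc%d", seq_len(ncol(pcs)))
    pcs
  })
  if (length(short))
    warning("reduced-rank CSF block on slice(s) ",
            paste(short, collapse = ", "),
            ": fewer canal voxels than requested components")
  out
}

#' DVARS outlier detection
#'
#' DVARS at volume t is the root mean square, over mask voxels, of the
#' intensity difference between volume t and volume t-1.  Volumes whose
#' DVARS exceeds the box-plot cutoff (75th percentile + 1.5 x
#' interquartile range of the DVARS series) are flagged as motion
#' outliers.  A single spike volume perturbs two consecutive differences,
#' so both adjacent volumes are flagged.  Flags are invariant under global
#' intensity scaling and constant offsets.
#'
#' @param bold 4D array (x, y, z, t).
#' @param mask 3D logical array.
#' @return List of class \code{dvars_result}: \code{dvars} (length t,
#'   first element \code{NA}), \code{flags} (flagged volume indices),
#'   \code{threshold}.
#' @export
dvars_outliers <- function(bold, mask) {
  d <- dim(bold)
  stopifnot(length(d) == 4L, identical(dim(mask), d[1:3]))
  if (d[4L] < 3L) stop("need at least 3 volumes for DVARS")
  if (!any(mask)) stop("empty mask")
  y <- matrix(bold[rep(mask, d[4L])], nrow = sum(mask))  # vox x t
  dv <- sqrt(colMeans((y[, -1L, drop = FALSE] -
                         y[, -d[4L], drop = FALSE])^2))
  q <- stats::quantile(dv, c(0.25, 0.75), names = FALSE, type = 7)
  thr <- q[2L] + 1.5 * (q[2L] - q[1L])
  flags <- which(dv > thr) + 1L   # dv[i] is the diff into volume i+1
  structure(list(dvars = c(NA_real_, dv), flags = flags, threshold = thr),
            class = "dvars_result")
}

#' @export
print.dvars_result <- function(x, ...) {
  cat(sprintf("DVARS over %d volumes: threshold %.4g, %d outlier volume(s)\n",
              length(x$dvars), x$threshold, length(x$flags)))
  if (length(x$flags)) cat("  flagged:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' High-pass filter by discrete cosine basis projection
#'
#' Removes fluctuations slower than \code{cutoff_s} by projecting out the
#' leading discrete-cosine basis functions (those with period longer than
#' the cutoff) and re-adding the series mean.  Applied identically to data
#' and nuisance regressors so that filtering commutes with the nuisance
#' regression.
#'
#' @param x numeric vector or matrix (time in rows).
#' @param cutoff_s cutoff period, seconds (default 100).
#' @param tr sampling interval, seconds.
#' @return Filtered object of the same shape.
#' @export
highpass <- function(x, cutoff_s = 100, tr) {
  vec <- is.null(dim(x))
  xm <- as.matrix(x)
  n <- nrow(xm)
  stopifnot(cutoff_s > 2 * tr)
  K <- floor(2 * n * tr / cutoff_s)
  if (K < 1L) return(x)
  t0 <- seq_len(n) - 0.5
  B <- sapply(seq_len(K), function(j) cos(pi * j * t0 / n))
  B <- qr.Q(qr(B))
  mu <- colMeans(xm)
  xc <- sweep(xm, 2, mu)
  out <- xc - B %*% crossprod(B, xc)
  out <- sweep(out, 2, mu, "+")
  if (vec) drop(out) else out
}

#' Flag spike volumes: nuisance one-hot columns for DVARS outliers
#'
#' @param flags integer volume indices.
#' @param n_volumes run length.
#' @return A volumes x length(flags) one-hot matrix (zero columns if none).
#' @export
outlier_columns <- function(flags, n_volumes) {
  flags <- sort(unique(as.integer(flags)))
  oh <- matrix(0, n_volumes, length(flags))
  if (length(flags)) {
    oh[cbind(flags, seq_along(flags))] <- 1
    colnames(oh) <- sprintf("out%03d", flags)
  }
  oh
}

#' Regress slice-specific nuisance signals from a BOLD series
#'
#' Removes, per axial slice, the span of that slice's nuisance columns
#' (RETROICOR physiological block, CSF principal components, and any extra
#' columns) from every voxel time series by least squares, restoring the
#' voxel mean.  A rank-deficient nuisance block triggers a
#' condition-number warning and a pseudo-inverse fit.
#'
#' @param bold 4D array (x, y, z, t).
#' @param nuisance list of per-slice matrices (volumes x columns), e.g.
#'   cbind of \code{\link{physio_basis}} and \code{\link{csf_pca}} output.
#' @param mask 3D logical array of voxels to denoise (others pass through).
#' @return The denoised 4D array.
#' @export
regress_nuisance <- function(bold, nuisance, mask) {
  d <- dim(bold)
  stopifnot(length(d) == 4L, identical(dim(mask), d[1:3]),
            length(nuisance) == d[3L])
  nv <- d[4L]
  out <- bold
  for (s in seq_len(d[3L])) {
    m <- mask[, , s]
    if (!any(m)) next
    N <- nuisance[[s]]
    if (is.null(N) || ncol(N) == 0L) next
    if (nrow(N) != nv) stop("nuisance rows must match volume count")
    Nc <- sweep(N, 2, colMeans(N))
    keep <- colSums(Nc^2) > 1e-12
    Nc <- Nc[, keep, drop = FALSE]
    if (ncol(Nc) == 0L) next
    y <- matrix(bold[, , s, ][rep(m, nv)], nrow = sum(m))  # vox x t
    y <- t(y)
    mu <- colMeans(y)
    yc <- sweep(y, 2, mu)
    qn <- qr(Nc)
    if (qn$rank < ncol(Nc)) {
      warning(sprintf("slice %d: collinear nuisance block (rank %d < %d); using pseudo-inverse",
                      s, qn$rank, ncol(Nc)))
      sv <- svd(Nc)
      pos <- sv$d > max(sv$d) * 1e-10
      fit <- sv$u[, pos, drop = FALSE] %*%
        crossprod(sv$u[, pos, drop = FALSE], yc)
    } else {
      fit <- qr.fitted(qn, yc)
    }
    res <- sweep(yc - fit, 2, mu, "+")
    sl <- out[, , s, ]
    sl[rep(m, nv)] <- as.vector(t(res))
    out[, , s, ] <- sl
  }
  out
}

# Zero-padded shift of a 3D or 4D array along axis 1..3 by k voxels.
shift_array <- function(a, axis, k) {
  if (k == 0L) return(a)
  d <- dim(a)
  out <- array(0, dim = d)
  n <- d[axis]
  if (abs(k) >= n) return(out)
  src <- if (k > 0) 1:(n - k) else (1 - k):n
  dst <- if (k > 0) (1 + k):n else 1:(n + k)
  ix_src <- rep(list(quote(expr = )), length(d))
  ix_dst <- ix_src
  ix_src[[axis]] <- src
  ix_dst[[axis]] <- dst
  out <- do.call(`[<-`, c(list(out), ix_dst,
                          list(do.call(`[`, c(list(a), ix_src)))))
  out
}

# Separable Gaussian smoothing of a 3D or 4D array (first three axes).
gaussian_smooth_array <- function(a, sigma_vox) {
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s < 0.05) next
    r <- max(1L, ceiling(3 * s))
    w <- exp(-(seq(-r, r))^2 / (2 * s^2))
    w <- w / sum(w)
    acc <- array(0, dim = dim(a))
    for (i in seq(-r, r)) acc <- acc + w[i + r + 1L] * shift_array(a, axis, i)
    a <- acc
  }
  a
}

#' Masked Gaussian smoothing
#'
#' Spatially smooths a BOLD series with an isotropic Gaussian kernel of
#' the given FWHM, restricted to a mask: the data are multiplied by the
#' mask, smoothed, and renormalized by the smoothed mask so that edge
#' voxels are not diluted by outside-mask zeros.  A uniform field inside
#' the mask is left exactly unchanged.
#'
#' @param bold 4D array (x, y, z, t) (or a 3D array, smoothed as a single
#'   volume).
#' @param mask 3D logical array.
#' @param fwhm_mm kernel full width at half maximum, mm.
#' @param voxel_size numeric(3), mm per voxel.
#' @return Smoothed array of the same shape; voxels outside the mask are
#'   returned unchanged.
#' @export
smooth_bold <- function(bold, mask, fwhm_mm = 2, voxel_size = c(1, 1, 3)) {
  if (!any(mask)) stop("empty mask")
  sigma_vox <- (fwhm_mm / (2 * sqrt(2 * log(2)))) / voxel_size
  three_d <- length(dim(bold)) == 3L
  if (three_d) dim(bold) <- c(dim(bold), 1L)
  d <- dim(bold)
  stopifnot(identical(dim(mask), d[1:3]))
  mnum <- array(as.numeric(mask), dim = d[1:3])
  wsum <- gaussian_smooth_array(mnum, sigma_vox)
  masked <- bold * as.vector(mnum)
  sm <- gaussian_smooth_array(masked, sigma_vox)
  wsafe <- ifelse(wsum > 1e-12, wsum, 1)
  sm <- sm / as.vector(wsafe)
  out <- bold
  sel <- rep(as.vector(mask), d[4L])
  out[sel] <- sm[sel]
  if (three_d) dim(out) <- d[1:3]
  out
}

#' Temporal signal-to-noise ratio map
#'
#' Voxelwise temporal mean divided by the temporal standard deviation of
#' the linearly detrended series, within a mask.  Voxels with zero
#' residual variance are excluded from the masked mean and counted.
#'
#' @param bold 4D array (x, y, z, t) with at least 10 volumes.
#' @param mask 3D logical array.
#' @return List of class \code{tsnr_result}: \code{map} (3D, \code{NA}
#'   outside mask and at excluded voxels), \code{mean_tsnr},
#'   \code{n_excluded}.
#' @export
tsnr_map <- function(bold, mask) {
  d <- dim(bold)
  stopifnot(length(d) == 4L, identical(dim(mask), d[1:3]))
  if (d[4L] < 10L) stop("need at least 10 volumes for TSNR")
  nt <- d[4L]
  y <- matrix(bold[rep(mask, nt)], nrow = sum(mask))   # vox x t
  mu <- rowMeans(y)
  tt <- seq_len(nt) - (nt + 1) / 2
  slope <- (y %*% tt) / sum(tt^2)
  res <- y - mu - slope %*% t(tt)
  sdres <- sqrt(rowSums(res^2) / (nt - 2))
  tsnr <- ifelse(sdres > 1e-12, mu / sdres, NA_real_)
  map <- array(NA_real_, dim = d[1:3])
  map[mask] <- tsnr
  structure(list(map = map, mean_tsnr = mean(tsnr, na.rm = TRUE),
                 n_excluded = sum(is.na(tsnr))),
            class = "tsnr_result")
}

#' @export
print.tsnr_result <- function(x, ...) {
  cat(sprintf("TSNR: mean %.2f over %d voxels (%d excluded for zero variance)\n",
              x$mean_tsnr, sum(!is.na(x$map)), x$n_excluded))
  invisible(x)
}

#' Slice-timing correction by linear interpolation
#'
#' Resamples each axial slice's time series to the volume midpoint
#' (t = (v - 0.5) * TR) by linear interpolation between the two nearest
#' acquisitions of that slice, compensating the interleaved acquisition
#' order.  Run edges are clamped.
#'
#' @param bold 4D array (x, y, z, t).
#' @param slice_times per-slice acquisition offsets within the TR, seconds.
#' @param tr repetition time, seconds.
#' @return Corrected 4D array.
#' @export
slice_timing_correct <- function(bold, slice_times, tr) {
  d <- dim(bold)
  stopifnot(length(d) == 4L, length(slice_times) == d[3L])
  nt <- d[4L]
  out <- bold
  for (s in seq_len(d[3L])) {
    delta <- tr / 2 - slice_times[s]   # shift from acquisition to midpoint
    a <- delta / tr
    x <- matrix(bold[, , s, ], ncol = nt)
    if (abs(a) < 1e-12) next
    if (a > 0) {
      nxt <- x[, c(2:nt, nt), drop = FALSE]
      out[, , s, ] <- array((1 - a) * x + a * nxt, dim = c(d[1:2], 1, nt))
    } else {
      prv <- x[, c(1, 1:(nt - 1)), drop = FALSE]
      out[, , s, ] <- array((1 + a) * x - a * prv, dim = c(d[1:2], 1, nt))
    }
  }
  out
}

#' Interleaved slice acquisition timing
#'
#' @param n_slices number of axial slices.
#' @param tr repetition time, seconds.
#' @return Numeric vector of within-TR acquisition offsets per slice for
#'   an interleaved (odd slices first) acquisition.
#' @export
interleaved_slice_times <- function(n_slices, tr) {
  order <- c(seq(1L, n_slices, 2L), seq(2L, n_slices, 2L))
  times <- numeric(n_slices)
  times[order] <- (seq_len(n_slices) - 1) * tr / n_slices
  times
}
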