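#' Fit a prewhitened voxelwise GLM
#'
#' Fits the trialwise design to every voxel time series inside a mask by
#' AR(1)-prewhitened least squares (one Cochrane-Orcutt iteration): an
#' ordinary least-squares pass estimates each voxel's lag-1 residual
#' autocorrelation, the model is refit after whitening data and design
#' with that coefficient, and contrast inference uses the whitened
#' covariance.  Voxels are binned by their (quantized) AR coefficient so
#' that whitened designs are factored once per bin.
#'
#' @param bold 4D array (x, y, z, t).
#' @param design a \code{\link{build_design}} object.
#' @param mask 3D logical analysis mask.
#' @param prewhiten logical; \code{FALSE} gives plain OLS.
#' @param rho_bin quantization step for the AR(1) coefficient (default
#'   0.01; voxels sharing a bin share a whitened design factorization).
#' @return An object of class \code{cord_glm} with per-voxel coefficients,
#'   residual variances, AR coefficients, the shared whitened
#'   cross-product inverses, residual degrees of freedom, and the residual
#'   spatial smoothness estimate (FWHM in voxels per axis) used for
#'   cluster-extent null simulation.
#' @export
cord_glm <- function(bold, design, mask, prewhiten = TRUE, rho_bin = 0.01) {
  stopifnot(inherits(design, "cord_design"))
  d <- dim(bold)
  stopifnot(length(d) == 4L, identical(dim(mask), d[1:3]))
  X <- design$X
  nt <- nrow(X)
  p <- ncol(X)
  if (d[4L] != nt) stop("volume count does not match design rows")
  qx <- qr(cbind(1, X))
  if (qx$rank < p + 1L)
    stop("rank-deficient design (with intercept): offending columns ",
         paste(c("intercept", colnames(X))[qx$pivot[-seq_len(qx$rank)]],
               collapse = ", "))
  Xi <- cbind(`(Intercept)` = 1, X)
  Y <- matrix(bold[rep(mask, nt)], nrow = sum(mask))   # vox x t
  Y <- t(Y)                                            # t x vox
  nvox <- ncol(Y)

  q0 <- qr(Xi)
  res0 <- qr.resid(q0, Y)
  if (prewhiten) {
    num <- colSums(res0[-1L, , drop = FALSE] * res0[-nt, , drop = FALSE])
    den <- colSums(res0^2)
    rho <- ifelse(den > 1e-12, num / den, 0)
    rho <- pmax(pmin(rho, 0.95), -0.95)
    rho_q <- round(rho / rho_bin) * rho_bin
  } else {
    rho <- rho_q <- rep(0, nvox)
  }

  dof <- nt - (p + 1L)
  if (dof <= 0) stop("non-positive residual degrees of freedom")
  betas <- matrix(NA_real_, p + 1L, nvox,
                  dimnames = list(colnames(Xi), NULL))
  sigma2 <- numeric(nvox)
  ubins <- sort(unique(rho_q))
  bin_index <- match(rho_q, ubins)
  xtxinv <- vector("list", length(ubins))
  whiten <- function(M, r) {
    W <- rbind(sqrt(1 - r^2) * M[1L, , drop = FALSE],
               M[-1L, , drop = FALSE] - r * M[-nt, , drop = FALSE])
    W
  }
  for (b in seq_along(ubins)) {
    r <- ubins[b]
    sel <- bin_index == b
    Xw <- if (r == 0) Xi else whiten(Xi, r)
    Yw <- if (r == 0) Y[, sel, drop = FALSE] else whiten(Y[, sel, drop = FALSE], r)
    qw <- qr(Xw)
    bb <- qr.coef(qw, Yw)
    bb[is.na(bb)] <- 0
    rw <- Yw - Xw %*% bb
    betas[, sel] <- bb
    sigma2[sel] <- colSums(rw^2) / dof
    xtxinv[[b]] <- solve(crossprod(Xw))
  }

  smo <- estimate_fwhm_vox(res0, mask, d[1:3])
  structure(list(betas = betas, sigma2 = sigma2, rho = rho, dof = dof,
                 bin_index = bin_index, xtxinv = xtxinv,
                 mask = mask, dim = d[1:3], design = design,
                 colnames = colnames(Xi), prewhiten = prewhiten,
                 resid_fwhm_vox = smo),
            class = "cord_glm")
}

#' @export
print.cord_glm <- function(x, ...) {
  cat(sprintf("Prewhitened voxelwise GLM: %d voxels, %d design columns (+ intercept), dof %d\n",
              length(x$sigma2), length(x$colnames) - 1L, x$dof))
  cat(sprintf("  AR(1) coefficient: median %.3f (range %.3f..%.3f)%s\n",
              stats::median(x$rho), min(x$rho), max(x$rho),
              if (x$prewhiten) "" else " [prewhitening off]"))
  cat(sprintf("  residual smoothness FWHM (voxels): %.2f x %.2f x %.2f\n",
              x$resid_fwhm_vox[1], x$resid_fwhm_vox[2], x$resid_fwhm_vox[3]))
  invisible(x)
}

#' @export
coef.cord_glm <- function(object, ...) object$betas

#' @export
summary.cord_glm <- function(object, ...) {
  out <- list(n_voxels = length(object$sigma2), dof = object$dof,
              rho = stats::quantile(object$rho, c(0.05, 0.5, 0.95)),
              sigma = stats::quantile(sqrt(object$sigma2), c(0.05, 0.5, 0.95)),
              resid_fwhm_vox = object$resid_fwhm_vox)
  class(out) <- "summary.cord_glm"
  out
}

#' @export
print.summary.cord_glm <- function(x, ...) {
  cat(sprintf("Voxelwise GLM summary: %d voxels, dof %d\n", x$n_voxels, x$dof))
  cat("  AR(1) rho quantiles (5/50/95%):",
      paste(sprintf("%.3f", x$rho), collapse = " / "), "\n")
  cat("  residual SD quantiles (5/50/95%):",
      paste(sprintf("%.3g", x$sigma), collapse = " / "), "\n")
  invisible(x)
}

#' Contrast specification over task columns
#'
#' Builds the contrast weight vector for the standard contrasts: the mean
#' of the 20 left-trial (or right-trial) explanatory variables, and their
#' differences for the lateralization contrasts.  Weights are zero on all
#' covariates of no interest.
#'
#' @param design a \code{cord_design}.
#' @param name one of \code{"L"}, \code{"R"}, \code{"L>R"}, \code{"R>L"}.
#' @return An object of class \code{contrast_spec}: list with
#'   \code{name}, \code{weights} (length = design columns + intercept).
#' @export
contrast_spec <- function(design, name = c("L", "R", "L>R", "R>L")) {
  name <- match.arg(name)
  p <- ncol(design$X)
  w <- numeric(p + 1L)            # leading intercept
  nl <- length(design$left_cols)
  nr <- length(design$right_cols)
  if (name %in% c("L", "L>R")) w[1L + design$left_cols] <- 1 / nl
  if (name %in% c("R", "R>L")) w[1L + design$right_cols] <- 1 / nr
  if (name == "L>R") w[1L + design$right_cols] <- -1 / nr
  if (name == "R>L") w[1L + design$left_cols] <- -1 / nl
  structure(list(name = name, weights = w), class = "contrast_spec")
}

# Convert t statistics to Z scores through tail probabilities (stable in
# the far tails via log-scale probabilities).
t_to_z <- function(t, dof) {
  lp <- stats::pt(abs(t), df = dof, lower.tail = FALSE, log.p = TRUE)
  z <- stats::qnorm(lp, lower.tail = FALSE, log.p = TRUE)
  sign(t) * z
}

#' Contrast estimate and Z map
#'
#' Computes the contrast of parameter estimates (cope), its variance
#' (varcope) from the whitened covariance, and the Z map obtained by
#' converting the t statistic at the fit's residual degrees of freedom to
#' a standard normal deviate.
#'
#' @param fit a \code{\link{cord_glm}}.
#' @param contrast a \code{\link{contrast_spec}} or a raw weight vector
#'   (length = columns + intercept, or columns, intercept weight 0).
#' @return An object of class \code{stat_map}: 3D arrays \code{z},
#'   \code{cope}, \code{varcope} (NA outside the mask), the analysis
#'   \code{mask}, \code{dof} and metadata.
#' @export
contrast_z <- function(fit, contrast) {
  stopifnot(inherits(fit, "cord_glm"))
  if (inherits(contrast, "contrast_spec")) {
    w <- contrast$weights
    nm <- contrast$name
  } else {
    w <- as.numeric(contrast)
    nm <- "custom"
  }
  p1 <- nrow(fit$betas)
  if (length(w) == p1 - 1L) w <- c(0, w)
  stopifnot(length(w) == p1)
  cope <- drop(crossprod(w, fit$betas))
  cfac <- vapply(fit$xtxinv, function(V) drop(crossprod(w, V %*% w)),
                 numeric(1))
  varcope <- fit$sigma2 * cfac[fit$bin_index]
  tstat <- ifelse(varcope > 0, cope / sqrt(varcope), 0)
  z <- t_to_z(tstat, fit$dof)
  as_stat_map(z, cope, varcope, fit$mask, fit$dim,
              dof = fit$dof, contrast = nm,
              resid_fwhm_vox = fit$resid_fwhm_vox)
}

as_stat_map <- function(z, cope, varcope, mask, dim3, ...) {
  tovol <- function(v) {
    a <- array(NA_real_, dim = dim3)
    a[mask] <- v
    a
  }
  structure(c(list(z = tovol(z), cope = tovol(cope),
                   varcope = tovol(varcope), mask = mask, dim = dim3),
              list(...)),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  zv <- x$z[x$mask]
  cat(sprintf("Stat map (%s): %d voxels, Z range %.2f..%.2f\n",
              if (is.null(x$contrast)) "?" else x$contrast,
              sum(x$mask), min(zv), max(zv)))
  if (!is.null(x$active_mask))
    cat(sprintf("  active: %d voxels (threshold Z > %.2f, %s)\n",
                sum(x$active_mask), x$z_thresh,
                if (is.null(x$correction)) "uncorrected" else x$correction))
  invisible(x)
}

#' Threshold a stat map voxelwise (uncorrected)
#'
#' @param statmap a \code{stat_map}.
#' @param z_thresh voxelwise Z threshold (default 2.3).
#' @return The stat map with an \code{active_mask} of suprathreshold
#'   voxels and threshold metadata.
#' @export
threshold_z <- function(statmap, z_thresh = 2.3) {
  am <- statmap$mask & !is.na(statmap$z) & statmap$z > z_thresh
  statmap$active_mask <- am
  statmap$z_thresh <- z_thresh
  statmap$correction <- "uncorrected"
  statmap
}

#' Inverse-variance fixed-effects combination
#'
#' Combines contrast estimates across inputs (trials, runs or subjects)
#' treating within-input variance as the only variance component:
#' \code{cope* = sum(cope/var) / sum(1/var)}, \code{var* = 1/sum(1/var)},
#' \code{Z = cope*/sqrt(var*)}.
#'
#' @param copes list of 3D cope arrays (or vectors over mask voxels).
#' @param varcopes list of matching varcope arrays; all must be positive
#'   on the mask.
#' @param mask 3D logical analysis mask.
#' @return A \code{stat_map} with the combined cope, varcope and Z.
#' @export
fixed_effects <- function(copes, varcopes, mask) {
  stopifnot(length(copes) >= 1L, length(copes) == length(varcopes))
  getv <- function(a) if (is.null(dim(a)) || length(dim(a)) == 1L) a else a[mask]
  cm <- vapply(copes, getv, numeric(sum(mask)))
  vm <- vapply(varcopes, getv, numeric(sum(mask)))
  cm <- matrix(cm, ncol = length(copes))
  vm <- matrix(vm, ncol = length(varcopes))
  if (any(vm <= 0, na.rm = TRUE) || any(is.na(vm)))
    stop("fixed_effects requires positive varcopes on the mask")
  wsum <- rowSums(1 / vm)
  cstar <- rowSums(cm / vm) / wsum
  vstar <- 1 / wsum
  z <- cstar / sqrt(vstar)
  dim3 <- dim(mask)
  as_stat_map(z, cstar, vstar, mask, dim3, contrast = "fixed_effects",
              n_inputs = length(copes))
}

# Residual spatial smoothness per axis, as Gaussian FWHM in voxels,
# estimated from the variance ratio of spatial derivatives of the
# residuals (average over volumes).
estimate_fwhm_vox <- function(res, mask, dim3) {
  nt <- nrow(res)
  vol <- array(NA_real_, dim = dim3)
  num <- den <- numeric(3)
  take <- unique(round(seq(1, nt, length.out = min(nt, 40L))))
  for (tt in take) {
    vol[mask] <- res[tt, ]
    v0 <- stats::var(res[tt, ])
    for (axis in 1:3) {
      sh <- shift_array(vol, axis, 1L)
      dd <- vol - sh
      ok <- !is.na(dd)
      if (sum(ok) > 10) {
        num[axis] <- num[axis] + stats::var(dd[ok])
        den[axis] <- den[axis] + 2 * v0
      }
    }
  }
  ratio <- pmin(pmax(num / pmax(den, 1e-12), 1e-6), 0.999999)
  # for white noise smoothed with a Gaussian of SD sigma (voxels), the
  # lag-1 autocorrelation is exp(-1/(4 sigma^2)), so
  # var(dx)/(2 var(x)) = 1 - exp(-1/(4 sigma^2))
  sig2 <- -1 / (4 * log(pmax(1 - ratio, 1e-6)))
  fwhm <- sqrt(8 * log(2)) * sqrt(pmax(sig2, 1e-4))
  pmax(pmin(fwhm, 10), 0.1)
}
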