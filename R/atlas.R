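#' Phantom geometry specification
#'
#' Describes the template-space grid and cord geometry used to rasterize a
#' synthetic spinal-cord atlas.  The cord is an elliptical cylinder aligned
#' with the z axis; gray matter is modelled as a concentric inner ellipse
#' (a deliberate simplification of the GM butterfly, sufficient for
#' count-based statistics); a CSF ring of width \code{canal_margin}
#' surrounds the cord.  The z axis increases superiorly, so the C5 segment
#' occupies the top z interval, C6 the middle and C7 the bottom.
#'
#' Axis conventions: x increases toward the subject's left (so the left
#' hemicord is the high-x half), y increases dorsally (dorsal hemicord is
#' the high-y half).
#'
#' @param grid_shape integer(3), voxels along x, y, z.  The x dimension
#'   should be even so no voxel column straddles the left/right midline.
#' @param voxel_size numeric(3), mm per voxel along each axis.
#' @param cord_radii numeric(2), in-plane ellipse semi-axes in mm (x, y).
#' @param gm_fraction target gray-matter share of the cord cross-section,
#'   in (0, 1).  Must be small enough that rasterized WM > 3 x GM.
#' @param segment_z_bounds named list with elements \code{C5}, \code{C6},
#'   \code{C7}, each an integer(2) of inclusive voxel-z bounds.  Must be
#'   disjoint, contiguous and cover 1..nz.  Default splits the grid into
#'   three equal thirds with C5 most superior.
#' @param canal_margin width of the CSF ring around the cord, mm.
#' @param n_volumes number of volumes in a simulated run.
#' @param tr repetition time, seconds.
#' @return An object of class \code{cord_phantom_spec}.
#' @export
cord_phantom_spec <- function(grid_shape = c(24L, 24L, 48L),
                              voxel_size = c(1, 1, 3),
                              cord_radii = c(4, 3),
                              gm_fraction = 0.2,
                              segment_z_bounds = NULL,
                              canal_margin = 2,
                              n_volumes = 450L,
                              tr = 2) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape > 0L),
            length(voxel_size) == 3L, all(voxel_size > 0),
            length(cord_radii) == 2L, all(cord_radii > 0),
            tr > 0, n_volumes >= 1L)
  if (!(gm_fraction > 0 && gm_fraction < 1))
    stop("gm_fraction must lie in (0, 1)")
  nz <- grid_shape[3L]
  if (is.null(segment_z_bounds)) {
    cut1 <- floor(nz / 3)
    cut2 <- floor(2 * nz / 3)
    segment_z_bounds <- list(C7 = c(1L, cut1),
                             C6 = c(cut1 + 1L, cut2),
                             C5 = c(cut2 + 1L, nz))
  }
  segment_z_bounds <- segment_z_bounds[c("C5", "C6", "C7")]
  if (any(vapply(segment_z_bounds, is.null, logical(1))))
    stop("segment_z_bounds must name C5, C6 and C7")
  b <- do.call(rbind, segment_z_bounds)
  covered <- sort(unlist(mapply(seq, b[, 1L], b[, 2L], SIMPLIFY = FALSE)))
  if (!identical(as.integer(covered), seq_len(nz)))
    stop("segment z intervals must be disjoint, contiguous and cover 1..nz")
  # C5 must be the most superior interval (z increases superiorly)
  if (!(segment_z_bounds$C5[1L] > segment_z_bounds$C6[2L] &&
        segment_z_bounds$C6[1L] > segment_z_bounds$C7[2L]))
    stop("segments must be ordered C7 (inferior) < C6 < C5 (superior) in z")
  structure(list(grid_shape = grid_shape,
                 voxel_size = as.numeric(voxel_size),
                 cord_radii = as.numeric(cord_radii),
                 gm_fraction = gm_fraction,
                 segment_z_bounds = segment_z_bounds,
                 canal_margin = canal_margin,
                 n_volumes = as.integer(n_volumes),
                 tr = tr),
            class = "cord_phantom_spec")
}

#' @export
print.cord_phantom_spec <- function(x, ...) {
  cat("Spinal cord phantom specification\n")
  cat(sprintf("  grid: %d x %d x %d voxels (%.3g x %.3g x %.3g mm)\n",
              x$grid_shape[1], x$grid_shape[2], x$grid_shape[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat(sprintf("  cord radii: %.3g x %.3g mm, GM fraction %.2f, CSF margin %.3g mm\n",
              x$cord_radii[1], x$cord_radii[2], x$gm_fraction, x$canal_margin))
  for (s in c("C5", "C6", "C7"))
    cat(sprintf("  %s: z %d..%d\n", s, x$segment_z_bounds[[s]][1],
                x$segment_z_bounds[[s]][2]))
  cat(sprintf("  run: %d volumes, TR %.3g s\n", x$n_volumes, x$tr))
  invisible(x)
}

#' Build a synthetic spinal-cord atlas
#'
#' Rasterizes the phantom geometry into a set of named binary compartment
#' masks on a common voxel grid: the whole cord, left/right and
#' dorsal/ventral hemicords, C5/C6/C7 segments, gray and white matter, and
#' the surrounding spinal canal CSF.  The hemicord, segment and GM/WM mask
#' pairs/triples are exact partitions of the cord, mirroring the
#' template-space compartment masks used for localization statistics.
#'
#' @param spec a \code{\link{cord_phantom_spec}}.
#' @return An object of class \code{cord_atlas}: a list with \code{masks}
#'   (named logical arrays), \code{dim}, \code{voxel_size}, \code{spec} and
#'   a diagonal \code{affine} carrying the voxel size.
#' @export
build_atlas <- function(spec = cord_phantom_spec()) {
  stopifnot(inherits(spec, "cord_phantom_spec"))
  d <- spec$grid_shape
  vx <- spec$voxel_size
  cx <- (d[1L] + 1) / 2
  cy <- (d[2L] + 1) / 2
  xin <- (seq_len(d[1L]) - cx) * vx[1L]
  yin <- (seq_len(d[2L]) - cy) * vx[2L]
  # in-plane squared elliptical radius, 1 on the cord boundary
  r2 <- outer((xin / spec$cord_radii[1L])^2, (yin / spec$cord_radii[2L])^2, "+")
  cord2d <- r2 <= 1
  gm_scale <- spec$gm_fraction            # area scales with radii^2
  gm2d <- r2 <= gm_scale
  outer_r2 <- outer((xin / (spec$cord_radii[1L] + spec$canal_margin))^2,
                    (yin / (spec$cord_radii[2L] + spec$canal_margin))^2, "+")
  canal2d <- (outer_r2 <= 1) & !cord2d

  rep_z <- function(m2d) array(rep(m2d, d[3L]), dim = d)
  cord <- rep_z(cord2d)
  gm <- rep_z(gm2d)
  wm <- cord & !gm
  canal <- rep_z(canal2d)

  left2d <- cord2d & (row(cord2d) > cx)   # x increases toward the left
  right2d <- cord2d & (row(cord2d) < cx)
  mid2d <- cord2d & (row(cord2d) == cx)   # only possible for odd nx
  dorsal2d <- cord2d & (col(cord2d) > cy)
  ventral2d <- cord2d & (col(cord2d) < cy)
  midy2d <- cord2d & (col(cord2d) == cy)
  if (any(mid2d) || any(midy2d)) {
    # midline voxel columns are excluded from both hemicords and the cord
    # itself so that hemicord pairs stay exact partitions
    drop2d <- mid2d | midy2d
    cord2d <- cord2d & !drop2d
    cord <- rep_z(cord2d)
    gm <- gm & cord
    wm <- wm & cord
    left2d <- left2d & !drop2d; right2d <- right2d & !drop2d
    dorsal2d <- dorsal2d & !drop2d; ventral2d <- ventral2d & !drop2d
  }

  seg_mask <- function(bounds) {
    m <- array(FALSE, dim = d)
    m[, , bounds[1L]:bounds[2L]] <- TRUE
    m & cord
  }
  masks <- list(cord = cord,
                left_hemicord = rep_z(left2d),
                right_hemicord = rep_z(right2d),
                dorsal_hemicord = rep_z(dorsal2d),
                ventral_hemicord = rep_z(ventral2d),
                C5 = seg_mask(spec$segment_z_bounds$C5),
                C6 = seg_mask(spec$segment_z_bounds$C6),
                C7 = seg_mask(spec$segment_z_bounds$C7),
                gm = gm, wm = wm, canal_csf = canal)

  n <- vapply(masks, sum, numeric(1))
  if (any(n == 0))
    stop("invalid phantom geometry: empty compartment(s): ",
         paste(names(n)[n == 0], collapse = ", "))
  if (n[["wm"]] <= 3 * n[["gm"]])
    stop(sprintf(paste0("invalid phantom geometry: WM voxel count (%d) must ",
                        "exceed 3 x GM voxel count (%d); lower gm_fraction"),
                 n[["wm"]], n[["gm"]]))
  atlas <- structure(list(masks = masks, dim = d, voxel_size = vx,
                          affine = diag(c(vx, 1)), spec = spec),
                     class = "cord_atlas")
  stopifnot(atlas_partitions_ok(atlas))
  atlas
}

#' Check the atlas partition identities
#'
#' Verifies that left/right hemicords, dorsal/ventral hemicords, GM/WM and
#' the C5/C6/C7 segments each partition the cord exactly, and that the CSF
#' canal is disjoint from the cord.
#'
#' @param atlas a \code{cord_atlas}.
#' @return \code{TRUE} if all identities hold, otherwise \code{FALSE}.
#' @export
atlas_partitions_ok <- function(atlas) {
  m <- atlas$masks
  part <- function(a, b) !any(a & b) && all((a | b) == m$cord)
  ok <- part(m$left_hemicord, m$right_hemicord) &&
    part(m$dorsal_hemicord, m$ventral_hemicord) &&
    part(m$gm, m$wm) &&
    !any(m$C5 & m$C6) && !any(m$C6 & m$C7) && !any(m$C5 & m$C7) &&
    all((m$C5 | m$C6 | m$C7) == m$cord) &&
    !any(m$canal_csf & m$cord)
  isTRUE(ok)
}

#' @export
print.cord_atlas <- function(x, ...) {
  cat("Spinal cord phantom atlas\n")
  cat(sprintf("  grid %d x %d x %d, voxel %.3g x %.3g x %.3g mm\n",
              x$dim[1], x$dim[2], x$dim[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  n <- vapply(x$masks, sum, numeric(1))
  cat("  compartment voxel counts:\n")
  for (k in names(n)) cat(sprintf("    %-16s %6d\n", k, n[[k]]))
  cat(sprintf("  WM/GM volume ratio: %.2f\n", n[["wm"]] / n[["gm"]]))
  invisible(x)
}

#' Write atlas masks as NIfTI volumes
#'
#' @param atlas a \code{cord_atlas}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written (one per compartment mask).
#' @export
write_atlas <- function(atlas, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (k in names(atlas$masks)) {
    p <- file.path(dir, paste0("mask_", k, ".nii.gz"))
    img <- RNifti::asNifti(array(as.integer(atlas$masks[[k]]), dim = atlas$dim),
                           pixdim = atlas$voxel_size)
    RNifti::writeNifti(img, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
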