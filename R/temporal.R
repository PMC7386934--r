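#' Per-set activation summaries over consecutive trial blocks
#'
#' Divides the run's trial estimates into consecutive, non-overlapping
#' sets (five sets of four trials for the default 20-trial protocol),
#' combines each set's trial copes by inverse-variance fixed effects,
#' thresholds the set map (uncorrected Z, as at the subject level), and
#' records the number of active voxels and their mean Z per set.
#'
#' @param trial_copes list of per-trial 3D cope arrays (in trial order).
#' @param trial_varcopes matching list of varcope arrays.
#' @param mask 3D logical analysis mask.
#' @param n_sets number of sets (default 5); the trial count must be
#'   divisible by it.
#' @param z_thresh per-set activation threshold (default 2.3,
#'   uncorrected).
#' @return An object of class \code{trial_set_series}: data frame with
#'   columns \code{set}, \code{trials}, \code{n_active}, \code{mean_z}.
#' @export
trial_sets <- function(trial_copes, trial_varcopes, mask, n_sets = 5L,
                       z_thresh = 2.3) {
  nt <- length(trial_copes)
  if (nt == 0L || nt != length(trial_varcopes))
    stop("need matching, non-empty cope and varcope lists")
  if (nt %% n_sets != 0L)
    stop("trial count ", nt, " is not divisible into ", n_sets, " sets")
  per <- nt %/% n_sets
  rows <- lapply(seq_len(n_sets), function(k) {
    sel <- ((k - 1L) * per + 1L):(k * per)
    fe <- fixed_effects(trial_copes[sel], trial_varcopes[sel], mask)
    fe <- threshold_z(fe, z_thresh)
    zv <- fe$z[fe$active_mask]
    data.frame(set = k,
               trials = paste(range(sel), collapse = "-"),
               n_active = sum(fe$active_mask),
               mean_z = if (length(zv)) mean(zv) else NA_real_)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("trial_set_series", "data.frame")
  out
}

#' Linear trend test across trial sets
#'
#' Tests for habituation (decrease) or sensitization (increase) of the
#' response across consecutive trial sets.  Each subject's five set
#' values are reduced to an orthogonal-polynomial linear contrast score
#' (weights -2, -1, 0, 1, 2), and the scores are tested against zero with
#' a two-sided one-sample t-test - equivalent to the linear contrast of a
#' one-way repeated-measures ANOVA.  The full RM-ANOVA table is attached
#' for completeness.
#'
#' @param series numeric matrix, subjects x sets (default 5 columns), of
#'   per-set summaries (e.g. \code{n_active} or \code{mean_z}).
#' @return An object of class \code{trend_result}: \code{scores} (per
#'   subject), \code{t}, \code{df}, \code{p}, \code{degenerate} flag and
#'   \code{anova} (the RM-ANOVA summary, when estimable).
#' @export
linear_trend <- function(series) {
  series <- as.matrix(series)
  ns <- ncol(series)
  if (nrow(series) < 2L) stop("need at least 2 subjects")
  if (ns < 3L) stop("need at least 3 sets for a linear trend")
  w <- seq_len(ns) - (ns + 1) / 2           # (-2,-1,0,1,2) for 5 sets
  scores <- drop(series %*% w)
  s <- stats::sd(scores)
  if (s == 0) {
    if (mean(scores) == 0)
      return(structure(list(scores = scores, t = 0, df = nrow(series) - 1L,
                            p = 1, degenerate = FALSE, anova = NULL),
                       class = "trend_result"))
    return(structure(list(scores = scores, t = sign(mean(scores)) * Inf,
                          df = nrow(series) - 1L, p = 0, degenerate = TRUE,
                          anova = NULL),
                     class = "trend_result"))
  }
  tt <- stats::t.test(scores, mu = 0)
  long <- data.frame(y = as.vector(series),
                     set = factor(rep(seq_len(ns), each = nrow(series))),
                     subject = factor(rep(seq_len(nrow(series)), ns)))
  an <- tryCatch(summary(stats::aov(y ~ set + Error(subject), data = long)),
                 error = function(e) NULL)
  structure(list(scores = scores, t = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value,
                 degenerate = FALSE, anova = an),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("Linear trend across sets: t(%g) = %.3f, p = %.4g%s\n",
              x$df, x$t, x$p,
              if (x$degenerate) " [degenerate: zero score variance]" else ""))
  invisible(x)
}
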