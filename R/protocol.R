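#' Generate a block-design tactile stimulation protocol
#'
#' Each trial consists of a rest block followed by a left-sided and a
#' right-sided stimulation block of equal length, with the side order
#' pseudorandomized per trial (rest-left-right or rest-right-left).  The
#' order sequence is balanced to within one trial and constrained to at
#' most three identical consecutive orders.
#'
#' @param n_trials number of trials (default 20).
#' @param block_s block duration in seconds (default 15); each trial is
#'   \code{3 * block_s} long.  Must be divisible by \code{tr}.
#' @param tr repetition time in seconds (default 2).
#' @param site stimulation site label, \code{"lateral_shoulder"} or
#'   \code{"dorsal_third_digit"}.
#' @param seed integer seed for the order pseudorandomization.
#' @return An object of class \code{stim_protocol} with the per-trial
#'   order flags, block onset table, run duration and implied volume count.
#' @export
generate_protocol <- function(n_trials = 20L, block_s = 15, tr = 2,
                              site = c("lateral_shoulder",
                                       "dorsal_third_digit"),
                              seed = 1L) {
  site <- match.arg(site)
  n_trials <- as.integer(n_trials)
  stopifnot(n_trials >= 1L, block_s > 0, tr > 0)
  if (abs(3 * n_trials * block_s / tr -
            round(3 * n_trials * block_s / tr)) > 1e-9)
    stop("run duration (n_trials * 3 * block_s) must be divisible by tr")
  rng <- local_rng(seed)
  n_lr <- ceiling(n_trials / 2)
  repeat {
    order <- rng$sample(rep(c("LR", "RL"), c(n_lr, n_trials - n_lr)))
    r <- rle(order)$lengths
    if (max(r) <= 3L || n_trials <= 3L) break
  }
  duration <- n_trials * 3 * block_s
  trial_start <- (seq_len(n_trials) - 1) * 3 * block_s
  left_on <- trial_start + ifelse(order == "LR", block_s, 2 * block_s)
  right_on <- trial_start + ifelse(order == "LR", 2 * block_s, block_s)
  structure(list(n_trials = n_trials, block_s = block_s, tr = tr,
                 site = site, order = order, trial_start_s = trial_start,
                 left_onset_s = left_on, right_onset_s = right_on,
                 duration_s = duration,
                 n_volumes = as.integer(round(duration / tr)),
                 seed = as.integer(seed)),
            class = "stim_protocol")
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf("Stimulation protocol (%s)\n", x$site))
  cat(sprintf("  %d trials x 3 blocks x %g s = %g s, %d volumes at TR %g s\n",
              x$n_trials, x$block_s, x$duration_s, x$n_volumes, x$tr))
  cat("  order:", paste(x$order, collapse = " "), "\n")
  invisible(x)
}

#' Write / read a protocol as JSON
#' @param protocol a \code{stim_protocol}.
#' @param path JSON file path.
#' @return \code{write_protocol} returns \code{path} invisibly;
#'   \code{read_protocol} returns a \code{stim_protocol}.
#' @export
write_protocol <- function(protocol, path) {
  jsonlite::write_json(unclass(protocol), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  p$n_trials <- as.integer(p$n_trials)
  p$n_volumes <- as.integer(p$n_volumes)
  structure(p, class = "stim_protocol")
}

#' Gamma hemodynamic response kernel
#'
#' A gamma-density HRF parameterized by its mean lag and standard
#' deviation (shape = (lag/sd)^2, scale = sd^2/lag), shifted by
#' \code{phase_s} and scaled to unit peak so that a regressor built from
#' it keeps percent-signal-change interpretable.  The defaults (phase 0 s,
#' SD 3 s, mean lag 6 s) give shape 4 and scale 1.5 s, with the kernel
#' mode at (shape - 1) * scale = 4.5 s.
#'
#' @param phase_s onset shift in seconds.
#' @param sd_s standard deviation of the gamma density, seconds.
#' @param mean_lag_s mean of the gamma density, seconds.
#' @param dt sampling step, seconds.
#' @param support_s kernel support length, seconds (tail truncated there).
#' @return An object of class \code{hrf_kernel}: list with \code{t},
#'   \code{values} (unit peak), \code{dt}, \code{shape}, \code{scale},
#'   \code{support_s}.
#' @export
gamma_hrf <- function(phase_s = 0, sd_s = 3, mean_lag_s = 6, dt = 0.1,
                      support_s = 32) {
  stopifnot(dt > 0, sd_s > 0, mean_lag_s > 0, support_s > mean_lag_s)
  shape <- (mean_lag_s / sd_s)^2
  scale <- sd_s^2 / mean_lag_s
  t <- seq(0, support_s, by = dt)
  v <- stats::dgamma(t - phase_s, shape = shape, scale = scale)
  v[!is.finite(v)] <- 0
  v <- v / max(v)
  structure(list(t = t, values = v, dt = dt, shape = shape, scale = scale,
                 phase_s = phase_s, support_s = support_s),
            class = "hrf_kernel")
}

#' @export
print.hrf_kernel <- function(x, ...) {
  m <- sum(x$t * x$values) / sum(x$values)
  cat(sprintf("Gamma HRF kernel: shape %.3g, scale %.3g s (mode %.2f s, mean %.2f s), dt %g s\n",
              x$shape, x$scale, (x$shape - 1) * x$scale + x$phase_s, m, x$dt))
  invisible(x)
}

# Convolve per-trial boxcars with the HRF on a fine grid and decimate at
# volume midpoints.  onsets: vector of block onsets (s).  Returns a
# n_volumes x length(onsets) matrix.
trial_evs <- function(onsets, block_s, hrf, tr, n_volumes) {
  dt <- hrf$dt
  dur <- n_volumes * tr
  fine_n <- ceiling((dur + hrf$support_s) / dt) + 1L
  fine_t <- (seq_len(fine_n) - 1) * dt
  vol_t <- (seq_len(n_volumes) - 0.5) * tr
  ev <- matrix(0, n_volumes, length(onsets))
  k <- hrf$values
  for (j in seq_along(onsets)) {
    box <- as.numeric(fine_t >= onsets[j] & fine_t < onsets[j] + block_s)
    conv <- stats::convolve(box, rev(k), type = "open")[seq_len(fine_n)] * dt
    conv[abs(conv) < 1e-10] <- 0           # FFT roundoff; EVs have compact support
    ev[, j] <- stats::approx(fine_t, conv, xout = vol_t, rule = 2)$y
  }
  ev
}

#' Build the trialwise design matrix
#'
#' Constructs the task design for a block protocol: one explanatory
#' variable per left trial and per right trial (boxcars convolved with the
#' HRF on a 0.1 s grid and sampled at volume midpoints), the temporal
#' derivative of every task column, six rigid motion parameters, and
#' optional one-hot outlier columns and extra nuisance columns - the
#' latter three groups labelled as covariates of no interest.
#'
#' @param protocol a \code{stim_protocol}.
#' @param hrf an \code{hrf_kernel} (default \code{gamma_hrf()}).
#' @param motion_params numeric matrix, volumes x 6, or \code{NULL} to omit.
#' @param outlier_flags integer vector of outlier volume indices (one
#'   one-hot column each), or \code{NULL}.
#' @param nuisance numeric matrix of additional nuisance columns, or
#'   \code{NULL}.
#' @return An object of class \code{cord_design}: list with \code{X}
#'   (volumes x columns, named), \code{groups} (column role labels),
#'   \code{task_cols}, \code{left_cols}, \code{right_cols}, \code{time_s},
#'   \code{peak_height} (max of the per-side summed task EV, used to
#'   convert contrast estimates to percent signal change) and \code{tr}.
#' @export
build_design <- function(protocol, hrf = gamma_hrf(), motion_params = NULL,
                         outlier_flags = NULL, nuisance = NULL) {
  stopifnot(inherits(protocol, "stim_protocol"), inherits(hrf, "hrf_kernel"))
  nv <- protocol$n_volumes
  tr <- protocol$tr
  evL <- trial_evs(protocol$left_onset_s, protocol$block_s, hrf, tr, nv)
  evR <- trial_evs(protocol$right_onset_s, protocol$block_s, hrf, tr, nv)
  nt <- protocol$n_trials
  colnames(evL) <- sprintf("L%02d", seq_len(nt))
  colnames(evR) <- sprintf("R%02d", seq_len(nt))
  task <- cbind(evL, evR)
  if (any(colSums(abs(task)) == 0))
    stop("degenerate design: all-zero task column(s): ",
         paste(colnames(task)[colSums(abs(task)) == 0], collapse = ", "))
  deriv <- apply(task, 2, function(x) c(0, diff(x)) / tr)
  colnames(deriv) <- paste0(colnames(task), "_d")
  X <- cbind(task, deriv)
  groups <- c(rep("task_left", nt), rep("task_right", nt),
              rep("derivative", 2 * nt))
  if (!is.null(motion_params)) {
    motion_params <- as.matrix(motion_params)
    if (nrow(motion_params) != nv)
      stop("motion_params must have one row per volume")
    colnames(motion_params) <- sprintf("mot%d", seq_len(ncol(motion_params)))
    X <- cbind(X, motion_params)
    groups <- c(groups, rep("motion", ncol(motion_params)))
  }
  if (!is.null(outlier_flags) && length(outlier_flags)) {
    outlier_flags <- sort(unique(as.integer(outlier_flags)))
    if (any(outlier_flags < 1L | outlier_flags > nv))
      stop("outlier_flags outside the run")
    oh <- matrix(0, nv, length(outlier_flags))
    oh[cbind(outlier_flags, seq_along(outlier_flags))] <- 1
    colnames(oh) <- sprintf("out%03d", outlier_flags)
    X <- cbind(X, oh)
    groups <- c(groups, rep("outlier", ncol(oh)))
  }
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != nv) stop("nuisance must have one row per volume")
    if (is.null(colnames(nuisance)))
      colnames(nuisance) <- sprintf("nui%02d", seq_len(ncol(nuisance)))
    X <- cbind(X, nuisance)
    groups <- c(groups, rep("nuisance", ncol(nuisance)))
  }
  qx <- qr(X)
  if (qx$rank < 2 * nt)
    stop("degenerate design: rank ", qx$rank, " < task column count ",
         2 * nt, "; dependent columns include ",
         paste(colnames(X)[qx$pivot[-seq_len(qx$rank)]], collapse = ", "))
  structure(list(X = X, groups = groups,
                 task_cols = seq_len(2 * nt),
                 left_cols = seq_len(nt),
                 right_cols = nt + seq_len(nt),
                 time_s = (seq_len(nv) - 0.5) * tr,
                 peak_height = c(left = max(rowSums(evL)),
                                 right = max(rowSums(evR))),
                 tr = tr, protocol = protocol, hrf = hrf),
            class = "cord_design")
}

#' @export
print.cord_design <- function(x, ...) {
  cat(sprintf("Trialwise design: %d volumes x %d columns\n",
              nrow(x$X), ncol(x$X)))
  print(table(x$groups))
  invisible(x)
}

#' Write a design matrix as TSV
#' @param design a \code{cord_design}.
#' @param path output TSV path (header names every column).
#' @return Invisibly, \code{path}.
#' @export
write_design <- function(design, path) {
  utils::write.table(design$X, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
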