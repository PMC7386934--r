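#' Simulate cardiac and respiratory traces
#'
#' Generates quasi-periodic cardiac and respiratory signals of the kind
#' recorded alongside spinal cord fMRI (pulse oximeter and respiratory
#' bellows).  Each cycle's period is jittered multiplicatively:
#' \code{period_i = (1/rate) * (1 + rate_jitter * e_i)} with
#' \code{e_i ~ N(0, 1)} truncated to keep periods positive.  The cardiac
#' trace is a train of sharp raised-cosine pulses with the pulse onsets
#' recorded as \code{peak_times}; the respiratory trace is a smooth
#' raised-cosine oscillation with per-cycle amplitude jitter, giving the
#' amplitude distribution needed for histogram-equalized respiratory
#' phase.
#'
#' @param duration_s total duration to cover, seconds.
#' @param cardiac_rate_hz mean cardiac rate (default 1 Hz).
#' @param resp_rate_hz mean respiratory rate (default 0.25 Hz).
#' @param rate_jitter relative SD of per-cycle period jitter (default 0.05).
#' @param sampling_rate_hz sampling rate of the returned traces.
#' @param amp_jitter relative SD of per-cycle amplitude jitter for the
#'   respiratory trace.
#' @param seed integer seed; the generator is fully reproducible.
#' @return A list with elements \code{cardiac} and \code{respiratory}, each
#'   of class \code{physio_trace} with fields \code{time_s},
#'   \code{samples}, \code{sampling_rate}, \code{kind} and (cardiac only)
#'   \code{peak_times}.
#' @export
simulate_physio <- function(duration_s, cardiac_rate_hz = 1,
                            resp_rate_hz = 0.25, rate_jitter = 0.05,
                            sampling_rate_hz = 40, amp_jitter = 0.1,
                            seed = 1L) {
  stopifnot(duration_s > 0, cardiac_rate_hz > 0, resp_rate_hz > 0,
            rate_jitter >= 0, sampling_rate_hz > 0)
  if (rate_jitter >= 0.5)
    stop("rate_jitter too large: jittered periods could become non-positive")
  rng <- local_rng(seed)
  tgrid <- seq(0, duration_s, by = 1 / sampling_rate_hz)

  draw_onsets <- function(rate) {
    mean_period <- 1 / rate
    n_max <- ceiling(duration_s * rate * 1.5) + 10L
    e <- rng$rnorm(n_max)
    e <- pmax(pmin(e, 3), -3)           # truncate: periods stay positive
    periods <- mean_period * (1 + rate_jitter * e)
    onsets <- cumsum(c(0, periods))
    onsets[onsets <= duration_s + mean_period]
  }

  card_on <- draw_onsets(cardiac_rate_hz)
  # phase within the current cardiac cycle at each sample
  idx <- findInterval(tgrid, card_on)
  idx[idx < 1L] <- 1L
  t0 <- card_on[idx]
  t1 <- card_on[pmin(idx + 1L, length(card_on))]
  frac <- ifelse(t1 > t0, (tgrid - t0) / (t1 - t0), 0)
  # sharp systolic pulse: raised cosine to the 4th power
  card_sig <- ((1 + cos(2 * pi * frac)) / 2)^4

  resp_on <- draw_onsets(resp_rate_hz)
  amps <- pmax(1 + amp_jitter * pmax(pmin(rng$rnorm(length(resp_on)), 3), -3),
               0.1)
  ridx <- findInterval(tgrid, resp_on)
  ridx[ridx < 1L] <- 1L
  r0 <- resp_on[ridx]
  r1 <- resp_on[pmin(ridx + 1L, length(resp_on))]
  rfrac <- ifelse(r1 > r0, (tgrid - r0) / (r1 - r0), 0)
  resp_sig <- amps[ridx] * (1 - cos(2 * pi * rfrac)) / 2

  card <- structure(list(time_s = tgrid, samples = card_sig,
                         sampling_rate = sampling_rate_hz, kind = "cardiac",
                         peak_times = card_on[card_on < duration_s]),
                    class = "physio_trace")
  # keep the peak just beyond the run so phases interpolate at run end
  attr(card, "extended_peaks") <- card_on
  resp <- structure(list(time_s = tgrid, samples = resp_sig,
                         sampling_rate = sampling_rate_hz,
                         kind = "respiratory",
                         cycle_onsets = resp_on[resp_on <= duration_s]),
                    class = "physio_trace")
  list(cardiac = card, respiratory = resp)
}

#' @export
print.physio_trace <- function(x, ...) {
  cat(sprintf("%s trace: %.1f s at %g Hz (%d samples)\n", x$kind,
              max(x$time_s), x$sampling_rate, length(x$samples)))
  if (!is.null(x$peak_times))
    cat(sprintf("  %d peaks, mean interval %.3f s\n", length(x$peak_times),
                mean(diff(x$peak_times))))
  invisible(x)
}

#' Write a physiological trace as TSV plus JSON header
#'
#' @param trace a \code{physio_trace}.
#' @param path output TSV path (two columns: time_s, amplitude); a JSON
#'   sidecar with the sampling rate, kind and peak times is written next to
#'   it with extension \code{.json}.
#' @return Invisibly, \code{path}.
#' @export
write_physio <- function(trace, path) {
  stopifnot(inherits(trace, "physio_trace"))
  utils::write.table(data.frame(time_s = trace$time_s,
                                amplitude = trace$samples),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  hdr <- list(sampling_rate = trace$sampling_rate, kind = trace$kind)
  if (!is.null(trace$peak_times)) hdr$peak_times <- trace$peak_times
  jsonlite::write_json(hdr, paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a physiological trace written by \code{write_physio}
#'
#' @param path TSV path with JSON sidecar.
#' @return A \code{physio_trace}.
#' @export
read_physio <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  hdr <- jsonlite::read_json(paste0(tools::file_path_sans_ext(path), ".json"),
                             simplifyVector = TRUE)
  structure(list(time_s = tab$time_s, samples = tab$amplitude,
                 sampling_rate = hdr$sampling_rate, kind = hdr$kind,
                 peak_times = hdr$peak_times),
            class = "physio_trace")
}

# Scoped RNG: draws come from a private stream so callers' RNG state is
# untouched and results depend only on the seed argument.
local_rng <- function(seed) {
  seed <- as.integer(seed)
  env <- new.env()
  run <- function(f, ...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      assign(".state", get(".Random.seed", globalenv()), envir = env)
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    if (exists(".state", env)) assign(".Random.seed", get(".state", env), envir = globalenv())
    else set.seed(seed)
    f(...)
  }
  list(rnorm = function(n, ...) run(stats::rnorm, n, ...),
       runif = function(n, ...) run(stats::runif, n, ...),
       sample = function(x, ...) run(base::sample, x, ...),
       rbinom = function(n, ...) run(stats::rbinom, n, ...))
}
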