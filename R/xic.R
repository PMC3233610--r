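#' Extract an ion chromatogram from a run
#'
#' Sums, per MS1 scan, all centroid intensities within a symmetric ppm window
#' around a target m/z. Scans with no centroid inside the window contribute
#' zero, so the trace always has one point per scan.
#'
#' @param run A [run_data] object.
#' @param target_mz Target m/z in Thomson.
#' @param ppm_window Half-width of the mass window in parts-per-million of
#'   `target_mz` (default 10, typical for Orbitrap-class accuracy).
#' @return An object of class `xic`: a list with `run_id`, `target_mz`,
#'   `ppm_window`, `times` (seconds) and `intensities`.
#' @export
extract_xic <- function(run, target_mz, ppm_window = 10) {
  stopifnot(inherits(run, "run_data"), target_mz > 0, ppm_window > 0)
  half <- target_mz * ppm_window * 1e-6
  lo <- target_mz - half
  hi <- target_mz + half
  ints <- vapply(run$scans, function(s) {
    mz <- s[, 1L]
    sum(s[mz >= lo & mz <= hi, 2L])  # window inclusive on both ends
  }, numeric(1))
  structure(list(run_id = run$run_id, target_mz = target_mz,
                 ppm_window = ppm_window, times = run$times,
                 intensities = ints),
            class = "xic")
}

#' First-isotope m/z of a peptide ion
#'
#' Adds one C13-C12 neutron mass spacing (1.0033548 Da) divided by the charge
#' to the monoisotopic m/z.
#'
#' @param mz_mono Monoisotopic m/z (Th).
#' @param charge Positive integer charge state.
#' @return The m/z of the first isotopologue peak.
#' @export
first_isotope_mz <- function(mz_mono, charge) {
  if (any(charge < 1)) stop("charge must be >= 1", call. = FALSE)
  mz_mono + 1.0033548 / charge
}

#' Robust background-noise estimate for an XIC
#'
#' The noise level is the median of all trace intensities; the noise standard
#' deviation is a MAD-based estimate (1.4826 x median absolute deviation from
#' the level) restricted to points at or below the 90th intensity percentile,
#' so that the elution peaks themselves do not inflate the estimate.
#'
#' @param xic An [extract_xic] trace.
#' @return A list of class `noise_estimate` with fields `level` and `sigma`.
#' @export
estimate_noise <- function(xic) {
  stopifnot(inherits(xic, "xic"), length(xic$intensities) > 0)
  y <- xic$intensities
  level <- stats::median(y)
  sub <- y[y <= stats::quantile(y, 0.9, names = FALSE)]
  sigma <- 1.4826 * stats::median(abs(sub - level))
  structure(list(level = level, sigma = sigma), class = "noise_estimate")
}

new_peak_interval <- function(times, intensities) {
  stopifnot(length(times) > 0, length(times) == length(intensities))
  k <- which.max(intensities)
  structure(list(start_time = times[1L], end_time = times[length(times)],
                 apex_time = times[k], apex_intensity = intensities[k],
                 times = times, intensities = intensities),
            class = "peak_interval")
}

#' @export
print.peak_interval <- function(x, ...) {
  cat(sprintf("peak interval [%.2f, %.2f] s, apex %.2f s @ %.4g\n",
              x$start_time, x$end_time, x$apex_time, x$apex_intensity))
  invisible(x)
}

#' Detect candidate elution-peak intervals in an XIC
#'
#' Applies a threshold of three noise standard deviations above the median
#' noise level; maximal runs of consecutive scans above the threshold become
#' candidate intervals. Runs shorter than `min_points` scans are discarded as
#' spikes; if more than `max_n` intervals remain, the `max_n` with the highest
#' apex intensity are kept.
#'
#' @param xic An [extract_xic] trace.
#' @param noise An [estimate_noise] result (computed from `xic` if missing).
#' @param max_n Maximum number of intervals to return.
#' @param min_points Minimum number of scans per interval.
#' @return List of `peak_interval` objects sorted by start time (possibly
#'   empty).
#' @export
detect_peak_intervals <- function(xic, noise = estimate_noise(xic),
                                  max_n = 20, min_points = 3) {
  stopifnot(inherits(xic, "xic"), max_n >= 1, min_points >= 1)
  thr <- noise$level + 3 * noise$sigma
  above <- xic$intensities > thr
  if (!any(above)) return(list())
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_points
  if (!any(keep)) return(list())
  iv <- mapply(function(s, e) {
    new_peak_interval(xic$times[s:e], xic$intensities[s:e])
  }, starts[keep], ends[keep], SIMPLIFY = FALSE)
  if (length(iv) > max_n) {
    apex <- vapply(iv, `[[`, numeric(1), "apex_intensity")
    iv <- iv[order(apex, decreasing = TRUE)[seq_len(max_n)]]
  }
  iv[order(vapply(iv, `[[`, numeric(1), "start_time"))]
}

#' Candidate corresponding features in an unidentified run
#'
#' All detected peak intervals of the XIC are treated as candidates for the
#' corresponding feature; this is [detect_peak_intervals] under its
#' match-between-runs role.
#'
#' @inheritParams detect_peak_intervals
#' @return List of candidate `peak_interval` objects (empty if nothing is
#'   detected, in which case the peptide is reported unmatched downstream).
#' @export
candidate_features <- function(xic, noise = estimate_noise(xic),
                               max_n = 20, min_points = 3) {
  detect_peak_intervals(xic, noise, max_n = max_n, min_points = min_points)
}

#' Locate the identified feature among detected intervals
#'
#' Selects the interval containing the Tandem-MS retention time; if no
#' interval contains it, falls back to the interval whose apex is nearest,
#' provided the apex is within `rt_tolerance` seconds.
#'
#' @param intervals List of `peak_interval` objects from one XIC.
#' @param rt_sec Identified retention time (seconds).
#' @param rt_tolerance Maximum apex distance for the fallback (seconds).
#' @return The matching `peak_interval`.
#' @export
locate_feature <- function(intervals, rt_sec, rt_tolerance = 60) {
  if (length(intervals) > 0) {
    inside <- vapply(intervals, function(iv)
      iv$start_time <= rt_sec && rt_sec <= iv$end_time, logical(1))
    if (any(inside)) return(intervals[[which(inside)[1L]]])
    d <- abs(vapply(intervals, `[[`, numeric(1), "apex_time") - rt_sec)
    if (min(d) <= rt_tolerance) return(intervals[[which.min(d)]])
  }
  cond <- structure(
    class = c("feature_not_found", "error", "condition"),
    list(message = sprintf("no peak interval within %g s of RT %.1f s",
                           rt_tolerance, rt_sec),
         call = sys.call(-1)))
  stop(cond)
}
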