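#' Tuning parameters for match-between-runs fitting
#'
#' Collects every tunable of the pipeline with its default. Defaults suit
#' Orbitrap-class data: a 10 ppm mass window, up to 20 candidate intervals
#' per XIC, and a probability threshold of 0.95 for the ground-truth list.
#'
#' @param ppm_window XIC mass half-window, ppm of the target m/z.
#' @param max_candidates Maximum detected intervals per XIC.
#' @param min_peak_points Minimum scans per detected interval (suppresses
#'   single-scan spikes).
#' @param rt_tolerance_sec Apex tolerance when locating an identified feature
#'   whose recorded RT falls just outside every detected interval.
#' @param detection_trace Which isotope trace drives detection and shape
#'   comparison: `"iso1"` (first isotope, default — less prone to -1 Da
#'   co-eluting interference), `"mono"`, or `"sum"` of both.
#' @param prob_threshold Minimum identification probability for ground truth.
#' @param train_fraction Fraction of ground truth (top intensities) used for
#'   training.
#' @param min_training_size Below this training size a warning is issued
#'   (pairwise matching in [complete_identification] skips such pairs).
#' @param warp_degree Degree of the warping polynomial.
#' @param ar_grid_points Resampling grid size for the shape R-squared.
#' @param x_floor Lower clamp on 1 - R-squared before Gamma fitting.
#' @param at_landmark Landmark for the RT-shift statistic: `"apex"` or
#'   `"midpoint"`.
#' @return A list of class `mbr_control`.
#' @export
mbr_control <- function(ppm_window = 10,
                        max_candidates = 20,
                        min_peak_points = 3,
                        rt_tolerance_sec = 60,
                        detection_trace = c("iso1", "mono", "sum"),
                        prob_threshold = 0.95,
                        train_fraction = 0.20,
                        min_training_size = 50,
                        warp_degree = 3,
                        ar_grid_points = 50,
                        x_floor = 1e-6,
                        at_landmark = c("apex", "midpoint")) {
  detection_trace <- match.arg(detection_trace)
  at_landmark <- match.arg(at_landmark)
  stopifnot(ppm_window > 0, max_candidates >= 1, min_peak_points >= 1,
            rt_tolerance_sec >= 0, prob_threshold >= 0, prob_threshold <= 1,
            train_fraction > 0, train_fraction <= 1, warp_degree >= 1,
            ar_grid_points >= 5, x_floor > 0, x_floor < 1)
  structure(as.list(environment()), class = "mbr_control")
}

#' Merge a YAML configuration file into a control object
#'
#' Reads a YAML file whose keys are [mbr_control] argument names (unknown
#' keys are rejected) and returns the merged control list. Used by the
#' command-line interface.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param ... Overrides applied after the file.
#' @return An `mbr_control` list.
#' @export
read_control <- function(path = NULL, ...) {
  args <- list()
  if (!is.null(path)) {
    cfg <- yaml::read_yaml(path)
    known <- names(formals(mbr_control))
    bad <- setdiff(names(cfg), known)
    if (length(bad) > 0)
      stop("unknown control key(s) in ", path, ": ",
           paste(bad, collapse = ", "), call. = FALSE)
    args <- cfg
  }
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(mbr_control, args)
}
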