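#' Construct an LC-MS run object
#'
#' A `run_data` object holds the MS1 scans of one LC-MS run: a vector of scan
#' retention times (seconds, strictly increasing) and, per scan, a two-column
#' matrix of centroided peaks (`mz`, `intensity`).
#'
#' @param run_id Character label for the run.
#' @param times Numeric vector of scan retention times in seconds.
#' @param scans List of numeric matrices, one per scan, each with columns
#'   `mz` (ascending) and `intensity` (non-negative counts).
#' @return An object of class `run_data`.
#' @export
run_data <- function(run_id, times, scans) {
  stopifnot(is.character(run_id), length(run_id) == 1L,
            is.numeric(times), is.list(scans), length(times) == length(scans))
  if (length(times) == 0L)
    stop("run '", run_id, "' has no MS1 scans", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE)) {
    warning("scan times in run '", run_id, "' are not strictly increasing; sorting",
            call. = FALSE)
    o <- order(times)
    times <- times[o]
    scans <- scans[o]
  }
  scans <- lapply(scans, function(s) {
    s <- as.matrix(s)
    if (ncol(s) != 2L)
      stop("each scan must be a two-column (mz, intensity) matrix", call. = FALSE)
    colnames(s) <- c("mz", "intensity")
    if (nrow(s) > 1L && is.unsorted(s[, 1L])) s <- s[order(s[, 1L]), , drop = FALSE]
    if (any(s[, 2L] < 0)) stop("negative intensities in scan", call. = FALSE)
    s
  })
  structure(list(run_id = run_id, times = as.numeric(times), scans = scans),
            class = "run_data")
}

#' @export
print.run_data <- function(x, ...) {
  npk <- sum(vapply(x$scans, nrow, integer(1)))
  cat("LC-MS run '", x$run_id, "': ", length(x$times), " MS1 scans, ",
      sprintf("%.1f-%.1f s, ", min(x$times), max(x$times)),
      npk, " centroids\n", sep = "")
  invisible(x)
}

#' @export
length.run_data <- function(x) length(x$times)
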