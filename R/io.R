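#' Read the MS1 scans of an mzML file
#'
#' Reads a centroided mzML file through \pkg{mzR}, keeps MS1 scans only and
#' returns them time-sorted with retention times in seconds (mzR normalises
#' minute-encoded source files to seconds on read).
#'
#' @param path Path to an mzML file.
#' @param run_id Run label; defaults to the file name without extension.
#' @return A [run_data] object.
#' @export
read_mzml <- function(path, run_id = NULL) {
  if (!file.exists(path)) stop("mzML file not found: ", path, call. = FALSE)
  if (is.null(run_id)) run_id <- sub("\\.[^.]+$", "", basename(path))
  ms <- mzR::openMSfile(path)
  on.exit(mzR::close(ms), add = TRUE)
  h <- mzR::header(ms)
  ms1 <- which(h$msLevel == 1L)
  if (length(ms1) == 0L)
    stop("no MS1 spectra in ", path, call. = FALSE)
  pks <- mzR::peaks(ms)
  if (is.matrix(pks)) pks <- list(pks)
  run_data(run_id, times = h$retentionTime[ms1], scans = pks[ms1])
}

.id_cols <- c("sequence", "charge", "mz", "rt_sec", "probability")

#' Read a peptide identification table
#'
#' Tab-separated table with header columns `sequence`, `charge`, `mz`,
#' `rt_sec`, `probability` (the role of a PeptideProphet-style search-engine
#' output: one confident identification per row). Rows whose probability lies
#' outside \[0, 1\] are rejected with a warning.
#'
#' @param path Path to the TSV file.
#' @param run_id Run label attached to every row; defaults to the file name.
#' @return A data frame with the five schema columns plus `run_id`.
#' @export
read_peptide_table <- function(path, run_id = NULL) {
  if (!file.exists(path)) stop("identification table not found: ", path, call. = FALSE)
  if (is.null(run_id)) run_id <- sub("\\.[^.]+$", "", basename(path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(.id_cols, names(df))
  if (length(missing) > 0)
    stop("identification table ", path, " lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df <- df[, .id_cols]
  if (nrow(df) == 0) {
    warning("empty identification table: ", path, call. = FALSE)
  } else {
    bad <- !is.finite(df$probability) | df$probability < 0 | df$probability > 1
    if (any(bad)) {
      warning(sum(bad), " row(s) with probability outside [0, 1] rejected",
              call. = FALSE)
      df <- df[!bad, , drop = FALSE]
    }
  }
  df$charge <- as.integer(df$charge)
  df$run_id <- rep(run_id, nrow(df))
  rownames(df) <- NULL
  df
}

#' Write a peptide identification table
#'
#' Inverse of [read_peptide_table]; used by the synthetic-experiment writer.
#'
#' @param ids Data frame with the identification schema columns.
#' @param path Output TSV path.
#' @export
write_peptide_table <- function(ids, path) {
  stopifnot(all(.id_cols %in% names(ids)))
  utils::write.table(ids[, .id_cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.corr_cols <- c("sequence", "charge", "q1_run", "q1_rt_apex", "q2_run",
                "q2_rt_apex", "q2_interval_start", "q2_interval_end",
                "rt_shift", "shape_r2", "score", "n_candidates")

#' Write a correspondence result table
#'
#' One row per Q1 feature with its selected Q2 feature, the warp-corrected
#' retention-time shift (`rt_shift`, seconds), the peak-shape alignment
#' R-squared (`shape_r2`), the combined likelihood score and the number of
#' candidates considered. Rows are ordered by sequence then charge so output
#' is deterministic; unmatched peptides carry NA in the Q2 columns.
#'
#' @param pairs Data frame of correspondences (see [predict.mbr_fit]).
#' @param path Output TSV path.
#' @export
write_correspondences <- function(pairs, path) {
  if (nrow(pairs) == 0) {
    pairs <- as.data.frame(stats::setNames(
      rep(list(logical(0)), length(.corr_cols)), .corr_cols))
  }
  missing <- setdiff(.corr_cols, names(pairs))
  if (length(missing) > 0)
    stop("correspondence table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  pairs <- pairs[order(pairs$sequence, pairs$charge), .corr_cols, drop = FALSE]
  num <- vapply(pairs, is.double, logical(1))
  pairs[num] <- lapply(pairs[num], function(x) {
    ifelse(is.na(x), NA_character_, sprintf("%.12g", x))
  })
  utils::write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a correspondence result table
#'
#' @param path Path written by [write_correspondences].
#' @return Data frame with the correspondence schema columns.
#' @export
read_correspondences <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(.corr_cols, names(df))
  if (length(missing) > 0)
    stop("not a correspondence table: missing ",
         paste(missing, collapse = ", "), call. = FALSE)
  df
}
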