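#' Collapse repeated identifications of the same peptide ion
#'
#' A peptide ion — a (sequence, charge) pair, with modifications encoded in
#' the sequence string — is often identified by several MS2 spectra in one
#' run. The identification with the highest probability is kept; ties are
#' broken by the earliest retention time so the result is deterministic.
#'
#' @param ids Identification data frame from one run (see
#'   [read_peptide_table]).
#' @return The deduplicated data frame, one row per peptide ion.
#' @export
dedupe_identifications <- function(ids) {
  if (nrow(ids) == 0) return(ids)
  o <- order(ids$sequence, ids$charge, -ids$probability, ids$rt_sec)
  ids <- ids[o, , drop = FALSE]
  keep <- !duplicated(ids[, c("sequence", "charge")])
  out <- ids[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the two-run ground-truth list
#'
#' Peptide ions identified in both runs with probability at or above the
#' threshold in each run form the ground truth used for model training and
#' accuracy evaluation. No retention-time filtering is applied, so outlier
#' identifications are controlled only through the probability threshold
#' (filtering on RT would bias the shift model toward small shifts).
#'
#' @param ids_q1,ids_q2 Deduplicated identification tables of the two runs.
#' @param prob_threshold Minimum identification probability (default 0.95).
#' @return Data frame with columns `sequence`, `charge`, `mz_mono`, `rt_q1`,
#'   `rt_q2`, `probability` (the smaller of the two runs' probabilities) and
#'   `apex_intensity_q1` (NA until features are located).
#' @export
build_ground_truth <- function(ids_q1, ids_q2, prob_threshold = 0.95) {
  stopifnot(prob_threshold >= 0, prob_threshold <= 1)
  f1 <- ids_q1[ids_q1$probability >= prob_threshold, , drop = FALSE]
  f2 <- ids_q2[ids_q2$probability >= prob_threshold, , drop = FALSE]
  gt <- merge(f1, f2, by = c("sequence", "charge"),
              suffixes = c("_q1", "_q2"))
  if (nrow(gt) == 0)
    warning("empty ground-truth list: no shared identifications above p >= ",
            prob_threshold, call. = FALSE)
  out <- data.frame(
    sequence = gt$sequence,
    charge = gt$charge,
    mz_mono = gt$mz_q1,
    rt_q1 = gt$rt_sec_q1,
    rt_q2 = gt$rt_sec_q2,
    probability = pmin(gt$probability_q1, gt$probability_q2),
    apex_intensity_q1 = rep(NA_real_, nrow(gt)),
    stringsAsFactors = FALSE)
  out[order(out$sequence, out$charge), , drop = FALSE]
}

#' Split the ground truth into training and testing sets
#'
#' High-intensity features are least corrupted by noise, so the entries with
#' the top `train_fraction` of Q1 apex intensities form the training set and
#' the remainder the testing set. Intensity ties are broken lexicographically
#' by (sequence, charge) for reproducibility.
#'
#' @param entries Ground-truth data frame with `apex_intensity_q1` filled.
#' @param train_fraction Fraction assigned to training (default 0.20).
#' @param min_training Warn if the training set is smaller than this; reliable
#'   model training wants on the order of 200 shared identifications.
#' @return List of class `train_test_split` with `training` and `testing`
#'   data frames (disjoint, exhaustive).
#' @export
split_train_test <- function(entries, train_fraction = 0.20,
                             min_training = 50) {
  stopifnot(train_fraction >= 0, train_fraction <= 1,
            !anyNA(entries$apex_intensity_q1))
  n <- nrow(entries)
  n_train <- ceiling(train_fraction * n)
  o <- order(-entries$apex_intensity_q1, entries$sequence, entries$charge)
  entries <- entries[o, , drop = FALSE]
  idx <- seq_len(n) <= n_train
  if (n_train < min_training)
    warning("training set has only ", n_train, " entries; around 200 shared ",
            "identifications are preferable for stable models", call. = FALSE)
  structure(list(training = entries[idx, , drop = FALSE],
                 testing = entries[!idx, , drop = FALSE]),
            class = "train_test_split")
}

#' @export
print.train_test_split <- function(x, ...) {
  cat("Ground-truth split:", nrow(x$training), "training /",
      nrow(x$testing), "testing entries\n")
  invisible(x)
}

#' Sample non-corresponding (decoy) pairs from the training set
#'
#' For each training pair with at least two detected Q2 intervals, the true
#' Q2 feature is replaced by a uniformly random *other* interval from the
#' same XIC, yielding a non-corresponding pair from the same chromatographic
#' context. Entries whose XIC holds only the true interval are skipped.
#'
#' @param train_features List of per-entry training features as built by
#'   [mbr_fit]: each element has `q1_feature`, `q2_feature` and `candidates`
#'   (the detected Q2 intervals).
#' @param seed Optional integer seed for the decoy draw.
#' @return List of elements with `q1_feature` and `q2_feature` (the decoy).
#' @export
sample_decoy_pairs <- function(train_features, seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  out <- list()
  for (tf in train_features) {
    others <- Filter(function(iv) !identical_interval(iv, tf$q2_feature),
                     tf$candidates)
    if (length(others) == 0) next
    pick <- others[[sample.int(length(others), 1L)]]
    out[[length(out) + 1L]] <- list(q1_feature = tf$q1_feature,
                                    q2_feature = pick)
  }
  out
}

identical_interval <- function(a, b) {
  isTRUE(all.equal(c(a$start_time, a$end_time), c(b$start_time, b$end_time))) &&
    isTRUE(all.equal(a$apex_time, b$apex_time))
}
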