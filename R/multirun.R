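#' Identification-set cardinalities across runs
#'
#' Standard Venn accounting on (sequence, charge) keys of per-run
#' identification tables: per-run counts, union and intersection sizes, and
#' the pairwise overlap matrix. In typical experiments the intersection is
#' far smaller than the union, which is why identity propagation pays off.
#'
#' @param id_tables List of deduplicated identification data frames.
#' @return List with `per_run`, `union`, `intersection` and `pairwise`
#'   (matrix of pairwise overlap counts).
#' @export
venn_counts <- function(id_tables) {
  keys <- lapply(id_tables, function(df) unique(paste(df$sequence, df$charge)))
  k <- length(keys)
  pairwise <- matrix(0L, k, k)
  for (i in seq_len(k)) for (j in seq_len(k))
    pairwise[i, j] <- length(intersect(keys[[i]], keys[[j]]))
  list(per_run = lengths(keys),
       union = length(Reduce(union, keys)),
       intersection = length(Reduce(intersect, keys)),
       pairwise = pairwise)
}

#' Propagate identifications across runs to complete identification
#'
#' For every peptide ion in the union identification set and every run where
#' it lacks a Tandem-MS identity, attempts to locate its elution peak by
#' likelihood matching from a run where its peak is known. Pairwise models
#' are trained once per unordered run pair on their shared identifications
#' (the reverse direction reuses the same training set via [mbr_reverse]);
#' pairs with too few shared identifications are skipped with a warning.
#' Source runs are tried in order of identification probability (identified
#' sources before propagated ones, higher probability first, then run
#' order), and matching passes repeat until no new peak is located, so a
#' peptide identified in a single run can still reach runs with which that
#' run's pair model is missing, through an intermediate run.
#'
#' @param runs List of [run_data] objects (>= 2).
#' @param id_tables List of per-run identification tables.
#' @param control An [mbr_control]; `min_training_size` is the minimum
#'   number of shared identifications for a pair model to be trained.
#' @param seed Optional integer seed (decoy sampling inside pair training).
#' @return List of class `coverage_result` with `correspondences` (data
#'   frame of all propagated matches), `report` (coverage accounting, see
#'   Details) and `features` (per peptide per run: located interval or NA).
#'
#' @details The report counts peptides completely identified (a located peak
#' interval in every run) and partially identified (in at least two runs).
#' Two coverage denominators are reported: the union minus the full
#' intersection (the set on which propagation has work to do) and the full
#' union.
#' @export
complete_identification <- function(runs, id_tables,
                                    control = mbr_control(), seed = NULL) {
  n_runs <- length(runs)
  stopifnot(n_runs >= 2, length(id_tables) == n_runs)
  ded <- lapply(id_tables, function(df) {
    d <- dedupe_identifications(df)
    d[d$probability >= control$prob_threshold, , drop = FALSE]
  })
  vn <- venn_counts(ded)

  all_keys <- sort(Reduce(union, lapply(ded, function(d)
    unique(paste(d$sequence, d$charge, sep = "\r")))))
  n_pep <- length(all_keys)
  parts <- strsplit(all_keys, "\r", fixed = TRUE)
  sequence <- vapply(parts, `[[`, character(1), 1L)
  charge <- as.integer(vapply(parts, `[[`, character(1), 2L))
  mz <- rep(NA_real_, n_pep)
  prob <- matrix(NA_real_, n_pep, n_runs)
  rt_id <- matrix(NA_real_, n_pep, n_runs)
  for (r in seq_len(n_runs)) {
    idx <- match(paste(ded[[r]]$sequence, ded[[r]]$charge, sep = "\r"),
                 all_keys)
    prob[idx, r] <- ded[[r]]$probability
    rt_id[idx, r] <- ded[[r]]$rt_sec
    mz[idx] <- ded[[r]]$mz
  }

  # candidate intervals per peptide per run, and located identified features
  candidates <- vector("list", n_runs)
  feature <- matrix(list(NULL), n_pep, n_runs)
  for (r in seq_len(n_runs)) {
    side <- prepare_side(runs[[r]], mz, charge,
                         ifelse(is.na(rt_id[, r]), -Inf, rt_id[, r]), control)
    candidates[[r]] <- side$candidates
    for (i in which(!is.na(rt_id[, r])))
      feature[[i, r]] <- side$feature[[i]]
  }

  # pairwise models (one fit per unordered pair, reversed for the other way)
  models <- vector("list", n_runs * n_runs)
  dim(models) <- c(n_runs, n_runs)
  for (i in seq_len(n_runs - 1)) for (j in seq.int(i + 1, n_runs)) {
    common <- vn$pairwise[i, j]
    if (common < control$min_training_size) {
      warning(sprintf(
        "run pair (%s, %s): only %d shared identifications (< %d); pair skipped",
        runs[[i]]$run_id, runs[[j]]$run_id, common,
        control$min_training_size), call. = FALSE)
      next
    }
    m <- tryCatch(
      mbr_fit(runs[[i]], runs[[j]], ded[[i]], ded[[j]], control, seed = seed),
      error = function(e) {
        warning("run pair (", runs[[i]]$run_id, ", ", runs[[j]]$run_id,
                ") could not be trained: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    if (is.null(m)) next
    models[[i, j]] <- m
    models[[j, i]] <- mbr_reverse(m)
  }

  identified_in <- !is.na(prob)
  corr_rows <- list()
  repeat {
    changed <- FALSE
    for (p in seq_len(n_pep)) {
      has <- !vapply(feature[p, ], is.null, logical(1))
      if (all(has) || !any(has)) next
      src_order <- order(!identified_in[p, ], -ifelse(is.na(prob[p, ]), -Inf,
                                                      prob[p, ]),
                         seq_len(n_runs))
      src_order <- src_order[has[src_order]]
      for (t in which(!has)) {
        for (s in src_order) {
          m <- models[[s, t]]
          if (is.null(m)) next
          hit <- match_feature(feature[[p, s]], candidates[[t]][[p]], m)
          if (is.null(hit)) next
          feature[[p, t]] <- hit$q2_feature
          corr_rows[[length(corr_rows) + 1L]] <- data.frame(
            sequence = sequence[p], charge = charge[p],
            q1_run = runs[[s]]$run_id,
            q1_rt_apex = feature[[p, s]]$apex_time,
            q2_run = runs[[t]]$run_id,
            q2_rt_apex = hit$q2_feature$apex_time,
            q2_interval_start = hit$q2_feature$start_time,
            q2_interval_end = hit$q2_feature$end_time,
            rt_shift = hit$shift, shape_r2 = hit$r2, score = hit$score,
            n_candidates = hit$n_candidates, stringsAsFactors = FALSE)
          changed <- TRUE
          break
        }
      }
    }
    if (!changed) break
  }

  n_located <- apply(feature, 1L, function(row)
    sum(!vapply(row, is.null, logical(1))))
  in_all_ids <- rowSums(identified_in) == n_runs
  complete <- n_located == n_runs
  analyzed <- !in_all_ids   # union minus full intersection
  report <- list(
    per_run_identified = vn$per_run,
    union = vn$union,
    intersection = vn$intersection,
    n_analyzed = sum(analyzed),
    completely_identified = sum(complete & analyzed),
    completely_identified_total = sum(complete),
    partially_identified = sum(n_located >= 2 & !complete),
    coverage_analyzed = if (sum(analyzed) > 0)
      sum(complete & analyzed) / sum(analyzed) else NA_real_,
    coverage_union = sum(complete) / vn$union)

  corr <- if (length(corr_rows) > 0)
    do.call(rbind, c(corr_rows, list(make.row.names = FALSE)))
  else
    as.data.frame(stats::setNames(
      rep(list(logical(0)), length(.corr_cols)), .corr_cols))
  structure(list(correspondences = corr[order(corr$sequence, corr$charge,
                                              corr$q2_run), , drop = FALSE],
                 report = report, features = feature,
                 keys = data.frame(sequence = sequence, charge = charge)),
            class = "coverage_result")
}

#' @export
print.coverage_result <- function(x, ...) {
  r <- x$report
  cat("Multi-run identity propagation\n")
  cat("  per-run identified:", paste(r$per_run_identified, collapse = ", "),
      "\n")
  cat("  union:", r$union, " intersection:", r$intersection, "\n")
  cat(sprintf("  completely identified: %d of %d analyzed (%.2f%%)\n",
              r$completely_identified, r$n_analyzed,
              100 * r$coverage_analyzed))
  cat(sprintf("  completely identified in union: %d (%.2f%%); partial: %d\n",
              r$completely_identified_total, 100 * r$coverage_union,
              r$partially_identified))
  invisible(x)
}
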