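#' Fit a match-between-runs correspondence model from two runs
#'
#' Trains the full likelihood matcher on a pair of LC-MS runs with
#' identification tables:
#' \enumerate{
#'   \item builds the ground-truth list of peptide ions identified in both
#'     runs above the probability threshold, locates each entry's elution
#'     peak in both runs from its extracted-ion chromatogram, and splits the
#'     list into a high-intensity training set and a testing set;
#'   \item fits the polynomial retention-time warp (Q1 -> Q2) on the training
#'     pairs' apex times;
#'   \item fits the Gaussian model of the residual (warp-corrected) shifts
#'     and the Gamma model of the peak-shape dissimilarity 1 - R-squared on
#'     the training pairs;
#'   \item samples non-corresponding decoy pairs (random other interval from
#'     the same XIC) and fits the same two models to them for ROC
#'     diagnostics.
#' }
#'
#' @param run_q1,run_q2 [run_data] objects.
#' @param ids_q1,ids_q2 Identification tables of the two runs (see
#'   [read_peptide_table]); deduplicated internally.
#' @param control An [mbr_control] list of tuning parameters.
#' @param seed Optional integer seed for the decoy draw (model fitting itself
#'   is deterministic).
#' @return An object of class `mbr_fit`; see [predict.mbr_fit] for matching,
#'   plus `print`, `summary`, `coef`, `plot`, `residuals` and `simulate`
#'   methods.
#' @export
mbr_fit <- function(run_q1, run_q2, ids_q1, ids_q2,
                    control = mbr_control(), seed = NULL) {
  stopifnot(inherits(run_q1, "run_data"), inherits(run_q2, "run_data"),
            inherits(control, "mbr_control"))
  d1 <- dedupe_identifications(ids_q1)
  d2 <- dedupe_identifications(ids_q2)
  gt <- build_ground_truth(d1, d2, control$prob_threshold)
  if (nrow(gt) < 4)
    stop("ground-truth list too small (", nrow(gt), " shared identifications)",
         call. = FALSE)

  q1_side <- prepare_side(run_q1, gt$mz_mono, gt$charge, gt$rt_q1, control)
  q2_side <- prepare_side(run_q2, gt$mz_mono, gt$charge, gt$rt_q2, control)

  located <- !vapply(q1_side$feature, is.null, logical(1))
  n_dropped <- sum(!located)
  if (n_dropped > 0)
    warning(n_dropped, " ground-truth entr(ies) dropped: no Q1 peak interval ",
            "near the identified RT", call. = FALSE)
  gt <- gt[located, , drop = FALSE]
  q1_side <- lapply(q1_side, function(x) x[located])
  q2_side <- lapply(q2_side, function(x) x[located])
  gt$apex_intensity_q1 <- vapply(q1_side$feature, `[[`, numeric(1),
                                 "apex_intensity")

  split <- split_train_test(gt, control$train_fraction,
                            control$min_training_size)
  key <- paste(gt$sequence, gt$charge)
  tr_idx <- match(paste(split$training$sequence, split$training$charge), key)
  te_idx <- match(paste(split$testing$sequence, split$testing$charge), key)

  train_features <- list()
  for (i in tr_idx) {
    q2f <- tryCatch(
      locate_feature(q2_side$candidates[[i]], gt$rt_q2[i],
                     control$rt_tolerance_sec),
      feature_not_found = function(e) NULL)
    if (is.null(q2f)) next
    train_features[[length(train_features) + 1L]] <- list(
      sequence = gt$sequence[i], charge = gt$charge[i],
      q1_feature = q1_side$feature[[i]], q2_feature = q2f,
      candidates = q2_side$candidates[[i]])
  }
  if (length(train_features) < max(4, control$warp_degree + 1))
    stop("too few training pairs with located features (",
         length(train_features), ")", call. = FALSE)

  t1 <- vapply(train_features, function(f) f$q1_feature$apex_time, numeric(1))
  t2 <- vapply(train_features, function(f) f$q2_feature$apex_time, numeric(1))
  # a high-degree polynomial on few, intensity-selected points extrapolates
  # wildly outside their time span; cap the degree at ~5 points per
  # coefficient so small training sets fall back towards a linear warp
  eff_degree <- min(control$warp_degree,
                    max(1L, (length(t1) - 2L) %/% 5L))
  if (eff_degree < control$warp_degree)
    message("training set of ", length(t1), " pairs: warp degree reduced to ",
            eff_degree)
  warp <- fit_warp(t1, t2, eff_degree)

  pair_stats <- function(pairs) {
    data.frame(
      shift = vapply(pairs, function(f)
        rt_shift(f$q1_feature, f$q2_feature, warp, control$at_landmark),
        numeric(1)),
      r2 = vapply(pairs, function(f)
        shape_r2(f$q1_feature, f$q2_feature, control$ar_grid_points),
        numeric(1)))
  }
  train_stats <- pair_stats(train_features)
  shift_model <- fit_shift_model(train_stats$shift)
  shape_model <- fit_shape_model(train_stats$r2, control$x_floor)

  decoy_pairs <- sample_decoy_pairs(train_features, seed)
  decoy_stats <- if (length(decoy_pairs) > 0) pair_stats(decoy_pairs) else
    data.frame(shift = numeric(0), r2 = numeric(0))
  decoy_models <- list(
    shift = tryCatch(fit_shift_model(decoy_stats$shift),
                     error = function(e) NULL),
    shape = tryCatch(fit_shape_model(decoy_stats$r2, control$x_floor),
                     error = function(e) NULL))

  test_features <- lapply(te_idx, function(i) list(
    sequence = gt$sequence[i], charge = gt$charge[i],
    q1_feature = q1_side$feature[[i]],
    candidates = q2_side$candidates[[i]],
    rt_q2 = gt$rt_q2[i]))

  structure(list(
    run_ids = c(q1 = run_q1$run_id, q2 = run_q2$run_id),
    control = control,
    ground_truth = gt,
    split = split,
    warp = warp,
    shift_model = shift_model,
    shape_model = shape_model,
    decoy_models = decoy_models,
    train_features = train_features,
    train_stats = train_stats,
    decoy_stats = decoy_stats,
    test_features = test_features,
    n_dropped = n_dropped,
    call = match.call()),
    class = "mbr_fit")
}

# per-entry detection XIC, noise, candidate intervals and located feature
prepare_side <- function(run, mz_mono, charge, rt, control) {
  n <- length(mz_mono)
  xics <- vector("list", n); cands <- vector("list", n)
  feats <- vector("list", n)
  for (i in seq_len(n)) {
    x <- detection_xic(run, mz_mono[i], charge[i], control)
    cv <- candidate_features(x, max_n = control$max_candidates,
                             min_points = control$min_peak_points)
    feats[[i]] <- tryCatch(
      locate_feature(cv, rt[i], control$rt_tolerance_sec),
      feature_not_found = function(e) NULL)
    xics[[i]] <- x
    cands[[i]] <- cv
  }
  list(xic = xics, candidates = cands, feature = feats)
}

detection_xic <- function(run, mz_mono, charge, control) {
  iso <- first_isotope_mz(mz_mono, charge)
  switch(control$detection_trace,
    mono = extract_xic(run, mz_mono, control$ppm_window),
    iso1 = extract_xic(run, iso, control$ppm_window),
    sum = {
      a <- extract_xic(run, mz_mono, control$ppm_window)
      b <- extract_xic(run, iso, control$ppm_window)
      a$intensities <- a$intensities + b$intensities
      a
    })
}

#' Match one identified feature against its candidates
#'
#' Computes the residual shift, shape R-squared and likelihood score for
#' every candidate and returns the argmax. Ties are broken by the smaller
#' absolute residual shift, then the earlier apex. The `statistic` argument
#' selects the ranking: the combined likelihood (default), the shift density
#' alone, the shape density alone, or the warping-only nearest-peak baseline.
#'
#' @param q1_feature `peak_interval` of the identified feature in Q1.
#' @param candidates List of candidate `peak_interval`s in Q2.
#' @param model A fitted `mbr_fit` (or equivalent list with `warp`,
#'   `shift_model`, `shape_model`, `control`).
#' @param statistic `"combined"`, `"shift"`, `"shape"` or `"nearest"`.
#' @return A list with `q2_feature`, `shift`, `r2`, `score`, `n_candidates`,
#'   or `NULL` when there are no candidates (unmatched — distinct from a
#'   low-scoring match).
#' @export
match_feature <- function(q1_feature, candidates, model,
                          statistic = c("combined", "shift", "shape",
                                        "nearest")) {
  statistic <- match.arg(statistic)
  if (length(candidates) == 0) return(NULL)
  ctl <- model$control
  shift <- vapply(candidates, function(cv)
    rt_shift(q1_feature, cv, model$warp, ctl$at_landmark), numeric(1))
  r2 <- vapply(candidates, function(cv)
    shape_r2(q1_feature, cv, ctl$ar_grid_points), numeric(1))
  score <- switch(statistic,
    combined = score_pair(shift, r2, model$shift_model, model$shape_model),
    shift = shift_density(model$shift_model, shift),
    shape = shape_density(model$shape_model, r2),
    nearest = -abs(shift))
  best <- which(score == max(score))
  if (length(best) > 1L) {
    d <- abs(shift[best] - model$shift_model$mu)
    best <- best[d == min(d)]
    if (length(best) > 1L) {
      apex <- vapply(candidates[best], `[[`, numeric(1), "apex_time")
      best <- best[which.min(apex)]
    }
  }
  list(q2_feature = candidates[[best]], shift = shift[best], r2 = r2[best],
       score = score_pair(shift[best], r2[best],
                          model$shift_model, model$shape_model),
       n_candidates = length(candidates))
}

#' Predict correspondences for identified features
#'
#' Applies the fitted matcher to a list of prepared features (by default the
#' model's own testing set): each element holds the identified Q1 peak and
#' the candidate Q2 intervals, and the highest-likelihood candidate is
#' reported. Peptides without candidates are returned unmatched (NA columns).
#'
#' @param object A fitted `mbr_fit`.
#' @param features List of elements with `sequence`, `charge`, `q1_feature`
#'   and `candidates`; defaults to the model's testing set.
#' @param statistic Ranking statistic, see [match_feature].
#' @param ... Unused.
#' @return A correspondence data frame (see [write_correspondences]).
#' @export
predict.mbr_fit <- function(object, features = NULL,
                            statistic = c("combined", "shift", "shape",
                                          "nearest"), ...) {
  statistic <- match.arg(statistic)
  if (is.null(features)) features <- object$test_features
  rows <- lapply(features, function(f) {
    m <- match_feature(f$q1_feature, f$candidates, object, statistic)
    if (is.null(m)) {
      data.frame(sequence = f$sequence, charge = f$charge,
                 q1_run = unname(object$run_ids["q1"]),
                 q1_rt_apex = f$q1_feature$apex_time,
                 q2_run = unname(object$run_ids["q2"]),
                 q2_rt_apex = NA_real_, q2_interval_start = NA_real_,
                 q2_interval_end = NA_real_, rt_shift = NA_real_,
                 shape_r2 = NA_real_, score = NA_real_, n_candidates = 0L,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(sequence = f$sequence, charge = f$charge,
                 q1_run = unname(object$run_ids["q1"]),
                 q1_rt_apex = f$q1_feature$apex_time,
                 q2_run = unname(object$run_ids["q2"]),
                 q2_rt_apex = m$q2_feature$apex_time,
                 q2_interval_start = m$q2_feature$start_time,
                 q2_interval_end = m$q2_feature$end_time,
                 rt_shift = m$shift, shape_r2 = m$r2, score = m$score,
                 n_candidates = m$n_candidates, stringsAsFactors = FALSE)
    }
  })
  out <- if (length(rows) > 0)
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  else
    as.data.frame(stats::setNames(
      rep(list(logical(0)), length(.corr_cols)), .corr_cols))
  out[order(out$sequence, out$charge), , drop = FALSE]
}

#' Match a new run pair with a fitted model
#'
#' Pipeline wrapper: locates the identified features of `ids_q1` in
#' `run_q1`, detects candidate intervals in `run_q2` at the same m/z, and
#' scores them with the fitted model. Identifications are deduplicated and
#' filtered at the control's probability threshold first.
#'
#' @param model A fitted `mbr_fit` (or one read by [read_mbr_model]).
#' @param run_q1,run_q2 [run_data] objects.
#' @param ids_q1 Identification table of the Q1 run.
#' @param statistic Ranking statistic, see [match_feature].
#' @return A correspondence data frame.
#' @export
mbr_match <- function(model, run_q1, run_q2, ids_q1,
                      statistic = "combined") {
  ctl <- model$control
  ids <- dedupe_identifications(ids_q1)
  ids <- ids[ids$probability >= ctl$prob_threshold, , drop = FALSE]
  q1_side <- prepare_side(run_q1, ids$mz, ids$charge, ids$rt_sec, ctl)
  located <- !vapply(q1_side$feature, is.null, logical(1))
  if (any(!located))
    warning(sum(!located), " peptide(s) without a locatable Q1 feature skipped",
            call. = FALSE)
  feats <- lapply(which(located), function(i) {
    x2 <- detection_xic(run_q2, ids$mz[i], ids$charge[i], ctl)
    list(sequence = ids$sequence[i], charge = ids$charge[i],
         q1_feature = q1_side$feature[[i]],
         candidates = candidate_features(x2, max_n = ctl$max_candidates,
                                         min_points = ctl$min_peak_points))
  })
  predict(model, features = feats, statistic = statistic)
}

#' Reverse the direction of a fitted pair model
#'
#' Rebuilds the matcher for the Q2 -> Q1 direction from the same training
#' features: the warp is refitted in the reverse direction and the Gaussian
#' shift model on the reversed residuals; the Gamma shape model is shared
#' (shape dissimilarity is symmetric).
#'
#' @param model A fitted `mbr_fit`.
#' @return An `mbr_fit` matching from Q2 into Q1.
#' @export
mbr_reverse <- function(model) {
  tf <- model$train_features
  t1 <- vapply(tf, function(f) f$q1_feature$apex_time, numeric(1))
  t2 <- vapply(tf, function(f) f$q2_feature$apex_time, numeric(1))
  warp_rev <- fit_warp(t2, t1, model$warp$degree)
  shifts_rev <- t1 - polyval_(warp_rev$coefficients, t2)
  out <- model
  out$run_ids <- c(q1 = unname(model$run_ids["q2"]),
                   q2 = unname(model$run_ids["q1"]))
  out$warp <- warp_rev
  out$shift_model <- fit_shift_model(shifts_rev)
  out$train_features <- lapply(tf, function(f)
    list(sequence = f$sequence, charge = f$charge,
         q1_feature = f$q2_feature, q2_feature = f$q1_feature,
         candidates = list(f$q1_feature)))
  out$test_features <- list()
  out
}
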