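#' Accuracy of predicted correspondences against ground truth
#'
#' A prediction is correct when its selected Q2 interval contains the
#' ground-truth Q2 retention time of that peptide ion; an unmatched peptide
#' (no candidates) counts as incorrect, so the denominator is always the
#' full testing set.
#'
#' @param predictions Correspondence data frame (see [predict.mbr_fit]).
#' @param truth Ground-truth data frame with `sequence`, `charge`, `rt_q2`.
#' @return The fraction of correctly matched peptides, with attribute
#'   `n_correct`.
#' @export
match_accuracy <- function(predictions, truth) {
  if (nrow(truth) == 0) stop("empty testing set", call. = FALSE)
  m <- merge(truth[, c("sequence", "charge", "rt_q2")], predictions,
             by = c("sequence", "charge"), all.x = TRUE)
  correct <- !is.na(m$q2_interval_start) &
    m$q2_interval_start <= m$rt_q2 & m$rt_q2 <= m$q2_interval_end
  acc <- sum(correct) / nrow(truth)
  attr(acc, "n_correct") <- sum(correct)
  acc
}

roc_table <- function(scores_pos, scores_neg) {
  if (length(scores_pos) < 10 || length(scores_neg) < 10)
    warning("fewer than 10 scores in a class: ROC curve unreliable",
            call. = FALSE)
  thr <- c(Inf, sort(unique(c(scores_pos, scores_neg)), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores_pos >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores_neg >= t), numeric(1))
  o <- order(fpr, tpr)
  data.frame(threshold = thr[o], fpr = fpr[o], tpr = tpr[o])
}

trapezoid_auc <- function(fpr, tpr) {
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' ROC curves of the three ranking statistics
#'
#' Sweeps a threshold over the scores of corresponding versus
#' non-corresponding (decoy) pairs for each of the three statistics — the
#' shift density alone, the shape density alone, and the combined likelihood
#' — and reports (FPR, TPR) points with trapezoidal AUCs. Called on a fitted
#' model it uses the stored training and decoy pairs; statistic data frames
#' (columns `shift`, `r2`) can also be supplied directly.
#'
#' @param model A fitted `mbr_fit`.
#' @param corr,noncorr Optional data frames of statistics for corresponding
#'   and non-corresponding pairs; default to the model's stored training and
#'   decoy statistics.
#' @return List with `curves` (data frame: `statistic`, `threshold`, `fpr`,
#'   `tpr`, sorted by FPR within statistic) and `auc` (named vector).
#' @export
roc_curves <- function(model, corr = model$train_stats,
                       noncorr = model$decoy_stats) {
  stopifnot(nrow(corr) > 0, nrow(noncorr) > 0)
  score_sets <- list(
    shift = list(pos = shift_density(model$shift_model, corr$shift),
                 neg = shift_density(model$shift_model, noncorr$shift)),
    shape = list(pos = shape_density(model$shape_model, corr$r2),
                 neg = shape_density(model$shape_model, noncorr$r2)),
    combined = list(
      pos = score_pair(corr$shift, corr$r2, model$shift_model,
                       model$shape_model),
      neg = score_pair(noncorr$shift, noncorr$r2, model$shift_model,
                       model$shape_model)))
  curves <- do.call(rbind, lapply(names(score_sets), function(st) {
    tab <- roc_table(score_sets[[st]]$pos, score_sets[[st]]$neg)
    cbind(statistic = st, tab)
  }))
  auc <- vapply(names(score_sets), function(st) {
    tab <- curves[curves$statistic == st, ]
    trapezoid_auc(tab$fpr, tab$tpr)
  }, numeric(1))
  list(curves = curves, auc = auc)
}
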