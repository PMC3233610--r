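#' @export
print.mbr_fit <- function(x, ...) {
  cat("Match-between-runs model: ", x$run_ids["q1"], " -> ", x$run_ids["q2"],
      "\n", sep = "")
  cat("  ground truth:", nrow(x$ground_truth), "shared peptide ions (",
      nrow(x$split$training), "training /", nrow(x$split$testing),
      "testing )\n")
  cat("  warp: degree", x$warp$degree, "polynomial, residual SD",
      sprintf("%.3f s", stats::sd(residuals(x$warp))), "\n")
  cat(sprintf("  residual shift ~ Normal(%.3f, %.3f^2) s\n",
              x$shift_model$mu, x$shift_model$sigma))
  cat(sprintf("  shape dissimilarity 1 - R2 ~ Gamma(k = %.3f, theta = %.4g)\n",
              x$shape_model$k, x$shape_model$theta))
  invisible(x)
}

#' @export
coef.mbr_fit <- function(object, ...) {
  w <- object$warp$coefficients
  names(w) <- paste0("warp_t^", seq.int(object$warp$degree, 0))
  c(w, shift_mu = object$shift_model$mu, shift_sigma = object$shift_model$sigma,
    shape_k = object$shape_model$k, shape_theta = object$shape_model$theta)
}

#' @export
residuals.mbr_fit <- function(object, ...) object$train_stats$shift

#' Summary of a match-between-runs model
#'
#' Adds to [print.mbr_fit] the decoy (non-corresponding) model parameters,
#' the Kolmogorov-Smirnov separation between corresponding and decoy
#' statistics, and the candidate-count distribution of the testing set.
#'
#' @param object A fitted `mbr_fit`.
#' @param ... Unused.
#' @return An object of class `summary.mbr_fit`.
#' @export
summary.mbr_fit <- function(object, ...) {
  ks <- function(a, b) {
    if (length(a) < 2 || length(b) < 2) return(NA_real_)
    unname(suppressWarnings(stats::ks.test(a, b)$statistic))
  }
  n_cand <- vapply(object$test_features, function(f) length(f$candidates),
                   integer(1))
  structure(list(
    fit = object,
    ks_shift = ks(object$train_stats$shift, object$decoy_stats$shift),
    ks_r2 = ks(object$train_stats$r2, object$decoy_stats$r2),
    n_decoys = nrow(object$decoy_stats),
    n_dropped = object$n_dropped,
    candidate_summary = if (length(n_cand)) summary(n_cand) else NULL),
    class = "summary.mbr_fit")
}

#' @export
print.summary.mbr_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  separation (KS, corresponding vs %d decoy pairs): shift %.3f, shape R2 %.3f\n",
              x$n_decoys, x$ks_shift, x$ks_r2))
  if (!is.null(x$candidate_summary)) {
    cat("  candidates per testing peptide:\n")
    print(x$candidate_summary)
  }
  if (x$n_dropped > 0)
    cat("  dropped (no locatable Q1 feature):", x$n_dropped, "\n")
  invisible(x)
}

#' Simulate statistic pairs from a fitted model
#'
#' Draws residual shifts from the fitted Gaussian and shape R-squared values
#' from the fitted Gamma of 1 - R-squared (clamped to \[0, 1\]); useful for
#' posterior-predictive style checks of the two marginal models.
#'
#' @param object A fitted `mbr_fit`.
#' @param nsim Number of pairs to draw.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return Data frame with columns `shift` and `r2`.
#' @export
simulate.mbr_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  shift <- stats::rnorm(nsim, object$shift_model$mu, object$shift_model$sigma)
  x <- stats::rgamma(nsim, shape = object$shape_model$k,
                     scale = object$shape_model$theta)
  data.frame(shift = shift, r2 = pmin(pmax(1 - x, 0), 1))
}

#' Diagnostic plots for a match-between-runs model
#'
#' Four base-graphics panels: the warp with its training pairs; histograms of
#' the corresponding-pair residual shifts and shape dissimilarities with the
#' fitted densities (decoy densities dashed, when available); and the ROC
#' curves of the three ranking statistics.
#'
#' @param x A fitted `mbr_fit`.
#' @param ... Unused.
#' @export
plot.mbr_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op), add = TRUE)

  w <- x$warp
  graphics::plot(w$t_q1, w$t_q2, pch = 16, cex = 0.5,
                 xlab = "Q1 apex time (s)", ylab = "Q2 apex time (s)",
                 main = "Retention-time warp")
  tt <- seq(w$domain[1], w$domain[2], length.out = 200)
  graphics::lines(tt, polyval_(w$coefficients, tt), col = "red")

  s <- x$train_stats$shift
  graphics::hist(s, breaks = "FD", freq = FALSE,
                 xlab = "residual shift (s)", main = "Residual shift model")
  ss <- seq(min(s), max(s), length.out = 200)
  graphics::lines(ss, shift_density(x$shift_model, ss), col = "red")
  if (!is.null(x$decoy_models$shift))
    graphics::lines(ss, shift_density(x$decoy_models$shift, ss),
                    col = "blue", lty = 2)

  xx <- pmax(1 - x$train_stats$r2, x$control$x_floor)
  graphics::hist(xx, breaks = "FD", freq = FALSE, xlab = "1 - R2",
                 main = "Shape dissimilarity model")
  gx <- seq(1e-4, max(xx), length.out = 200)
  graphics::lines(gx, stats::dgamma(gx, shape = x$shape_model$k,
                                    scale = x$shape_model$theta), col = "red")

  rc <- roc_curves(x)
  cols <- c(combined = "black", shift = "red", shape = "blue")
  graphics::plot(NA, xlim = 0:1, ylim = 0:1, xlab = "false positive rate",
                 ylab = "true positive rate", main = "ROC")
  for (st in names(cols)) {
    cur <- rc$curves[rc$curves$statistic == st, ]
    graphics::lines(cur$fpr, cur$tpr, col = cols[st])
  }
  graphics::abline(0, 1, lty = 3)
  graphics::legend("bottomright", bty = "n", lty = 1, col = cols,
                   legend = sprintf("%s (AUC %.3f)", names(cols),
                                    rc$auc[names(cols)]))
  invisible(x)
}

#' Save a fitted model to a human-readable file
#'
#' Serialises the trained parameter set (warp polynomial, Gaussian shift
#' model, Gamma shape model and the control list) to YAML at full double
#' precision. The saved file is sufficient for matching with [mbr_match];
#' training data and diagnostics are not stored.
#'
#' @param model A fitted `mbr_fit`.
#' @param path Output YAML path.
#' @export
write_mbr_model <- function(model, path) {
  obj <- list(
    run_ids = as.list(model$run_ids),
    warp = list(coefficients = model$warp$coefficients,
                degree = model$warp$degree,
                domain = model$warp$domain),
    shift = list(mu = model$shift_model$mu, sigma = model$shift_model$sigma,
                 n = model$shift_model$n),
    shape = list(k = model$shape_model$k, theta = model$shape_model$theta,
                 x_floor = model$shape_model$x_floor, n = model$shape_model$n),
    control = unclass(model$control))
  writeLines(yaml::as.yaml(obj, precision = 17), path)
  invisible(path)
}

#' Load a fitted model saved by [write_mbr_model]
#'
#' @param path YAML model file.
#' @return A lightweight `mbr_fit` usable with [mbr_match] and
#'   [match_feature] (no stored training data).
#' @export
read_mbr_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  obj <- yaml::read_yaml(path)
  for (f in c("warp", "shift", "shape", "control"))
    if (is.null(obj[[f]])) stop("not a model file (missing '", f, "'): ",
                                path, call. = FALSE)
  warp <- structure(list(
    coefficients = as.numeric(obj$warp$coefficients),
    degree = obj$warp$degree, domain = as.numeric(obj$warp$domain),
    t_q1 = numeric(0), t_q2 = numeric(0), fitted = numeric(0)),
    class = "warp_model")
  structure(list(
    run_ids = c(q1 = obj$run_ids$q1, q2 = obj$run_ids$q2),
    control = do.call(mbr_control, obj$control),
    warp = warp,
    shift_model = structure(list(mu = obj$shift$mu, sigma = obj$shift$sigma,
                                 n = obj$shift$n), class = "shift_model"),
    shape_model = structure(list(k = obj$shape$k, theta = obj$shape$theta,
                                 x_floor = obj$shape$x_floor,
                                 n = obj$shape$n), class = "shape_model"),
    train_features = list(), test_features = list()),
    class = "mbr_fit")
}
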