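#' Warp-corrected retention-time shift between two features
#'
#' The residual elution-time shift of a candidate pair after mean-shift
#' correction: the Q2 landmark time minus the warped Q1 landmark time.
#' The landmark is the peak apex by default (the sharpest landmark of an
#' elution peak); interval midpoints are available as an alternative.
#'
#' @param q1_feature,q2_feature `peak_interval` objects.
#' @param warp A fitted `warp_model` (Q1 -> Q2).
#' @param landmark `"apex"` (default) or `"midpoint"`.
#' @return Residual shift in seconds.
#' @export
rt_shift <- function(q1_feature, q2_feature, warp,
                     landmark = c("apex", "midpoint")) {
  landmark <- match.arg(landmark)
  lm_of <- function(f) {
    if (landmark == "apex") f$apex_time else (f$start_time + f$end_time) / 2
  }
  lm_of(q2_feature) - polyval_(warp$coefficients, lm_of(q1_feature))
}

#' Peak-shape alignment R-squared of two elution peaks
#'
#' Each peak trace is linearly interpolated onto `n_grid` equally spaced
#' points spanning its own detected interval (boundary to boundary, so the
#' comparison is shape-only and independent of retention-time shift), and the
#' resampled Q2 vector is regressed on the resampled Q1 vector by simple
#' linear regression with intercept. The returned coefficient of
#' determination, 1 - SS_res/SS_tot, is clamped to \[0, 1\]; a value of 1
#' means identical shapes up to an affine intensity transform, so large
#' concentration fold changes between runs do not degrade it.
#'
#' @param q1_feature,q2_feature `peak_interval` objects with at least 3 trace
#'   points each.
#' @param n_grid Number of resampling points (default 50).
#' @return The alignment R-squared in \[0, 1\].
#' @export
shape_r2 <- function(q1_feature, q2_feature, n_grid = 50) {
  stopifnot(n_grid >= 5)
  x <- resample_trace(q1_feature, n_grid)
  y <- resample_trace(q2_feature, n_grid)
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  if (syy == 0) {
    warning("zero-variance peak trace: alignment R-squared undefined, returning 0",
            call. = FALSE)
    return(0)
  }
  if (sxx == 0) return(0)  # flat predictor: regression explains nothing
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  min(max(sxy^2 / (sxx * syy), 0), 1)
}

resample_trace <- function(feature, n_grid) {
  if (length(feature$times) < 2)
    stop("peak trace needs >= 2 points to resample", call. = FALSE)
  grid <- seq(feature$start_time, feature$end_time, length.out = n_grid)
  stats::approx(feature$times, feature$intensities, xout = grid, rule = 2)$y
}

#' Fit the Gaussian model of residual retention-time shifts
#'
#' Corresponding features, after warping, retain a random residual shift that
#' is modelled as Gaussian. Parameters are the sample mean and the unbiased
#' (n-1) sample standard deviation of the training shifts.
#'
#' @param shifts Numeric vector of residual shifts (seconds), at least two
#'   distinct values.
#' @return An object of class `shift_model` with fields `mu` and `sigma`.
#' @export
fit_shift_model <- function(shifts) {
  shifts <- shifts[is.finite(shifts)]
  if (length(unique(shifts)) < 2)
    stop("need >= 2 distinct shifts to fit the Gaussian model (sigma would be 0)",
         call. = FALSE)
  structure(list(mu = mean(shifts), sigma = stats::sd(shifts),
                 n = length(shifts)),
            class = "shift_model")
}

#' @export
print.shift_model <- function(x, ...) {
  cat(sprintf("Residual RT-shift model: Normal(mu = %.3f s, sigma = %.3f s), n = %d\n",
              x$mu, x$sigma, x$n))
  invisible(x)
}

#' Gaussian density of a residual shift
#'
#' @param model A `shift_model`.
#' @param shift Residual shift(s) in seconds.
#' @return Density value(s).
#' @export
shift_density <- function(model, shift) {
  stats::dnorm(shift, mean = model$mu, sd = model$sigma)
}

#' Fit the Gamma model of peak-shape dissimilarity
#'
#' The shape dissimilarity X = 1 - R-squared of corresponding peaks
#' concentrates near zero with a right tail and is modelled as
#' Gamma(shape k, scale theta). Values are clamped below at `x_floor` before
#' maximum-likelihood fitting so that near-perfect shape agreement (R-squared
#' of exactly 1) cannot drive the likelihood to a degenerate spike at zero.
#' The MLE is computed on mean-scaled data (the Gamma family is scale
#' equivariant) for numerical stability.
#'
#' @param r2 Numeric vector of alignment R-squared values in \[0, 1\].
#' @param x_floor Lower clamp for X = 1 - r2 (default 1e-6).
#' @return An object of class `shape_model` with fields `k` (shape), `theta`
#'   (scale) and `x_floor`.
#' @export
fit_shape_model <- function(r2, x_floor = 1e-6) {
  stopifnot(x_floor > 0, x_floor < 1)
  r2 <- r2[is.finite(r2)]
  x <- pmax(1 - r2, x_floor)
  if (length(unique(x)) < 2)
    stop("need >= 2 distinct shape-dissimilarity values to fit the Gamma model ",
         "(all R-squared at/above 1 - x_floor is degenerate)", call. = FALSE)
  m <- mean(x)
  fit <- MASS::fitdistr(x / m, "gamma", lower = c(1e-8, 1e-8))
  k <- unname(fit$estimate["shape"])
  theta <- m / unname(fit$estimate["rate"])
  structure(list(k = k, theta = theta, x_floor = x_floor, n = length(x)),
            class = "shape_model")
}

#' @export
print.shape_model <- function(x, ...) {
  cat(sprintf(
    "Peak-shape dissimilarity model: 1 - R2 ~ Gamma(k = %.3f, theta = %.4g), n = %d\n",
    x$k, x$theta, x$n))
  invisible(x)
}

#' Gamma density of a peak-shape R-squared value
#'
#' Evaluates the fitted Gamma density at X = max(1 - r2, x_floor).
#'
#' @param model A `shape_model`.
#' @param r2 Alignment R-squared value(s).
#' @return Density value(s).
#' @export
shape_density <- function(model, r2) {
  stats::dgamma(pmax(1 - r2, model$x_floor), shape = model$k,
                scale = model$theta)
}

#' Combined likelihood score of a candidate pair
#'
#' The two statistics are treated as independent, so the likelihood that a
#' pair with residual shift `shift` and shape agreement `r2` is corresponding
#' is the product of the Gaussian shift density and the Gamma shape density.
#' Densities (not normalised probabilities) are multiplied; no normalisation
#' across candidates is applied.
#'
#' @param shift Residual RT shift (seconds).
#' @param r2 Alignment R-squared.
#' @param shift_model A fitted `shift_model`.
#' @param shape_model A fitted `shape_model`.
#' @return Non-negative likelihood score(s).
#' @export
score_pair <- function(shift, r2, shift_model, shape_model) {
  shift_density(shift_model, shift) * shape_density(shape_model, r2)
}
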