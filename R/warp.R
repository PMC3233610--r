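#' Fit a ground-truth-based retention-time warping polynomial
#'
#' Least-squares polynomial regression of run-2 elution times on run-1
#' elution times, fitted to identified time pairs shared by the two runs.
#' This corrects the mean elution-time shift between runs; residual shifts
#' around the warp are modelled separately (see [fit_shift_model]). The
#' warp is typically smooth and mildly non-linear, so a low polynomial
#' degree suffices; on rank deficiency the degree is reduced automatically.
#'
#' @param t_q1,t_q2 Numeric vectors of paired elution times (seconds) in the
#'   reference run (Q1) and the target run (Q2).
#' @param degree Polynomial degree (default 3).
#' @return An object of class `warp_model` with `coefficients` (highest
#'   degree first), `degree` and `domain` (range of the training `t_q1`).
#' @examples
#' w <- fit_warp(c(0, 10, 20), c(5, 25, 45), degree = 1)
#' coef(w)           # slope 2, intercept 5
#' predict(w, 10)    # 25
#' @export
fit_warp <- function(t_q1, t_q2, degree = 3) {
  stopifnot(length(t_q1) == length(t_q2))
  ok <- is.finite(t_q1) & is.finite(t_q2)
  t_q1 <- t_q1[ok]; t_q2 <- t_q2[ok]
  if (length(t_q1) < 2) stop("need at least 2 time pairs to fit a warp", call. = FALSE)
  max_deg <- length(unique(t_q1)) - 1L
  if (degree > max_deg) {
    warning("only ", max_deg + 1L, " distinct time points; reducing warp ",
            "degree to ", max_deg, call. = FALSE)
    degree <- max_deg
  }
  repeat {
    X <- outer(t_q1, degree:0, `^`)
    fit <- stats::lm.fit(X, t_q2)
    if (!anyNA(fit$coefficients) && fit$rank == degree + 1L) break
    if (degree == 0L) break
    warning("rank-deficient warp fit; reducing degree to ", degree - 1L,
            call. = FALSE)
    degree <- degree - 1L
  }
  structure(list(coefficients = unname(fit$coefficients), degree = degree,
                 domain = range(t_q1), t_q1 = t_q1, t_q2 = t_q2,
                 fitted = unname(fit$fitted.values)),
            class = "warp_model")
}

polyval_ <- function(coefficients, t) {
  y <- rep(coefficients[1L], length(t))
  for (c_i in coefficients[-1L]) y <- y * t + c_i
  y
}

#' Map run-1 times into run-2 time coordinates
#'
#' @param object A `warp_model`.
#' @param t Numeric vector of run-1 times (seconds). Values outside the
#'   training domain are extrapolated (polynomials extrapolate smoothly over
#'   modest overhangs; a message notes it).
#' @param ... Unused.
#' @return Predicted run-2 times (seconds).
#' @export
predict.warp_model <- function(object, t, ...) {
  if (missing(t)) return(object$fitted)
  outside <- t < object$domain[1L] | t > object$domain[2L]
  if (any(outside, na.rm = TRUE))
    message(sum(outside), " time(s) outside the warp training domain [",
            sprintf("%.1f, %.1f", object$domain[1L], object$domain[2L]),
            "] s; extrapolating")
  polyval_(object$coefficients, t)
}

#' Apply a warp model to run-1 times
#'
#' Functional alias for [predict.warp_model].
#' @inheritParams predict.warp_model
#' @export
apply_warp <- function(object, t) predict(object, t)

#' @export
coef.warp_model <- function(object, ...) object$coefficients

#' @export
residuals.warp_model <- function(object, ...) object$t_q2 - object$fitted

#' @export
print.warp_model <- function(x, ...) {
  cat("Retention-time warp: degree", x$degree, "polynomial on",
      length(x$t_q1), "time pairs\n")
  cat("  coefficients (highest first):",
      paste(signif(x$coefficients, 6), collapse = ", "), "\n")
  cat(sprintf("  domain: [%.1f, %.1f] s, residual SD %.3f s\n",
              x$domain[1L], x$domain[2L], stats::sd(residuals(x))))
  invisible(x)
}

#' Nearest-peak baseline match after warping
#'
#' The warping-only baseline: maps the Q1 feature apex into Q2 time and picks
#' the candidate whose apex is closest to the mapped time. Ties go to the
#' earlier apex.
#'
#' @param q1_feature A `peak_interval` in Q1.
#' @param candidates List of candidate `peak_interval`s in Q2.
#' @param warp A fitted `warp_model` (Q1 -> Q2).
#' @return The selected candidate, or `NULL` if `candidates` is empty.
#' @export
nearest_warp_match <- function(q1_feature, candidates, warp) {
  if (length(candidates) == 0) return(NULL)
  mapped <- polyval_(warp$coefficients, q1_feature$apex_time)
  apex <- vapply(candidates, `[[`, numeric(1), "apex_time")
  d <- abs(apex - mapped)
  best <- which(d == min(d))
  if (length(best) > 1L) best <- best[which.min(apex[best])]
  candidates[[best]]
}
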