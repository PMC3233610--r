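mini_model <- function(mu = 0, sigma = 3, k = 2, theta = 0.05) {
  list(warp = fit_warp(c(0, 500), c(0, 500), degree = 1),
       shift_model = structure(list(mu = mu, sigma = sigma, n = 0),
                               class = "shift_model"),
       shape_model = structure(list(k = k, theta = theta, x_floor = 1e-6,
                                    n = 0), class = "shape_model"),
       control = mbr_control())
}

test_that("match_feature returns the maximum-likelihood candidate", {
  m <- mini_model()
  q1 <- make_emg_iv(3, 1.5, apex = 100)
  good <- make_emg_iv(3, 1.5, apex = 101)          # same shape, small shift
  bad <- make_emg_iv(1.2, 4, apex = 100 + 5 * 3)   # 5 sigma away, odd shape

  hit <- match_feature(q1, list(bad, good), m)
  expect_equal(hit$q2_feature$apex_time, good$apex_time)
  expect_equal(hit$n_candidates, 2L)
  expect_equal(hit$score,
               score_pair(hit$shift, hit$r2, m$shift_model, m$shape_model))

  single <- match_feature(q1, list(bad), m)
  expect_equal(single$q2_feature$apex_time, bad$apex_time)
  expect_null(match_feature(q1, list(), m))
})

test_that("the argmax is invariant to monotone score transforms", {
  m <- mini_model()
  set.seed(23)
  q1 <- make_emg_iv(3, 1.5, apex = 200)
  for (rep in 1:15) {
    cands <- lapply(1:4, function(i)
      make_emg_iv(runif(1, 1, 4), runif(1, 0.5, 3),
                  apex = 200 + rnorm(1, 0, 6)))
    hit <- match_feature(q1, cands, m)
    log_scores <- vapply(cands, function(cv) {
      s <- rt_shift(q1, cv, m$warp)
      r <- shape_r2(q1, cv, 50)
      log(shift_density(m$shift_model, s)) +
        log(shape_density(m$shape_model, r))
    }, numeric(1))
    expect_equal(hit$q2_feature$apex_time,
                 cands[[which.max(log_scores)]]$apex_time)
  }
})

test_that("accuracy is correct-containment over the full testing set", {
  truth <- data.frame(sequence = sprintf("P%03d", 1:144), charge = 2L,
                      rt_q2 = seq(100, by = 10, length.out = 144))
  pred <- data.frame(sequence = truth$sequence, charge = truth$charge,
                     q2_interval_start = truth$rt_q2 - 5,
                     q2_interval_end = truth$rt_q2 + 5)
  expect_equal(as.numeric(match_accuracy(pred, truth)), 1.0)

  # 95 of 144 correct; the rest point at intervals missing the truth
  pred$q2_interval_start[96:144] <- pred$q2_interval_start[96:144] + 100
  pred$q2_interval_end[96:144] <- pred$q2_interval_end[96:144] + 100
  acc <- match_accuracy(pred, truth)
  expect_equal(as.numeric(acc), 95 / 144, tolerance = 1e-12)
  expect_equal(attr(acc, "n_correct"), 95L)

  # unmatched predictions count in the denominator as errors
  pred$q2_interval_start[1:10] <- NA
  expect_equal(as.numeric(match_accuracy(pred, truth)), 85 / 144)
  expect_error(match_accuracy(pred, truth[0, ]), "empty")
})

test_that("scrambled candidate choice gives chance-level accuracy", {
  ex <- default_experiment()
  fit <- default_fit()
  te <- testing_truth(fit, ex)
  feats <- Filter(function(f) length(f$candidates) >= 2, fit$test_features)
  set.seed(77)
  rows <- lapply(feats, function(f) {
    cv <- f$candidates[[sample.int(length(f$candidates), 1)]]
    data.frame(sequence = f$sequence, charge = f$charge,
               q2_interval_start = cv$start_time,
               q2_interval_end = cv$end_time)
  })
  pred <- do.call(rbind, rows)
  truth <- te[paste(te$sequence, te$charge) %in%
                paste(pred$sequence, pred$charge), ]
  acc <- as.numeric(match_accuracy(pred, truth))
  chance <- mean(1 / vapply(feats, function(f) length(f$candidates), 1L))
  se <- sqrt(chance * (1 - chance) / nrow(truth))
  expect_lt(abs(acc - chance), 4 * se + 0.02)
})

test_that("ROC curves behave at the separability extremes", {
  expect_warning(sep <- mbralign:::roc_table(101:150, 1:9), "fewer than 10")
  expect_equal(mbralign:::trapezoid_auc(sep$fpr, sep$tpr), 1.0)

  same <- mbralign:::roc_table(1:200, 1:200)
  expect_equal(mbralign:::trapezoid_auc(same$fpr, same$tpr), 0.5,
               tolerance = 0.01)
})

test_that("roc_curves agrees with an independent ROC implementation", {
  fit <- default_fit()
  rc <- roc_curves(fit)
  expect_setequal(unique(rc$curves$statistic),
                  c("shift", "shape", "combined"))
  expect_true(all(rc$auc >= 0 & rc$auc <= 1))
  expect_true(all(diff(rc$curves$fpr[rc$curves$statistic == "combined"]) >= 0))

  pos <- score_pair(fit$train_stats$shift, fit$train_stats$r2,
                    fit$shift_model, fit$shape_model)
  neg <- score_pair(fit$decoy_stats$shift, fit$decoy_stats$r2,
                    fit$shift_model, fit$shape_model)
  ref <- suppressMessages(pROC::auc(
    response = c(rep(1, length(pos)), rep(0, length(neg))),
    predictor = c(pos, neg), direction = "<"))
  expect_equal(unname(rc$auc["combined"]), as.numeric(ref), tolerance = 1e-9)
})

test_that("empirical AUC matches the quadrature AUC of the model ROC", {
  # rank by the corresponding-model density, as the matcher does
  mu1 <- 0; s1 <- 3; mu2 <- 10; s2 <- 6
  dens <- function(x) dnorm(x, mu1, s1)
  grid <- seq(-40, 60, length.out = 20001)
  w <- diff(grid[1:2])
  dpos <- dnorm(grid, mu1, s1); dneg <- dnorm(grid, mu2, s2)
  sc <- dens(grid)
  thr <- sort(unique(sc), decreasing = TRUE)
  tpr <- vapply(thr, function(ct) sum(dpos[sc >= ct]) * w, numeric(1))
  fpr <- vapply(thr, function(ct) sum(dneg[sc >= ct]) * w, numeric(1))
  o <- order(fpr, tpr)
  auc_quad <- mbralign:::trapezoid_auc(c(0, fpr[o], 1), c(0, tpr[o], 1))

  set.seed(41)
  pos <- dens(rnorm(2000, mu1, s1))
  neg <- dens(rnorm(2000, mu2, s2))
  tab <- mbralign:::roc_table(pos, neg)
  auc_emp <- mbralign:::trapezoid_auc(tab$fpr, tab$tpr)
  expect_lt(abs(auc_emp - auc_quad), 0.02)
})
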