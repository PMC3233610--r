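test_that("rt_shift is the Q2 apex minus the warped Q1 apex", {
  ident <- fit_warp(c(0, 100), c(0, 100), degree = 1)
  f1 <- make_iv(95:105, c(1:6, 5:1))    # apex 100
  f2 <- make_iv(98:108, c(1:6, 5:1))    # apex 103
  expect_equal(rt_shift(f1, f2, ident), 3)

  w25 <- fit_warp(c(0, 10), c(5, 25), degree = 1)  # t2 = 2 t1 + 5
  g1 <- make_iv(5:15, c(1:6, 5:1))      # apex 10 -> mapped 25
  g2 <- make_iv(20:30, c(1:6, 5:1))     # apex 25
  expect_equal(rt_shift(g1, g2, w25), 0)

  # swap-and-invert antisymmetry on a unit-slope line, scaled for slope a
  set.seed(13)
  for (rep in 1:10) {
    a <- sample(c(1, 1, 2, 0.5), 1)
    b <- runif(1, -20, 20)
    t1 <- runif(1, 50, 200)
    t2 <- a * t1 + b + rnorm(1, 0, 5)
    fw <- fit_warp(c(0, 300), a * c(0, 300) + b, degree = 1)
    bw <- fit_warp(a * c(0, 300) + b, c(0, 300), degree = 1)
    p1 <- make_iv(t1 + (-2:2), c(1, 2, 5, 2, 1))
    p2 <- make_iv(t2 + (-2:2), c(1, 2, 5, 2, 1))
    r_fwd <- rt_shift(p1, p2, fw)
    r_rev <- rt_shift(p2, p1, bw)
    expect_equal(r_rev, -r_fwd / a, tolerance = 1e-9)
    if (a == 1) expect_equal(r_rev, -r_fwd, tolerance = 1e-9)
  }
})

test_that("shape_r2 equals the least-squares R2 and is affine invariant", {
  # identical traces and 50-fold scaling are perfect matches
  a <- make_emg_iv(3, 2)
  expect_equal(shape_r2(a, a), 1)
  a50 <- a
  a50$intensities <- a50$intensities * 50
  a50$apex_intensity <- a50$apex_intensity * 50
  expect_equal(shape_r2(a, a50), 1, tolerance = 1e-12)

  # closed-form least-squares oracle on random resampled pairs
  set.seed(17)
  for (rep in 1:40) {
    p <- make_emg_iv(runif(1, 1, 4), runif(1, 0.5, 3),
                     f2 = runif(1, 0, 0.7), off = runif(1, -5, 5))
    q <- make_emg_iv(runif(1, 1, 4), runif(1, 0.5, 3),
                     f2 = runif(1, 0, 0.7), off = runif(1, -5, 5))
    x <- mbralign:::resample_trace(p, 50)
    y <- mbralign:::resample_trace(q, 50)
    fit <- lm(y ~ x)
    oracle <- 1 - sum(residuals(fit)^2) / sum((y - mean(y))^2)
    expect_equal(shape_r2(p, q), oracle, tolerance = 1e-12)
    # symmetric under run swap; equals the squared Pearson correlation
    expect_equal(shape_r2(p, q), shape_r2(q, p), tolerance = 1e-9)
    expect_equal(shape_r2(p, q), cor(x, y)^2, tolerance = 1e-9)
    # affine intensity transforms of either trace change nothing
    q2 <- q
    q2$intensities <- runif(1, 0.1, 50) * q2$intensities + runif(1, 0, 100)
    expect_equal(shape_r2(p, q2), shape_r2(p, q), tolerance = 1e-9)
  }

  flat <- make_iv(1:10, rep(5, 10))
  expect_warning(r <- shape_r2(a, flat), "zero-variance")
  expect_equal(r, 0)
})

test_that("the Gaussian shift model uses mean and n-1 standard deviation", {
  m <- fit_shift_model(c(-1, 0, 1))
  expect_equal(m$mu, 0)
  expect_equal(m$sigma, 1)
  m2 <- fit_shift_model(c(-1, 0, 1) + 7)
  expect_equal(m2$mu, 7)
  expect_equal(m2$sigma, 1)
  expect_error(fit_shift_model(rep(2, 5)), "distinct")

  set.seed(270)
  m3 <- fit_shift_model(rnorm(270, 0, 5))
  expect_lt(abs(m3$mu), 1.0)
  expect_lt(abs(m3$sigma - 5) / 5, 0.15)
})

test_that("shift_density is the Normal pdf", {
  m <- fit_shift_model(c(-3, -1, 0, 1, 3))
  expect_equal(shift_density(m, m$mu), 1 / (m$sigma * sqrt(2 * pi)))
  expect_equal(shift_density(m, m$mu + 2.5), shift_density(m, m$mu - 2.5))
  set.seed(5)
  x <- rnorm(100, 0, 10)
  oracle <- exp(-(x - m$mu)^2 / (2 * m$sigma^2)) / (m$sigma * sqrt(2 * pi))
  expect_equal(shift_density(m, x), oracle, tolerance = 1e-12)
})

test_that("the Gamma shape model recovers parameters and normalises", {
  set.seed(270)
  x <- rgamma(270, shape = 2, scale = 0.05)
  m <- fit_shape_model(1 - x)
  expect_lt(abs(m$k - 2) / 2, 0.30)
  expect_lt(abs(m$k * m$theta - 0.1) / 0.1, 0.15)

  expect_error(fit_shape_model(rep(1, 10)), "degenerate")

  quad <- integrate(function(z) shape_density(m, 1 - z), lower = 0,
                    upper = Inf, rel.tol = 1e-9)
  expect_lt(abs(quad$value - 1), 1e-6)
})

test_that("shape_density follows the Gamma pdf in x = 1 - R2", {
  m1 <- structure(list(k = 1, theta = 0.2, x_floor = 1e-6, n = 0),
                  class = "shape_model")
  xs <- seq(0.01, 0.9, by = 0.01)
  expect_equal(shape_density(m1, 1 - xs), (1 / 0.2) * exp(-xs / 0.2),
               tolerance = 1e-12)

  m2 <- structure(list(k = 3, theta = 0.1, x_floor = 1e-6, n = 0),
                  class = "shape_model")
  grid <- seq(1e-4, 1, by = 1e-4)
  expect_equal(grid[which.max(shape_density(m2, 1 - grid))], (3 - 1) * 0.1,
               tolerance = 1e-3)

  # closed-form reference normalised by quadrature
  set.seed(9)
  r2 <- runif(100)
  x <- pmax(1 - r2, m2$x_floor)
  ref_un <- x^(m2$k - 1) * exp(-x / m2$theta)
  z <- integrate(function(u) u^(m2$k - 1) * exp(-u / m2$theta), 0, Inf,
                 rel.tol = 1e-12)$value
  expect_equal(shape_density(m2, r2), ref_un / z, tolerance = 1e-10)
})

test_that("score_pair factorises and peaks where both densities peak", {
  sm <- fit_shift_model(c(-4, -1, 0, 1, 4))
  gm <- structure(list(k = 2, theta = 0.05, x_floor = 1e-6, n = 0),
                  class = "shape_model")
  set.seed(2)
  sh <- rnorm(50); r2 <- runif(50)
  expect_equal(score_pair(sh, r2, sm, gm),
               shift_density(sm, sh) * shape_density(gm, r2),
               tolerance = 1e-12)
  best <- score_pair(sm$mu, 1 - (gm$k - 1) * gm$theta, sm, gm)
  expect_true(all(score_pair(sh, r2, sm, gm) <= best + 1e-12))
  # monotone decay in |shift - mu| at fixed shape
  d <- seq(0, 10, by = 0.5)
  sc <- score_pair(sm$mu + d, 0.9, sm, gm)
  expect_true(all(diff(sc) < 0))
})

test_that("model parameter recovery holds across seeds", {
  ok <- vapply(1:20, function(seed) {
    set.seed(seed)
    sm <- fit_shift_model(rnorm(270, 0, 5))
    gm <- fit_shape_model(1 - rgamma(270, shape = 2, scale = 0.05))
    abs(sm$mu) <= 1.0 && abs(sm$sigma - 5) / 5 <= 0.15 &&
      abs(gm$k - 2) / 2 <= 0.30 && abs(gm$k * gm$theta - 0.1) / 0.1 <= 0.15
  }, logical(1))
  expect_gte(sum(ok), 18)
})
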