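test_that("ball samples are uniform by measure and reproducible", {
  expect_error(sample_ball_uniform(0, 1), "n > 0")

  n <- 1e6
  pts <- sample_ball_uniform(n, radius = 1, dim = 3, seed = 5)
  r <- sqrt(rowSums(pts^2))
  expect_lte(max(r), 1)
  # E[r] = 3/4 for the uniform unit ball; sd(r) = sqrt(3/80)
  se <- sqrt(3 / 80) / sqrt(n)
  expect_lt(abs(mean(r) - 3 / 4), 3 * se)
  # shell counts proportional to shell volume
  edges <- seq(0, 1, by = 0.1)
  counts <- table(cut(r, edges))
  p <- diff(edges^3)
  chi <- sum((counts - n * p)^2 / (n * p))
  expect_gt(stats::pchisq(chi, df = 9, lower.tail = FALSE), 0.001)

  # determinism + offset
  expect_identical(pts, sample_ball_uniform(n, 1, 3, seed = 5))
  off <- sample_ball_uniform(10, 1, 3, seed = 5, center = c(5, 6, 7))
  expect_equal(off, sweep(pts[1:10, ], 2, c(5, 6, 7), "+"))

  # 2D: E[r] = 2/3, sd = sqrt(1/18)
  pts2 <- sample_ball_uniform(n, 1, dim = 2, seed = 5)
  r2 <- sqrt(rowSums(pts2^2))
  expect_lte(max(r2), 1)
  expect_lt(abs(mean(r2) - 2 / 3), 3 * sqrt(1 / 18) / sqrt(n))

  # compatibility transform is center-biased: mean radius 1/2, not 3/4
  rb <- sqrt(rowSums(sample_ball_uniform(1e5, 1, 3, seed = 5,
                                         biased = TRUE)^2))
  expect_lt(abs(mean(rb) - 1 / 2), 0.01)
})

test_that("MC energy is deterministic per seed and near zero on constant images", {
  v <- array(0.6, c(48, 48, 48))
  s <- snake(c(23.5, 23.5, 23.5), 12)
  cfg <- sampling_config(n_samples = 10000, seed = 3)
  e1 <- mc_energy(v, s, cfg = cfg)
  expect_identical(e1, mc_energy(v, s, cfg = cfg))
  # zero-mean weight: within 3 MC standard errors of 0
  ests <- vapply(1:50, function(sd)
    mc_energy(v, s, cfg = sampling_config(n_samples = 10000, seed = sd)),
    numeric(1))
  expect_lt(abs(e1), 3 * stats::sd(ests))
  expect_lt(abs(mean(ests)), 3 * stats::sd(ests) / sqrt(50))
  # different iteration -> different draw, same iteration -> same draw
  expect_identical(mc_energy(v, s, cfg = cfg, iter = 2),
                   mc_energy(v, s, cfg = cfg, iter = 2))
  expect_false(identical(e1, mc_energy(v, s, cfg = cfg, iter = 2)))
})

test_that("MC energy RMSE scales as 1/sqrt(N)", {
  # grid oracle on a well-smoothed blob (the estimator and the grid sum agree
  # only up to interpolation-quadrature differences, which vanish for smooth
  # integrands -- see the methods vignette)
  v <- blob_volume(64, 10, smooth_sigma = 4)
  s <- snake(c(31.5, 31.5, 31.5), 2^(1 / 3) * 10)
  Eg <- discrete_energy(v, s)
  ns <- c(1e3, 1e4, 1e5)
  rmse <- vapply(ns, function(n) {
    est <- vapply(1:50, function(sd)
      mc_energy(v, s, cfg = sampling_config(n_samples = n, seed = sd)),
      numeric(1))
    sqrt(mean((est - Eg)^2))
  }, numeric(1))
  slope <- stats::coef(stats::lm(log10(rmse) ~ log10(ns)))[2]
  expect_gt(slope, -0.6)
  expect_lt(slope, -0.4)

  # pure sampling-noise check on the sharp blob: spread about the estimator
  # mean is exactly 1/sqrt(N)
  vs <- blob_volume(64, 10)
  sds <- vapply(ns, function(n) {
    est <- vapply(1:50, function(sd)
      mc_energy(vs, s, cfg = sampling_config(n_samples = n, seed = sd)),
      numeric(1))
    stats::sd(est)
  }, numeric(1))
  slope2 <- stats::coef(stats::lm(log10(sds) ~ log10(ns)))[2]
  expect_gt(slope2, -0.6)
  expect_lt(slope2, -0.4)
})

test_that("MC estimator is unbiased against the grid energy on a smooth image", {
  v <- gaussian_bump(64, sigma = 8)
  s <- snake(c(31.5, 31.5, 31.5), 12)
  Eg <- discrete_energy(v, s)
  est <- vapply(1:200, function(sd)
    mc_energy(v, s, cfg = sampling_config(n_samples = 10000, seed = sd)),
    numeric(1))
  se <- stats::sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - Eg), 2 * se)
})

test_that("MC gradient converges to the grid gradient and shares samples", {
  v <- blob_volume(64, 10, smooth_sigma = 2)
  s <- snake(c(29.5, 33.5, 31.5), 13)
  gg <- energy_gradient(v, s)
  gm <- mc_gradient(v, s, cfg = sampling_config(n_samples = 1e5, seed = 2))
  expect_equal(gm, gg, tolerance = 0.05)
  # constant image: each component within 3 SE of zero
  vc <- array(0.5, c(48, 48, 48))
  sc <- snake(c(23.5, 23.5, 23.5), 12)
  gs <- t(vapply(1:50, function(sd)
    mc_gradient(vc, sc, cfg = sampling_config(n_samples = 10000, seed = sd)),
    numeric(4)))
  for (k in 1:4)
    expect_lt(abs(mean(gs[, k])), 3 * stats::sd(gs[, k]) / sqrt(50) + 1e-12)
  # determinism
  cfg <- sampling_config(n_samples = 5000, seed = 9)
  expect_identical(mc_gradient(v, s, cfg = cfg, iter = 3),
                   mc_gradient(v, s, cfg = cfg, iter = 3))
})

test_that("pre-smoothing does not increase MC variance on the binary blob", {
  vs <- blob_volume(64, 10)
  vsm <- gaussian_smooth(vs, 2)
  s <- snake(c(31.5, 31.5, 31.5), 2^(1 / 3) * 10)
  var_of <- function(v) {
    est <- vapply(1:60, function(sd)
      mc_energy(v, s, cfg = sampling_config(n_samples = 5000, seed = sd)),
      numeric(1))
    stats::var(est)
  }
  expect_lte(var_of(vsm), var_of(vs))
})

test_that("gaussian_smooth preserves constants and mass", {
  v <- array(0.42, c(24, 24, 24))
  expect_equal(gaussian_smooth(v, 2), v, tolerance = 1e-12)
  set.seed(1)
  w <- array(stats::runif(24^3), c(24, 24, 24))
  ws <- gaussian_smooth(w, 1.5)
  expect_equal(dim(ws), dim(w))
  expect_lt(stats::sd(ws), stats::sd(w))  # smoothing reduces variance
})
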