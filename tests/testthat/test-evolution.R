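canonical_phantom <- function(seed = 3) {
  generate_phantom(phantom_spec(shape = c(64, 64, 64), n_spheres = 1,
                                radius_range = c(10, 10), seed = seed))
}

test_that("snakes do not move on constant images", {
  v <- array(0.5, c(48, 48, 48))
  s <- snake(c(23.5, 22.1, 25.7), 12)
  tr <- evolve_snake(v, s, samp_cfg = sampling_config(mode = "grid"))
  expect_equal(tr$center, s$center, tolerance = 1e-6)
  expect_equal(tr$radius, s$radius, tolerance = 1e-6)
  expect_true(tr$status %in% c("converged", "active"))
  expect_lt(tr$last_step, 1e-6)
})

test_that("evolution recovers an isolated blob's center and radius", {
  ph <- canonical_phantom()
  truth <- rev(as.numeric(ph$truth[1, c("z", "y", "x")]))
  r0 <- ph$truth$r0[1]
  s0 <- snake(truth + c(4, 0, 0), 18)
  for (mode in c("grid", "monte-carlo")) {
    tr <- evolve_snake(ph$volume$data, s0,
                       samp_cfg = sampling_config(mode = mode, seed = 1))
    expect_identical(tr$status, "converged")
    expect_lt(sqrt(sum((tr$center - truth)^2)), 1)         # center < 1 vox
    expect_lt(abs(tr$radius * 2^(-1 / 3) - r0) / r0, 0.1)  # rho*R within 10%
  }
})

test_that("step_tol = Inf converges in exactly one iteration", {
  ph <- canonical_phantom()
  s0 <- snake(c(30, 30, 30), 14)
  tr <- evolve_snake(ph$volume$data, s0,
                     evo_cfg = evolution_config(step_tol = Inf),
                     samp_cfg = sampling_config(mode = "grid"))
  expect_identical(tr$iterations, 1L)
  expect_identical(tr$status, "converged")
})

test_that("energy is non-increasing under grid descent on the noiseless blob", {
  ph <- canonical_phantom()
  truth <- rev(as.numeric(ph$truth[1, c("z", "y", "x")]))
  s0 <- snake(truth + c(4, 0, 0), 18)
  tr <- evolve_snake(ph$volume$data, s0,
                     samp_cfg = sampling_config(mode = "grid"))
  e <- tr$trajectory[, "energy"]
  expect_lt(max(diff(e)), 1e-6)
})

test_that("trajectory bookkeeping matches the contract", {
  ph <- canonical_phantom()
  s0 <- snake(c(30, 30, 30), 14)
  cfgs <- list(evolution_config(max_iters = 25),
               evolution_config())
  for (evo in cfgs) {
    tr <- evolve_snake(ph$volume$data, s0, evo_cfg = evo,
                       samp_cfg = sampling_config(seed = 2))
    expect_lte(nrow(tr$trajectory), evo$max_iters)
    expect_identical(nrow(tr$trajectory), as.integer(tr$iterations))
    if (tr$status == "converged")
      expect_lt(tr$trajectory[tr$iterations, "step"], evo$step_tol)
  }
})

test_that("snakes shrinking below R_min are culled as domain losses", {
  # a blob far smaller than R_min * rho pulls the contour below R_min
  ph <- generate_phantom(phantom_spec(shape = c(64, 64, 64), n_spheres = 1,
                                      radius_range = c(4, 4), seed = 6))
  truth <- rev(as.numeric(ph$truth[1, c("z", "y", "x")]))
  tr <- evolve_snake(ph$volume$data, snake(truth, 10),
                     samp_cfg = sampling_config(mode = "grid"))
  expect_identical(tr$status, "culled-domain")
  expect_lt(tr$radius, 8)  # R_min = max(2 * delta_R, 3)
})

test_that("population evolution equals single-snake evolution, any backend,
           any order", {
  ph <- canonical_phantom()
  v <- ph$volume$data
  truth <- rev(as.numeric(ph$truth[1, c("z", "y", "x")]))
  snakes <- list(snake(truth + c(3, 1, -2), 16),
                 snake(truth + c(-4, 2, 0), 13),
                 snake(c(12, 50, 12), 12))
  evo <- evolution_config(epsilon0 = 60)
  samp <- sampling_config(seed = 7)

  vec <- evolve_population(v, snakes, evo_cfg = evo, samp_cfg = samp)
  ser <- evolve_population(v, snakes,
                           evo_cfg = evolution_config(epsilon0 = 60,
                                                      backend = "serial"),
                           samp_cfg = samp)
  expect_identical(vec, ser)  # backend equivalence, element-wise

  # population of one == evolve_snake
  single <- evolve_snake(v, snakes[[2]], evo_cfg = evo, samp_cfg = samp)
  expect_identical(vec[[2]]$center, single$center)
  expect_identical(vec[[2]]$trajectory, single$trajectory)

  # shuffle invariance
  perm <- c(3, 1, 2)
  shuf <- evolve_population(v, snakes[perm], evo_cfg = evo, samp_cfg = samp)
  expect_identical(shuf[order(perm)], vec)

  expect_error(evolve_population(v, list()), "empty")
})

# the full 100-initialization convergence-basin property is exercised by
# acceptance criterion 5 (test-acceptance.R); a reduced draw from the same
# basin keeps a fast regression check here
test_that("convergence basin: perturbed initializations find the blob", {
  ph <- canonical_phantom()
  v <- ph$volume$data
  truth <- rev(as.numeric(ph$truth[1, c("z", "y", "x")]))
  r0 <- ph$truth$r0[1]
  Rstar <- 2^(1 / 3) * r0
  set.seed(29)
  snakes <- lapply(1:20, function(i) {
    u <- stats::rnorm(3)
    u <- u / sqrt(sum(u^2)) * stats::runif(1, 0, 0.75 * r0)
    snake(truth + u, stats::runif(1, 0.8, 1.6) * Rstar)
  })
  trs <- evolve_population(v, snakes, samp_cfg = sampling_config(seed = 4),
                           record_trajectories = FALSE)
  ok <- vapply(trs, function(tr)
    tr$status == "converged" &&
      sqrt(sum((tr$center - truth)^2)) < 1 &&
      abs(tr$radius * 2^(-1 / 3) - r0) / r0 < 0.1, logical(1))
  expect_gte(sum(ok), 19L)
})
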