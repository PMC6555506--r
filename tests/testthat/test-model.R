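test_that("weight profile has the required structure and signs", {
  prof <- weight_profile(delta_R = 4, dim = 3)
  expect_equal(prof$rho, 2^(-1 / 3))
  expect_equal(prof$delta_r, 4 * 2^(-1 / 3))
  expect_equal(weight_profile(dim = 2)$rho, 2^(-1 / 2))

  R <- 20
  expect_lt(weight_value(0, R, prof), 0)               # inner core negative
  expect_gt(weight_value(0.95 * R, R, prof), 0)        # annulus positive
  expect_identical(weight_value(R + prof$delta_R / 2, R, prof), 0)
  expect_identical(weight_value(R + 10, R, prof), 0)   # zero beyond footprint

  # degenerate snakes are rejected
  expect_error(weight_value(1, R = prof$delta_R, prof), "degenerate")
  expect_error(discrete_energy(array(0, c(16, 16, 16)), snake(rep(8, 3), 2)),
               "degenerate")
})

test_that("weight profile moment integral is zero for any admissible R", {
  for (dm in c(2L, 3L)) {
    prof <- weight_profile(delta_R = 4, dim = dm)
    for (R in c(4.5, 6, 9, 14, 20, 35, 80)) {
      b2 <- R + prof$delta_R / 2
      f <- function(r) weight_value(r, R, prof) * r^(dm - 1)
      brk <- sort(unique(pmax(0, c(0, prof$rho * R - prof$delta_r / 2,
                                   prof$rho * R + prof$delta_r / 2,
                                   R - prof$delta_R / 2, b2))))
      I <- sum(vapply(seq_along(brk)[-1], function(i)
        stats::integrate(f, brk[i - 1], brk[i], rel.tol = 1e-12,
                         subdivisions = 400L)$value, numeric(1)))
      Iabs <- stats::integrate(function(r) abs(f(r)), 0, b2,
                               subdivisions = 500L, rel.tol = 1e-9)$value
      expect_lt(abs(I) / Iabs, 1e-9)
    }
  }
})

test_that("weight function is continuous and differentiable in r and R", {
  prof <- weight_profile(delta_R = 4, dim = 3)
  R <- 12
  r <- seq(0, R + prof$delta_R / 2 + 1, by = 1e-3)
  S <- weight_value(r, R, prof)
  expect_lt(max(abs(diff(S))), 2e-3 * max(abs(S)))  # no jumps
  # analytic dS/dr and dS/dR match central differences
  h <- 1e-5
  rs <- c(3, 7.5, 9.524, 11, 13.9)
  dv <- weight_value(rs, R, prof, derivatives = TRUE)
  fd_r <- (weight_value(rs + h, R, prof) - weight_value(rs - h, R, prof)) / (2 * h)
  fd_R <- (weight_value(rs, R + h, prof) - weight_value(rs, R - h, prof)) / (2 * h)
  expect_equal(dv$dS_dr, fd_r, tolerance = 1e-6)
  expect_equal(dv$dS_dR, fd_R, tolerance = 1e-6)
})

test_that("closed-form blob energy matches its three branches and the
           radial-quadrature oracle", {
  # branch values at the printed points
  expect_identical(closed_form_sphere_energy(0.5, 1), 0)
  expect_equal(closed_form_sphere_energy(1.1, 1), -(8 / 3) * pi * (1.331 - 1))
  expect_equal(closed_form_sphere_energy(2^(1 / 3), 1), -(8 / 3) * pi)
  expect_equal(closed_form_sphere_energy(3, 1), -(8 / 3) * pi)

  # independent oracle: 1-D quadrature of S(r) I(r) r^2 with a narrow ramp
  prof <- weight_profile(delta_R = 0.05, dim = 3)
  for (R in c(11, 12.599, 16)) {
    expect_equal(radial_weighted_energy(R, 10, prof),
                 closed_form_sphere_energy(R, 10),
                 tolerance = 0.01)
  }
  # 2D analogue
  prof2 <- weight_profile(delta_R = 0.05, dim = 2)
  for (R in c(11, 13, 15)) {
    expect_equal(radial_weighted_energy(R, 10, prof2),
                 closed_form_sphere_energy(R, 10, dim = 2),
                 tolerance = 0.01)
  }
})

test_that("normalized energy has a single minimum at R = 2^(1/3) r0", {
  expect_equal(normalized_energy(-(8 / 3) * pi, 2^(1 / 3), 3), -(4 / 3) * pi)
  expect_identical(normalized_energy(0, 5, 3), 0)

  r0 <- 1
  R <- seq(0.4, 4, by = 1e-3)
  Ebar <- normalized_energy(closed_form_sphere_energy(R, r0), R, 3)
  i <- which.min(Ebar)
  expect_equal(R[i], 2^(1 / 3) * r0, tolerance = 2e-3)
  # single local minimum: derivative changes sign exactly once
  d <- diff(Ebar)
  sign_changes <- sum(diff(sign(d[d != 0])) != 0)
  expect_equal(sign_changes, 1)
})

test_that("gradient symmetry at the optimum holds for alpha = 3 (and 2 in 2D)", {
  for (dm in c(3L, 2L)) {
    r0 <- 1
    alpha <- if (dm == 3) 3 else 2
    Rstar <- if (dm == 3) 2^(1 / 3) else sqrt(2)
    eps <- 1e-3 * r0
    Ebar <- function(R) normalized_energy(
      closed_form_sphere_energy(R, r0, dm), R, alpha)
    h <- 1e-6
    left <- (Ebar(Rstar - eps + h) - Ebar(Rstar - eps - h)) / (2 * h)
    right <- (Ebar(Rstar + eps + h) - Ebar(Rstar + eps - h)) / (2 * h)
    expect_equal(abs(left), abs(right), tolerance = 0.01)
    expect_lt(left, 0)
    expect_gt(right, 0)
  }
})

test_that("normalization exponent is recovered by the symmetry search", {
  expect_equal(recover_normalization_exponent(r0 = 1, dim = 3), 3,
               tolerance = 0.05 / 3)
  expect_equal(recover_normalization_exponent(r0 = 2.5, dim = 3), 3,
               tolerance = 0.05 / 3)
  expect_equal(recover_normalization_exponent(r0 = 1, dim = 2), 2,
               tolerance = 0.05 / 2)
})

test_that("discrete energy is exactly zero on constant images", {
  v <- array(0.7, c(64, 64, 64))
  for (cfg in list(list(c(31.5, 31.5, 31.5), 14),
                   list(c(20.2, 35.7, 28.1), 9.3),
                   list(c(31, 31, 31), 20))) {
    s <- snake(cfg[[1]], cfg[[2]])
    expect_lt(abs(discrete_energy(v, s)), 1e-6)
    expect_lt(max(abs(energy_gradient(v, s))), 1e-6)
  }
  expect_identical(discrete_energy(array(0, c(32, 32, 32)),
                                   snake(c(15, 15, 15), 10)), 0)
  # 2D
  v2 <- array(0.31, c(64, 64))
  s2 <- snake(c(30.4, 33.1), 12)
  prof2 <- weight_profile(dim = 2)
  expect_lt(abs(discrete_energy(v2, s2, prof2)), 1e-6)
  expect_lt(max(abs(energy_gradient(v2, s2, prof2))), 1e-6)
})

test_that("discrete energy matches the closed form on a voxelized blob", {
  # sharp-limit comparison: narrow ramps so the indicator-weight closed form
  # applies; 2% discretization tolerance at r0 = 10 on a 96^3 grid
  r0 <- 10
  n <- 96
  ctr <- rep((n - 1) / 2, 3)
  v <- blob_volume(n, r0, ctr)
  prof <- weight_profile(delta_R = 0.25, dim = 3)
  for (m in c(0.6, 0.9, 1.0, 1.1, 2^(1 / 3), 1.5)) {
    R <- m * r0
    Ed <- discrete_energy(v, snake(ctr, R), prof)
    Ec <- closed_form_sphere_energy(R, r0) / (2 * R)^3
    if (Ec == 0) {
      expect_lt(abs(Ed), 0.02 * (8 / 3) * pi * r0^3 / (2 * R)^3)
    } else {
      expect_equal(Ed, Ec, tolerance = 0.02)
    }
  }
})

test_that("analytic gradients match finite differences on random fields", {
  v <- smooth_field(48, sigma = 3, seed = 11)
  prof <- weight_profile(4, 3)
  set.seed(99)
  h <- 1e-3
  for (i in 1:100) {
    ctr <- stats::runif(3, 14, 33)
    R <- stats::runif(1, 9, 14)
    g <- energy_gradient(v, snake(ctr, R), prof)
    E <- function(px, qx, y, z)
      discrete_energy(v, snake(c((px + qx) / 2, y, z), (qx - px) / 2), prof)
    px <- ctr[1] - R
    qx <- ctr[1] + R
    fd <- c(
      px = (E(px + h, qx, ctr[2], ctr[3]) - E(px - h, qx, ctr[2], ctr[3])) / (2 * h),
      qx = (E(px, qx + h, ctr[2], ctr[3]) - E(px, qx - h, ctr[2], ctr[3])) / (2 * h),
      # moving p_y and q_y together by h moves the center by h
      y = (E(px, qx, ctr[2] + h / 2, ctr[3]) - E(px, qx, ctr[2] - h / 2, ctr[3])) / (2 * h),
      z = (E(px, qx, ctr[2], ctr[3] + h / 2) - E(px, qx, ctr[2], ctr[3] - h / 2)) / (2 * h))
    expect_equal(g, fd, tolerance = 1e-3)
  }
})

test_that("gradient vanishes on the symmetry plane of a symmetric image", {
  n <- 64
  ctr <- rep((n - 1) / 2, 3)
  v <- blob_volume(n, 10, ctr, smooth_sigma = 1)
  # snake centered in y: y-component must vanish by symmetry
  s <- snake(c(ctr[1] + 3, ctr[2], ctr[3] + 2), 12)
  g <- energy_gradient(v, s)
  expect_lt(abs(g[["y"]]), 1e-10)
})
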