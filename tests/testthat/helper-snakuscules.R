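# Shared fixtures, all generated in code.

# voxelized binary blob per the ideal model: intensity 2 inside r0, 0 outside
blob_volume <- function(n = 64, r0 = 10, center = rep((n - 1) / 2, 3),
                        smooth_sigma = 0, fg = 2) {
  v <- snakuscules:::cpp_fill_spheres(as.integer(c(n, n, n)),
                                      matrix(center, 1), r0, fg, 0)
  if (smooth_sigma > 0) v <- gaussian_smooth(v, smooth_sigma)
  v
}

# smooth random field in [0, 1]
smooth_field <- function(n = 48, sigma = 3, seed = 1, dim = 3) {
  set.seed(seed)
  dims <- rep(n, dim)
  v <- array(stats::runif(prod(dims)), dims)
  v <- gaussian_smooth(v, sigma)
  (v - min(v)) / (max(v) - min(v))
}

# smooth isotropic Gaussian bump (analytically smooth test image)
gaussian_bump <- function(n = 64, sigma = 8, center = rep((n - 1) / 2, 3)) {
  g <- 0:(n - 1)
  r2 <- outer(outer((g - center[1])^2, (g - center[2])^2, "+"),
              (g - center[3])^2, "+")
  array(exp(-r2 / (2 * sigma^2)), c(n, n, n))
}

# truth table (z, y, x[, r0]) -> center matrix in (x, y, z) order
truth_centers <- function(truth) {
  as.matrix(truth[, c("x", "y", "z")])
}

# brute-force optimal one-to-one matching count (oracle for greedy matching)
optimal_match_count <- function(det, tru, max_dist) {
  det <- as.matrix(det)
  tru <- as.matrix(tru)
  nd <- nrow(det)
  nt <- nrow(tru)
  if (nd == 0 || nt == 0) return(0L)
  dmat <- as.matrix(stats::dist(rbind(det, tru)))[seq_len(nd),
                                                  nd + seq_len(nt),
                                                  drop = FALSE]
  best <- 0L
  rec <- function(i, used_t, count) {
    if (count + (nd - i + 1) <= best) return()
    if (i > nd) {
      best <<- max(best, count)
      return()
    }
    rec(i + 1, used_t, count)  # leave detection i unmatched
    for (j in seq_len(nt)) {
      if (!used_t[j] && dmat[i, j] <= max_dist) {
        used_t[j] <- TRUE
        rec(i + 1, used_t, count + 1L)
        used_t[j] <- FALSE
      }
    }
  }
  rec(1L, logical(nt), 0L)
  best
}

# radial quadrature of the weighted blob energy: independent 1-D oracle for
# the closed-form branches, E = surface * int S(r) I(r) r^(dim-1) dr
radial_weighted_energy <- function(R, r0, profile) {
  dm <- profile$dim
  surf <- if (dm == 3) 4 * pi else 2 * pi
  f <- function(r) {
    weight_value(r, R, profile) * ifelse(r < r0, 2, 0) * r^(dm - 1)
  }
  b2 <- R + profile$delta_R / 2
  brk <- sort(unique(pmin(b2, pmax(0, c(
    0, r0, profile$rho * R - profile$delta_r / 2,
    profile$rho * R + profile$delta_r / 2,
    R - profile$delta_R / 2, b2)))))
  segs <- vapply(seq_along(brk)[-1], function(i) {
    stats::integrate(f, brk[i - 1], brk[i], rel.tol = 1e-10,
                     subdivisions = 400L)$value
  }, numeric(1))
  surf * sum(segs)
}
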