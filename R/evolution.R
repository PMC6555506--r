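#' Evolution (gradient descent) configuration
#'
#' Snakes are evolved by gradient descent on the contour energy with a
#' decaying learning rate \eqn{\epsilon = \epsilon_0 / n} (iteration `n`),
#' stopping when the largest parameter update falls below `step_tol`, the
#' iteration cap is reached, or the snake degenerates (radius below `R_min`
#' or center leaving the image domain).
#'
#' When `epsilon0 = NULL` (the default) the base rate is auto-scaled per
#' snake, from that snake's own initial (grid-backend) gradient, so that its
#' first step is `first_step_voxels`. This makes the step schedule
#' independent of the image intensity scale and resolution, and lets
#' contours that start on weak-gradient plateaus (e.g. oversized contours
#' already enclosing a blob) move as decisively as contours on steep slopes.
#' Each per-snake rate is a deterministic function of that snake's initial
#' state alone, so population results remain order-independent. Updates are
#' additionally clamped to `max_step_voxels` per component per iteration,
#' which keeps a rate calibrated on a shallow plateau from producing runaway
#' moves when the contour later reaches a steep region. See the methods
#' vignette for the rationale.
#'
#' @param epsilon0 Base learning rate, or `NULL` to auto-scale per snake.
#' @param max_iters Iteration cap (default 400).
#' @param step_tol Convergence threshold on the largest update (voxels,
#'   default 0.001).
#' @param backend `"vectorized"` (population evolved in compiled code) or
#'   `"serial"` (one compiled call per snake); both produce identical results.
#' @param first_step_voxels Target first-iteration step used by the
#'   auto-scaling of `epsilon0` (default 2).
#' @param max_step_voxels Per-component, per-iteration step clamp in voxels
#'   (default 2).
#' @param R_min Minimum admissible radius; snakes shrinking below it are
#'   culled with status `"culled-domain"`. Default `max(2 * delta_R, 3)`,
#'   resolved against the profile at evolution time when `NULL`.
#' @return An object of class `evolution_config`.
#' @export
evolution_config <- function(epsilon0 = NULL, max_iters = 400,
                             step_tol = 0.001,
                             backend = c("vectorized", "serial"),
                             first_step_voxels = 2, max_step_voxels = 2,
                             R_min = NULL) {
  backend <- match.arg(backend)
  stopifnot(is.null(epsilon0) || epsilon0 > 0, max_iters >= 1, step_tol > 0,
            first_step_voxels > 0, max_step_voxels > 0)
  structure(
    list(epsilon0 = epsilon0, max_iters = as.integer(max_iters),
         step_tol = step_tol, backend = backend,
         first_step_voxels = first_step_voxels,
         max_step_voxels = max_step_voxels, R_min = R_min),
    class = "evolution_config"
  )
}

resolve_R_min <- function(evo_cfg, profile) {
  if (!is.null(evo_cfg$R_min)) evo_cfg$R_min else max(2 * profile$delta_R, 3)
}

status_labels <- c("active", "converged", "culled-domain")

# per-snake auto epsilon0: the snake's own initial (grid) gradient should
# produce a `first_step_voxels` move on iteration 1; snakes on flat regions
# (e.g. constant images, |g| < 1e-8) fall back to a fixed rate so they stay
# put instead of amplifying numerical noise.
auto_epsilon0 <- function(image, snakes, profile, evo_cfg) {
  v <- as_image_data(image)
  dims <- dim(v)
  vapply(snakes, function(s) {
    g <- cpp_grid_eval(as.numeric(v), as.integer(dims), s$center, s$radius,
                       unclass(profile), TRUE)$gradient
    gmax <- max(abs(g))
    if (!is.finite(gmax) || gmax < 1e-8) 10
    else evo_cfg$first_step_voxels / gmax
  }, numeric(1))
}

traj_colnames <- function(d) {
  if (d == 3) c("x", "y", "z", "radius", "energy", "step")
  else c("x", "y", "radius", "energy", "step")
}

wrap_trajectory <- function(res, d, initial) {
  tr <- res$trajectory
  if (!is.null(tr)) colnames(tr) <- traj_colnames(d)
  structure(
    list(center = res$center, radius = res$radius,
         status = status_labels[res$status + 1L],
         iterations = res$iterations, energy = res$energy,
         last_step = res$last_step, initial = initial, trajectory = tr),
    class = "snake_trajectory"
  )
}

#' @export
print.snake_trajectory <- function(x, ...) {
  cat(sprintf(
    "<snake_trajectory> %d iterations, status=%s\n  final center=(%s) R=%.3f energy=%s\n",
    x$iterations, x$status,
    paste(sprintf("%.3f", x$center), collapse = ", "), x$radius,
    if (is.na(x$energy)) "NA" else sprintf("%.5f", x$energy)))
  invisible(x)
}

#' Evolve a single snake
#'
#' Gradient descent on the snake parameters: the defining points move against
#' the energy gradient, `p <- p - eps * dE/dp` and likewise for `q`, with
#' `eps = epsilon0 / n`. The cross-axis coordinates of `p` and `q` receive the
#' same (shared) update, so the collinearity constraint is maintained exactly.
#' In Monte-Carlo mode the per-iteration sample stream is derived
#' deterministically from `(samp_cfg$seed, snake initial state, iteration)`,
#' so results are reproducible and independent of population order.
#'
#' @inheritParams discrete_energy
#' @param evo_cfg An [evolution_config()].
#' @param samp_cfg A [sampling_config()]; `presmooth_sigma > 0` smooths the
#'   image before evolution.
#' @return A `snake_trajectory`: final center/radius/energy/status, iteration
#'   count, and the per-iteration `(center, radius, energy, step)` matrix.
#' @export
evolve_snake <- function(image, s, profile = weight_profile(),
                         evo_cfg = evolution_config(),
                         samp_cfg = sampling_config()) {
  dims <- check_snake_image(image, s, profile)
  check_snake_radius(s$radius, profile)
  v <- as_image_data(image)
  if (samp_cfg$presmooth_sigma > 0)
    v <- cpp_gaussian_smooth(as.numeric(v), as.integer(dims),
                             samp_cfg$presmooth_sigma)
  eps0 <- evo_cfg$epsilon0
  if (is.null(eps0)) eps0 <- auto_epsilon0(v, list(s), profile, evo_cfg)[1]
  res <- cpp_evolve(as.numeric(v), as.integer(dims), s$center, s$radius,
                    unclass(profile), eps0, evo_cfg$max_iters,
                    evo_cfg$step_tol, resolve_R_min(evo_cfg, profile),
                    evo_cfg$max_step_voxels,
                    if (samp_cfg$mode == "grid") 0L else 1L,
                    samp_cfg$n_samples, as.numeric(samp_cfg$seed),
                    cpp_snake_key(s$center, s$radius),
                    samp_cfg$radial_bias_compat, TRUE)
  wrap_trajectory(res, length(dims), s)
}

#' Evolve a population of snakes
#'
#' Each snake evolves independently; the result for every snake is identical
#' to calling [evolve_snake()] on it alone (its Monte-Carlo stream is keyed by
#' its own initial state), and the output order matches the input order
#' regardless of backend or input permutation.
#'
#' @inheritParams evolve_snake
#' @param snakes Non-empty list of [snake()] objects.
#' @param record_trajectories Keep the full per-iteration trajectory of every
#'   snake (memory proportional to total iterations).
#' @return List of `snake_trajectory` objects, one per input snake.
#' @export
evolve_population <- function(image, snakes, profile = weight_profile(),
                              evo_cfg = evolution_config(),
                              samp_cfg = sampling_config(),
                              record_trajectories = TRUE) {
  if (!length(snakes)) stop("empty snake list", call. = FALSE)
  stopifnot(all(vapply(snakes, inherits, logical(1), "snake")))
  dims <- check_snake_image(image, snakes[[1]], profile)
  v <- as_image_data(image)
  if (samp_cfg$presmooth_sigma > 0)
    v <- cpp_gaussian_smooth(as.numeric(v), as.integer(dims),
                             samp_cfg$presmooth_sigma)
  eps0 <- evo_cfg$epsilon0
  eps0 <- if (is.null(eps0)) auto_epsilon0(v, snakes, profile, evo_cfg)
          else rep(eps0, length(snakes))
  d <- length(dims)
  mode <- if (samp_cfg$mode == "grid") 0L else 1L
  R_min <- resolve_R_min(evo_cfg, profile)

  if (evo_cfg$backend == "vectorized") {
    centers <- do.call(rbind, lapply(snakes, `[[`, "center"))
    radii <- vapply(snakes, `[[`, numeric(1), "radius")
    res <- cpp_evolve_population(as.numeric(v), as.integer(dims), centers,
                                 radii, unclass(profile), eps0,
                                 evo_cfg$max_iters, evo_cfg$step_tol, R_min,
                                 evo_cfg$max_step_voxels,
                                 mode, samp_cfg$n_samples,
                                 as.numeric(samp_cfg$seed),
                                 samp_cfg$radial_bias_compat,
                                 record_trajectories)
    lapply(seq_along(snakes), function(i)
      wrap_trajectory(res[[i]], d, snakes[[i]]))
  } else {
    lapply(seq_along(snakes), function(i) {
      s <- snakes[[i]]
      wrap_trajectory(
        cpp_evolve(as.numeric(v), as.integer(dims), s$center, s$radius,
                   unclass(profile), eps0[i], evo_cfg$max_iters,
                   evo_cfg$step_tol, R_min, evo_cfg$max_step_voxels, mode,
                   samp_cfg$n_samples, as.numeric(samp_cfg$seed),
                   cpp_snake_key(s$center, s$radius),
                   samp_cfg$radial_bias_compat, record_trajectories),
        d, s)
    })
  }
}
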