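#' Detection pipeline configuration
#'
#' Parameters of the full blob-detection pipeline: lattice initialization,
#' population evolution, energy-threshold culling, and overlap competition.
#'
#' The default energy threshold is `-0.04`, an operating point expressed on
#' the package's normalized `[0, 1]` intensity scale: a snake perfectly
#' fitting a unit-contrast blob reaches about `-0.262`, so `-0.04` keeps
#' contours capturing at least ~15% of full contrast while rejecting
#' contours that converged onto smoothed noise (whose optimized energies
#' stay above about `-0.035` even at 0.2 dB SNR). The commonly quoted
#' threshold of -3 presumes raw 8-bit intensities (equivalent to about
#' -0.012 here, ~5% of contrast) and admits noise-fitted contours on
#' normalized sparse volumes; see the methods vignette for the calibration.
#'
#' @param initial_radius Lattice snake radius `R0` in voxels (default 15,
#'   about 6 um at typical confocal resolution).
#' @param lattice_pitch_factor Neighboring lattice centers are
#'   `lattice_pitch_factor * R0` apart (default 1.5).
#' @param energy_threshold Culling threshold `E0 <= 0`; snakes with energy
#'   greater than `E0` are removed.
#' @param evolution An [evolution_config()].
#' @param sampling A [sampling_config()].
#' @param profile A [weight_profile()]; its `dim` is adapted to the image at
#'   detection time.
#' @param normalize Min-max normalize the image to `[0, 1]` before detection.
#' @param tie_break Deterministic rule for equal-energy overlap competition;
#'   only `"index"` (lower lattice index survives) is implemented.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(initial_radius = 15, lattice_pitch_factor = 1.5,
                            energy_threshold = -0.04,
                            evolution = evolution_config(),
                            sampling = sampling_config(),
                            profile = weight_profile(),
                            normalize = TRUE, tie_break = "index") {
  stopifnot(initial_radius > 0, lattice_pitch_factor > 0,
            energy_threshold <= 0, identical(tie_break, "index"))
  R_min <- if (!is.null(evolution$R_min)) evolution$R_min
           else max(2 * profile$delta_R, 3)
  if (initial_radius < R_min)
    stop("initial_radius must be at least R_min = ", R_min, call. = FALSE)
  structure(
    list(initial_radius = initial_radius,
         lattice_pitch_factor = lattice_pitch_factor,
         energy_threshold = energy_threshold, evolution = evolution,
         sampling = sampling, profile = profile, normalize = normalize,
         tie_break = tie_break),
    class = "pipeline_config"
  )
}

#' Initialize a lattice of snakes covering a volume
#'
#' Places snakes of radius `R0` on an axis-aligned cubic lattice with pitch
#' `lattice_pitch_factor * R0` per axis, centered in the volume, so that
#' every blob lies in some contour's basin of attraction.
#'
#' @param shape Integer volume dimensions `(nx, ny)` or `(nx, ny, nz)`.
#' @param cfg A [pipeline_config()].
#' @return List of [snake()] objects (empty, with a warning, when the volume
#'   cannot hold a single footprint).
#' @examples
#' cfg <- pipeline_config(initial_radius = 10)
#' length(initialize_lattice(c(90, 90, 90), cfg))  # 6^3 = 216
#' @export
initialize_lattice <- function(shape, cfg = pipeline_config()) {
  shape <- as.integer(shape)
  stopifnot(length(shape) %in% c(2L, 3L), all(shape >= 1L))
  R0 <- cfg$initial_radius
  footprint <- 2 * (R0 + cfg$profile$delta_R / 2)
  if (any(shape < footprint)) {
    warning("volume too small for a single snake footprint; empty lattice")
    return(list())
  }
  pitch <- cfg$lattice_pitch_factor * R0
  axes <- lapply(shape, function(n) {
    k <- floor((n - 1) / pitch) + 1
    offset <- ((n - 1) - (k - 1) * pitch) / 2
    offset + pitch * (seq_len(k) - 1)
  })
  grid <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  lapply(seq_len(nrow(grid)), function(i) snake(grid[i, ], R0))
}

#' Remove snakes above the energy threshold
#'
#' Snakes with energy strictly greater than `E0` get status `"culled-energy"`;
#' the others pass through unchanged.
#'
#' @param snakes A snake table: `data.frame` with at least columns `energy`
#'   and `status`.
#' @param E0 Energy threshold (\eqn{E_0 \le 0}).
#' @return The snake table with updated `status`.
#' @export
cull_by_energy <- function(snakes, E0) {
  stopifnot(is.data.frame(snakes), "energy" %in% names(snakes))
  active <- snakes$status == "active" | snakes$status == "converged"
  snakes$status[active & snakes$energy > E0] <- "culled-energy"
  snakes
}

overlap_pair <- function(d, R1, R2) d < max(R1, R2) / 2^(1 / 3)

#' Resolve overlapping snakes by energy competition
#'
#' Two snakes overlap when their center distance is below
#' \eqn{\max(R', R'') / 2^{1/3}} (the larger snake's inner-sphere radius).
#' Overlaps are resolved by keeping the lower-energy snake: snakes are
#' processed in ascending energy order (ties broken by lattice index) and a
#' snake is removed (status `"culled-overlap"`) if it overlaps any
#' already-accepted survivor. The greedy sweep is order-independent and
#' applies the pairwise rule transitively until no overlapping pair remains.
#'
#' @param snakes A snake table with columns `x`, `y` (and `z` in 3D),
#'   `radius`, `energy`, `status`, `index`.
#' @return The snake table with updated `status`.
#' @export
compete_overlaps <- function(snakes) {
  stopifnot(is.data.frame(snakes))
  cand <- which(snakes$status %in% c("active", "converged"))
  if (length(cand) <= 1) return(snakes)
  ord <- cand[order(snakes$energy[cand], snakes$index[cand])]
  axes <- intersect(c("x", "y", "z"), names(snakes))
  cen <- as.matrix(snakes[, axes, drop = FALSE])
  kept <- integer(0)
  for (i in ord) {
    clash <- FALSE
    for (j in kept) {
      d <- sqrt(sum((cen[i, ] - cen[j, ])^2))
      if (overlap_pair(d, snakes$radius[i], snakes$radius[j])) {
        clash <- TRUE
        break
      }
    }
    if (clash) snakes$status[i] <- "culled-overlap" else kept <- c(kept, i)
  }
  snakes
}

snake_table <- function(trajectories, d) {
  axes <- if (d == 3) c("x", "y", "z") else c("x", "y")
  if (!length(trajectories)) {
    df <- data.frame(index = integer(0))
    for (a in axes) df[[a]] <- numeric(0)
    df$radius <- numeric(0)
    df$energy <- numeric(0)
    df$iterations <- numeric(0)
    df$status <- character(0)
    return(df)
  }
  cen <- do.call(rbind, lapply(trajectories, `[[`, "center"))
  df <- data.frame(index = seq_along(trajectories))
  for (k in seq_len(d)) df[[axes[k]]] <- cen[, k]
  df$radius <- vapply(trajectories, `[[`, numeric(1), "radius")
  df$energy <- vapply(trajectories, `[[`, numeric(1), "energy")
  df$iterations <- vapply(trajectories, `[[`, numeric(1), "iterations")
  df$status <- vapply(trajectories, `[[`, character(1), "status")
  df
}

#' Detect bright blobs in an image volume
#'
#' Full detection pipeline: min-max normalization (optional), Gaussian
#' pre-smoothing (optional), lattice initialization, independent gradient
#' descent evolution of all snakes, grid-backend re-evaluation of the
#' converged energies (removing Monte-Carlo noise from the accept/reject
#' decisions), energy-threshold culling, and overlap competition.
#' Deterministic for a fixed `cfg$sampling$seed`.
#'
#' @param image 2D/3D numeric array or [image_volume()].
#' @param cfg A [pipeline_config()].
#' @return An object of class `detection_result`: `detections` (survivors as
#'   a data.frame with center, radius, energy, iterations), `snakes` (the
#'   full snake table with per-snake status), `counts` (snakes per final
#'   status), and the configuration used.
#' @export
detect <- function(image, cfg = pipeline_config()) {
  v <- as_image_data(image)
  dims <- dim(v)
  d <- length(dims)
  stopifnot(d %in% c(2L, 3L))
  profile <- cfg$profile
  if (profile$dim != d) profile <- weight_profile(profile$delta_R, dim = d)
  if (cfg$normalize) {
    rng <- range(v)
    v <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else array(0, dims)
  }
  if (cfg$sampling$presmooth_sigma > 0)
    v <- cpp_gaussian_smooth(as.numeric(v), as.integer(dims),
                             cfg$sampling$presmooth_sigma)

  lattice <- initialize_lattice(dims, cfg)
  if (!length(lattice)) {
    empty <- snake_table(list(), d)
    return(structure(list(detections = empty, snakes = empty,
                          counts = list(lattice = 0L), config = cfg,
                          dims = dims),
                     class = "detection_result"))
  }
  samp <- cfg$sampling
  samp$presmooth_sigma <- 0  # already applied
  traj <- evolve_population(v, lattice, profile, cfg$evolution, samp,
                            record_trajectories = FALSE)
  tab <- snake_table(traj, d)

  # grid-backend re-evaluation at the converged configuration
  R_min <- resolve_R_min(cfg$evolution, profile)
  for (i in seq_len(nrow(tab))) {
    if (tab$status[i] == "culled-domain") next
    if (tab$radius[i] < R_min) {
      tab$status[i] <- "culled-domain"
      next
    }
    cen <- as.numeric(tab[i, if (d == 3) c("x", "y", "z") else c("x", "y")])
    tab$energy[i] <- cpp_grid_eval(as.numeric(v), as.integer(dims), cen,
                                   tab$radius[i], unclass(profile),
                                   FALSE)$energy
  }
  tab <- cull_by_energy(tab, cfg$energy_threshold)
  tab <- compete_overlaps(tab)

  survivors <- tab[tab$status %in% c("active", "converged"), , drop = FALSE]
  rownames(survivors) <- NULL
  counts <- table(tab$status)
  structure(
    list(detections = survivors, snakes = tab,
         counts = c(lattice = length(lattice), as.list(counts)),
         config = cfg, dims = dims),
    class = "detection_result"
  )
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("<detection_result> %d survivors from %d initial snakes\n",
              nrow(x$detections), x$counts$lattice))
  cts <- x$counts[names(x$counts) != "lattice"]
  if (length(cts))
    cat("  ", paste(sprintf("%s=%s", names(cts), unlist(cts)),
                    collapse = ", "), "\n", sep = "")
  invisible(x)
}
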