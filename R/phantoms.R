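#' Synthetic sphere-phantom specification
#'
#' Describes a synthetic test image: bright spheres of known centers and radii
#' on a dark background, with smoothed edges (so the integrand is smooth, as
#' Monte-Carlo estimation assumes) and optional calibrated Gaussian noise
#' added separately with [add_gaussian_noise()].
#'
#' @param shape Volume dimensions `(nx, ny)` or `(nx, ny, nz)`,
#'   default `c(128, 128, 128)`.
#' @param n_spheres Number of spheres (default 20).
#' @param radius_range Sphere radius range in voxels, default `c(8, 12)`
#'   (radii drawn uniformly).
#' @param min_separation Minimum pairwise center distance, default
#'   `2.2 * max(radius_range)` (well-separated, non-overlapping spheres).
#' @param fg,bg Foreground / background intensities (defaults 1 and 0).
#' @param smooth_sigma Gaussian edge-smoothing width in voxels (default 1).
#' @param seed Integer seed; the same seed reproduces the phantom bit for bit.
#' @param max_tries Rejection-sampling retry cap for the packing.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(128, 128, 128), n_spheres = 20,
                         radius_range = c(8, 12), min_separation = NULL,
                         fg = 1, bg = 0, smooth_sigma = 1, seed = 1,
                         max_tries = 10000) {
  shape <- as.integer(shape)
  stopifnot(length(shape) %in% c(2L, 3L), all(shape >= 8L), n_spheres >= 0,
            length(radius_range) == 2, all(radius_range > 0),
            radius_range[1] <= radius_range[2], fg > bg, smooth_sigma >= 0)
  if (is.null(min_separation)) min_separation <- 2.2 * max(radius_range)
  structure(
    list(shape = shape, n_spheres = as.integer(n_spheres),
         radius_range = radius_range, min_separation = min_separation,
         fg = fg, bg = bg, smooth_sigma = smooth_sigma,
         seed = as.integer(seed), max_tries = as.integer(max_tries)),
    class = "phantom_spec"
  )
}

#' Generate a sphere phantom with known ground truth
#'
#' Rejection-samples non-overlapping sphere centers (respecting
#' `min_separation` and an in-volume margin of one radius plus the smoothing
#' support), voxelizes the spheres, and smooths the edges. The exact centers
#' and radii are returned as the ground-truth table.
#'
#' @param spec A [phantom_spec()].
#' @return List with `volume` (an [image_volume()]) and `truth` (data.frame
#'   with columns `z`, `y`, `x` — or `y`, `x` in 2D — and `r0`, in 0-based
#'   voxel coordinates).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  d <- length(spec$shape)
  set.seed(spec$seed)
  centers <- matrix(numeric(0), 0, d)
  radii <- numeric(0)
  if (spec$n_spheres > 0) {
    tries <- 0
    while (nrow(centers) < spec$n_spheres) {
      r <- stats::runif(1, spec$radius_range[1], spec$radius_range[2])
      margin <- r + 3 * spec$smooth_sigma + 1
      lo <- margin
      hi <- spec$shape - 1 - margin
      if (any(hi < lo))
        stop("phantom spheres do not fit inside the volume", call. = FALSE)
      cand <- stats::runif(d, lo, hi)
      ok <- TRUE
      if (nrow(centers)) {
        dists <- sqrt(colSums((t(centers) - cand)^2))
        ok <- all(dists >= spec$min_separation)
      }
      if (ok) {
        centers <- rbind(centers, cand)
        radii <- c(radii, r)
      }
      tries <- tries + 1
      if (tries > spec$max_tries)
        stop("could not pack ", spec$n_spheres, " spheres after ",
             spec$max_tries, " tries; relax the separation or count",
             call. = FALSE)
    }
  }
  v <- cpp_fill_spheres(spec$shape, centers, radii, spec$fg, spec$bg)
  if (spec$smooth_sigma > 0)
    v <- cpp_gaussian_smooth(v, spec$shape, spec$smooth_sigma)
  truth <- as.data.frame(centers)
  names(truth) <- c("x", "y", "z")[seq_len(d)]
  truth <- truth[, rev(seq_len(d)), drop = FALSE]  # report as z, y, x
  truth$r0 <- radii
  rownames(truth) <- NULL
  list(volume = image_volume(v), truth = truth)
}

#' Add Gaussian noise at a specified signal-to-noise ratio
#'
#' Adds zero-mean Gaussian noise with variance
#' \eqn{\sigma^2 = P_{signal} / 10^{snr/10}}, where \eqn{P_{signal}} is the
#' mean squared intensity of the clean image (background included). By
#' default the result is *not* clamped to `[0, 1]`, keeping the realized SNR
#' exact; set `clamp = TRUE` to clip.
#'
#' @param image 2D/3D numeric array or [image_volume()].
#' @param snr_db Target signal-to-noise ratio in decibels,
#'   \eqn{10 \log_{10}(P_{signal}/P_{noise})}.
#' @param seed Integer seed (same seed, same noise field).
#' @param clamp Clip the output to `[0, 1]`.
#' @return Noisy image of the same type as the input.
#' @export
add_gaussian_noise <- function(image, snr_db, seed = 1, clamp = FALSE) {
  v <- as_image_data(image)
  p_signal <- mean(v^2)
  if (p_signal <= 0)
    stop("all-zero image: SNR is undefined", call. = FALSE)
  sigma <- sqrt(p_signal / 10^(snr_db / 10))
  set.seed(seed)
  out <- v + stats::rnorm(length(v), 0, sigma)
  if (clamp) out <- pmin(1, pmax(0, out))
  dim(out) <- dim(v)
  if (inherits(image, "image_volume")) {
    image$data <- out
    image
  } else {
    out
  }
}
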