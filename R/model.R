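#' Radial weight profile of a snakuscule
#'
#' A snakuscule weighs image intensity with a differentiable radial profile
#' `S(r)`: a negative inner core (radius `rho * R`), a positive annulus
#' (up to radius `R`), smooth cubic transition ramps of fixed widths `delta_r`
#' (inner) and `delta_R` (outer), and zero beyond `R + delta_R / 2`. The
#' inner-core magnitude is solved in closed form so that the profile's
#' second-moment integral (first moment in 2D) vanishes,
#' \eqn{\int_0^\infty S(r) r^{d-1} dr = 0}, which makes the energy exactly
#' zero on constant images. The transition widths stay fixed while the
#' footprint scales with `R`.
#'
#' The inner/outer radius ratio `rho` defaults to the equal-measure value
#' \eqn{2^{-1/3}} in 3D (equal volumes) and \eqn{2^{-1/2}} in 2D (equal
#' areas), and the inner width is tied to the outer one by
#' `delta_r = delta_R * rho`.
#'
#' @param delta_R Outer transition width in voxels (default 4).
#' @param dim Image dimensionality, 2 or 3.
#' @param rho Inner-to-outer radius ratio; default the equal-measure value.
#' @return An object of class `weight_profile`.
#' @examples
#' prof <- weight_profile(delta_R = 4, dim = 3)
#' weight_value(c(0, 15, 25), R = 20, profile = prof)
#' @export
weight_profile <- function(delta_R = 4, dim = 3, rho = NULL) {
  stopifnot(dim %in% c(2L, 3L), delta_R > 0)
  if (is.null(rho)) rho <- if (dim == 3) 2^(-1 / 3) else 2^(-1 / 2)
  stopifnot(rho > 0, rho < 1)
  structure(
    list(dim = as.integer(dim), rho = rho, delta_R = delta_R,
         delta_r = delta_R * rho),
    class = "weight_profile"
  )
}

#' @export
print.weight_profile <- function(x, ...) {
  cat(sprintf(
    "<weight_profile> dim=%d rho=%.6f delta_R=%g delta_r=%g\n",
    x$dim, x$rho, x$delta_R, x$delta_r))
  invisible(x)
}

check_snake_radius <- function(R, profile) {
  if (!is.finite(R) || R <= profile$delta_R)
    stop("degenerate snake: radius R = ", format(R),
         " must exceed the outer transition width delta_R = ",
         profile$delta_R, call. = FALSE)
  invisible(TRUE)
}

#' Evaluate the radial weight function
#'
#' Returns the signed weight `S(r)` for a snake of radius `R`: negative on the
#' inner core, positive on the annulus, exactly zero at and beyond
#' `R + delta_R / 2`, and continuously differentiable everywhere.
#'
#' @param r Radial distances (voxels), vectorized.
#' @param R Snake radius (voxels); must exceed `profile$delta_R`.
#' @param profile A [weight_profile()].
#' @param derivatives If `TRUE` return a list with `S`, `dS_dr` and `dS_dR`.
#' @return Numeric vector of weights (or a list when `derivatives = TRUE`).
#' @export
weight_value <- function(r, R, profile = weight_profile(), derivatives = FALSE) {
  stopifnot(all(r >= 0))
  check_snake_radius(R, profile)
  ev <- cpp_weight_eval(as.numeric(r), R, unclass(profile))
  if (derivatives)
    list(S = ev$S, dS_dr = ev$S_r, dS_dR = ev$S_R)
  else
    ev$S
}

#' Inner-core weight magnitude
#'
#' The magnitude `A` of the (negative) inner-core weight that balances the
#' profile's moment integral to zero for a snake of radius `R`, together with
#' its derivative `dA/dR` (needed for analytic energy gradients).
#'
#' @inheritParams weight_value
#' @return List with elements `A` and `dA_dR`.
#' @export
weight_core_magnitude <- function(R, profile = weight_profile()) {
  check_snake_radius(R, profile)
  ev <- cpp_core_magnitude(R, unclass(profile))
  list(A = ev$A, dA_dR = ev$dA_dR)
}

#' Construct a snake (concentric-sphere active contour)
#'
#' A snake is parameterized by two points `p` and `q` that are collinear along
#' the first (x) axis and share the remaining coordinates, so it is fully
#' described by its center `c = (p + q) / 2` and radius `R = ||p - q|| / 2`.
#' Coordinates are 0-based voxel units (voxel centers at integers).
#'
#' @param center Numeric center `(x, y)` or `(x, y, z)`.
#' @param radius Snake radius in voxels (> 0).
#' @param status Snake status string.
#' @return An object of class `snake` with fields `p`, `q`, `center`,
#'   `radius`, `energy`, `status`.
#' @examples
#' s <- snake(c(32, 32, 32), radius = 12)
#' s$p; s$q
#' @export
snake <- function(center, radius, status = "active") {
  center <- as.numeric(center)
  stopifnot(length(center) %in% c(2L, 3L), is.finite(radius), radius > 0)
  p <- center; p[1] <- center[1] - radius
  q <- center; q[1] <- center[1] + radius
  structure(
    list(p = p, q = q, center = center, radius = radius,
         energy = NA_real_, status = status),
    class = "snake"
  )
}

#' @export
print.snake <- function(x, ...) {
  cat(sprintf("<snake> center=(%s) R=%.3f status=%s energy=%s\n",
              paste(sprintf("%.3f", x$center), collapse = ", "),
              x$radius, x$status,
              if (is.na(x$energy)) "NA" else sprintf("%.5f", x$energy)))
  invisible(x)
}

snake_dim <- function(s) length(s$center)

#' @rdname snake
#' @param s A `snake`.
#' @export
snake_center <- function(s) s$center

#' @rdname snake
#' @export
snake_radius <- function(s) s$radius

#' Closed-form energy of a snake concentric with a binary blob
#'
#' For the ideal blob model \eqn{I(r) = 1 + \mathrm{sgn}(r_0 - r)} (intensity
#' 2 strictly inside radius `r0`, 0 strictly outside) the unnormalized
#' contour energy of a concentric snake of radius `R` has a closed form with
#' three branches: zero while the snake is inside the blob, then decreasing
#' while the blob boundary crosses the annulus, then constant
#' \eqn{-(8/3)\pi r_0^3} once the inner sphere contains the blob
#' (3D; the 2D analogue is \eqn{-2\pi r_0^2}).
#'
#' @param R Snake radius (> 0), vectorized.
#' @param r0 Blob radius (> 0).
#' @param dim 2 or 3.
#' @return Energy \eqn{\hat E} (sharp-weight limit, no normalization).
#' @examples
#' closed_form_sphere_energy(2^(1/3), r0 = 1)  # -(8/3)*pi
#' @export
closed_form_sphere_energy <- function(R, r0, dim = 3) {
  stopifnot(all(R > 0), r0 > 0, dim %in% c(2, 3))
  if (dim == 3) {
    opt <- 2^(1 / 3) * r0
    ifelse(R < r0, 0,
           ifelse(R < opt, -(8 / 3) * pi * (R^3 - r0^3),
                  -(8 / 3) * pi * r0^3))
  } else {
    opt <- sqrt(2) * r0
    ifelse(R < r0, 0,
           ifelse(R < opt, -2 * pi * (R^2 - r0^2),
                  -2 * pi * r0^2))
  }
}

#' Radius-normalized energy
#'
#' Divides an unnormalized energy by `R^alpha` so that contours are penalized
#' for growing beyond the blob; with the symmetrizing exponent (`alpha = 3`
#' in 3D, `alpha = 2` in 2D) the normalized energy of the binary blob has a
#' single local minimum at `R = r0 / rho`.
#'
#' @param E_hat Unnormalized energy.
#' @param R Snake radius (> 0).
#' @param alpha Normalization exponent (> 0), default 3.
#' @export
normalized_energy <- function(E_hat, R, alpha = 3) {
  stopifnot(all(R > 0), alpha > 0)
  E_hat / R^alpha
}

#' Recover the normalization exponent by gradient symmetry
#'
#' The exponent `alpha` is fixed by requiring the normalized energy's slope
#' magnitudes to match on both sides of its optimum \eqn{R^* = r_0/\rho} for
#' the ideal binary blob: approaching contours should expand at the same rate
#' that oversized contours contract. This routine evaluates the one-sided
#' numerical slopes from the closed-form energy and solves the symmetry
#' condition for `alpha`.
#'
#' @param r0 Blob radius used for the closed-form model.
#' @param dim 2 or 3.
#' @param h Relative step for the one-sided finite differences.
#' @return The symmetrizing exponent (3 in 3D, 2 in 2D).
#' @export
recover_normalization_exponent <- function(r0 = 1, dim = 3, h = 1e-6) {
  stopifnot(r0 > 0, dim %in% c(2, 3))
  Rstar <- if (dim == 3) 2^(1 / 3) * r0 else sqrt(2) * r0
  hh <- h * r0
  slope <- function(alpha, side) {
    # one-sided secant slopes of E_hat / R^alpha just left/right of R*
    if (side < 0) {
      R1 <- Rstar - 2 * hh; R2 <- Rstar - hh
    } else {
      R1 <- Rstar + hh; R2 <- Rstar + 2 * hh
    }
    e1 <- normalized_energy(closed_form_sphere_energy(R1, r0, dim), R1, alpha)
    e2 <- normalized_energy(closed_form_sphere_energy(R2, r0, dim), R2, alpha)
    (e2 - e1) / (R2 - R1)
  }
  # symmetry condition: slope_left(alpha) = -slope_right(alpha)
  f <- function(alpha) slope(alpha, -1) + slope(alpha, +1)
  stats::uniroot(f, interval = c(0.05, 10), tol = 1e-10)$root
}

as_image_data <- function(image) {
  if (inherits(image, "image_volume")) image$data else image
}

image_dims <- function(image) {
  d <- dim(as_image_data(image))
  if (is.null(d) || !length(d) %in% c(2L, 3L))
    stop("image must be a 2D or 3D array (or image_volume)", call. = FALSE)
  d
}

check_snake_image <- function(image, s, profile) {
  d <- image_dims(image)
  if (length(d) != snake_dim(s))
    stop("snake dimensionality (", snake_dim(s),
         ") does not match image dimensionality (", length(d), ")",
         call. = FALSE)
  if (length(d) != profile$dim)
    stop("weight profile dim (", profile$dim,
         ") does not match image dimensionality (", length(d), ")",
         call. = FALSE)
  invisible(d)
}

#' Discrete snake energy (exhaustive grid backend)
#'
#' Sums the weighted intensities over every voxel within `R + delta_R / 2` of
#' the snake center and normalizes by \eqn{\|p - q\|^{d}} (i.e. \eqn{(2R)^d}).
#' The inner-core weight is re-balanced on the actual voxel lattice so that a
#' constant image yields exactly zero energy. Voxels outside the image domain
#' contribute zero intensity.
#'
#' @param image A 2D/3D numeric array or an [image_volume()].
#' @param s A [snake()].
#' @param profile A [weight_profile()].
#' @return Scalar energy (dimensionless for intensities in `[0, 1]`).
#' @export
discrete_energy <- function(image, s, profile = weight_profile()) {
  dims <- check_snake_image(image, s, profile)
  check_snake_radius(s$radius, profile)
  v <- as_image_data(image)
  cpp_grid_eval(as.numeric(v), as.integer(dims), s$center, s$radius,
                unclass(profile), FALSE)$energy
}

#' Analytic energy gradient (exhaustive grid backend)
#'
#' Partial derivatives of [discrete_energy()] with respect to the snake's
#' independent parameters, computed analytically through the chain rule on
#' the weight profile (including the radius dependence of the re-balanced
#' inner-core weight). Because `p` and `q` share cross-axis coordinates there
#' are `dim + 1` independent components.
#'
#' @inheritParams discrete_energy
#' @return Named numeric vector: `px`, `qx`, `y` (and `z` in 3D), where the
#'   `y`/`z` entries are the shared \eqn{\partial E/\partial p_y =
#'   \partial E/\partial q_y} components.
#' @export
energy_gradient <- function(image, s, profile = weight_profile()) {
  dims <- check_snake_image(image, s, profile)
  check_snake_radius(s$radius, profile)
  v <- as_image_data(image)
  g <- cpp_grid_eval(as.numeric(v), as.integer(dims), s$center, s$radius,
                     unclass(profile), TRUE)$gradient
  names(g) <- if (length(dims) == 3) c("px", "qx", "y", "z") else c("px", "qx", "y")
  g
}
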