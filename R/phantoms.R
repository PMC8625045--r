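#' Configuration for random square-ring phantoms
#'
#' The training corpus consists of square-shaped rings (square annuli)
#' with random side length, thickness, location and intensity profile,
#' placed so that the whole ring lies strictly inside the unit disc.
#' The intensity on the ring is a base value drawn uniformly from
#' `intensity_range` times a random low-order (affine) modulation along
#' the ring, clipped to `[0, 1]` — non-constant profiles without
#' committing to a specific law.
#'
#' @param side_range Range of outer side lengths (length units; disc
#'   radius is 1).
#' @param thickness_range Range of ring thicknesses.
#' @param intensity_range Range of base intensities in `[0, 1]`.
#' @param modulation Maximum relative amplitude of the affine profile
#'   modulation across the ring (0 disables it).
#' @param margin Clearance kept between the ring and the unit circle.
#' @param rotate Whether to rotate each ring by a random angle (default
#'   axis-aligned).
#' @param n_rings Rings per image (1 to 3).
#' @return An object of class `ring_phantom_config`.
#' @export
ring_phantom_config <- function(side_range = c(0.5, 1.0),
                                thickness_range = c(0.08, 0.2),
                                intensity_range = c(0.4, 1),
                                modulation = 0.5,
                                margin = 0.05,
                                rotate = FALSE,
                                n_rings = 1) {
  stopifnot(
    length(side_range) == 2, length(thickness_range) == 2,
    length(intensity_range) == 2,
    all(side_range > 0), all(thickness_range >= 0),
    all(intensity_range >= 0), all(intensity_range <= 1),
    diff(side_range) >= 0, diff(thickness_range) >= 0,
    diff(intensity_range) >= 0,
    modulation >= 0, margin >= 0, n_rings >= 1, n_rings <= 3
  )
  if (max(side_range) * sqrt(2) / 2 >= 1 - margin) {
    stop(
      "side_range allows rings whose corners cannot fit inside the unit disc",
      call. = FALSE
    )
  }
  structure(
    list(
      side_range = side_range, thickness_range = thickness_range,
      intensity_range = intensity_range, modulation = modulation,
      margin = margin, rotate = rotate, n_rings = as.integer(n_rings)
    ),
    class = "ring_phantom_config"
  )
}

# one ring, given already-drawn parameters; returns vector over pixels
ring_values <- function(grid, center, half_side, thickness, base, mod12,
                        angle = 0) {
  u <- grid$centers[, 1] - center[1]
  v <- grid$centers[, 2] - center[2]
  if (angle != 0) {
    cu <- cos(angle) * u + sin(angle) * v
    cv <- -sin(angle) * u + cos(angle) * v
    u <- cu
    v <- cv
  }
  cheb <- pmax(abs(u), abs(v))
  inside <- cheb <= half_side & cheb > half_side - thickness
  val <- numeric(nrow(grid$centers))
  val[inside] <- pmin(1, pmax(
    0,
    base * (1 + mod12[1] * u[inside] / half_side +
      mod12[2] * v[inside] / half_side)
  ))
  val
}

#' Random square-ring phantom
#'
#' Draws one image from the training distribution: `n_rings` square
#' annuli with random geometry and affine intensity modulation, values in
#' `[0, 1]`, support strictly inside the unit disc.  Deterministic given
#' the seed.
#'
#' @param grid A [grid_spec].
#' @param cfg A [ring_phantom_config].
#' @param seed Integer seed.
#' @return Coefficient vector of length `N^2` (flat pixel order).
#' @export
#' @examples
#' x <- square_ring_phantom(grid_spec(64), ring_phantom_config(), seed = 1)
#' range(x)
square_ring_phantom <- function(grid, cfg = ring_phantom_config(), seed) {
  stopifnot(inherits(grid, "grid_spec"), inherits(cfg, "ring_phantom_config"))
  withr::with_seed(as.integer(seed), {
    val <- numeric(grid$N^2)
    for (r in seq_len(cfg$n_rings)) {
      side <- stats::runif(1, cfg$side_range[1], cfg$side_range[2])
      thick <- stats::runif(1, cfg$thickness_range[1], cfg$thickness_range[2])
      thick <- min(thick, side / 2)
      base <- stats::runif(1, cfg$intensity_range[1], cfg$intensity_range[2])
      mod12 <- stats::runif(2, -cfg$modulation, cfg$modulation)
      ang <- if (cfg$rotate) stats::runif(1, 0, pi / 2) else 0
      half_side <- side / 2
      rmax <- 1 - cfg$margin - half_side * sqrt(2)
      if (rmax < 0) {
        stop("ring cannot fit inside the unit disc with this margin",
          call. = FALSE
        )
      }
      th <- stats::runif(1, 0, 2 * pi)
      rad <- rmax * sqrt(stats::runif(1))
      center <- rad * c(cos(th), sin(th))
      val <- val + ring_values(grid, center, half_side, thick, base, mod12, ang)
    }
    pmin(1, val)
  })
}

#' Superposition-of-discs phantom
#'
#' A deterministic phantom made of filled discs, used as the
#' out-of-distribution test object: its circular structures are absent
#' from the square-ring training corpus.
#'
#' @param grid A [grid_spec].
#' @param circles Data frame with columns `x`, `y`, `radius`, `intensity`
#'   (one row per disc).  Every disc must lie inside the unit disc.  An
#'   empty frame gives the zero image.
#' @return Coefficient vector of length `N^2`, values clipped to `[0, 1]`.
#' @export
#' @examples
#' ph <- circles_phantom(
#'   grid_spec(64),
#'   data.frame(x = c(0, 0.4), y = c(0, -0.2), radius = c(0.25, 0.12),
#'              intensity = c(0.8, 1))
#' )
circles_phantom <- function(grid, circles) {
  stopifnot(inherits(grid, "grid_spec"), is.data.frame(circles))
  val <- numeric(grid$N^2)
  if (nrow(circles) == 0) return(val)
  need <- c("x", "y", "radius", "intensity")
  if (!all(need %in% names(circles))) {
    stop("circles needs columns x, y, radius, intensity", call. = FALSE)
  }
  for (i in seq_len(nrow(circles))) {
    cc <- circles[i, ]
    if (cc$radius <= 0) stop("disc radius must be positive", call. = FALSE)
    if (sqrt(cc$x^2 + cc$y^2) + cc$radius > 1) {
      stop("disc ", i, " extends outside the unit disc", call. = FALSE)
    }
    inside <- (grid$centers[, 1] - cc$x)^2 + (grid$centers[, 2] - cc$y)^2 <=
      cc$radius^2
    val[inside] <- val[inside] + cc$intensity
  }
  pmin(1, pmax(0, val))
}

#' Default out-of-distribution circles phantom
#'
#' Three filled discs of different sizes and intensities, all inside the
#' unit disc and overlapping the masked stripe region for the default
#' mask.  Used by the reconstruction study as the structure-mismatch test
#' case.
#'
#' @param grid A [grid_spec].
#' @return Coefficient vector of length `N^2`.
#' @export
default_circles_phantom <- function(grid) {
  circles_phantom(grid, data.frame(
    x = c(-0.25, 0.35, 0.1),
    y = c(0.3, -0.1, -0.45),
    radius = c(0.3, 0.18, 0.1),
    intensity = c(0.7, 1, 0.9)
  ))
}

#' Generate a training dataset of phantoms and basic reconstructions
#'
#' Draws `n` square-ring phantoms `x_a` and forms their basic
#' reconstructions `h_a = A+(A x_a + eta_a)` with relative noise level
#' `sigma`: the pairs the regularizer is trained on, `x_a` being the
#' desired output and `h_a` the artifact-laden input.  Per-item seeds are
#' derived deterministically from the master seed, so regeneration is
#' bit-identical; phantom and noise draws use disjoint seed offsets.
#'
#' @param grid A [grid_spec].
#' @param op A `truncated_operator` over the same grid.
#' @param n Number of pairs (>= 1).
#' @param sigma Relative noise level for the simulated data.
#' @param cfg A [ring_phantom_config].
#' @param seed Master seed.
#' @return An object of class `nett_dataset`: list with `x` and `h`
#'   (`N^2 x n` matrices), `sigma`, `seed`, `cfg`.
#' @export
generate_dataset <- function(grid, op, n, sigma = 0.01,
                             cfg = ring_phantom_config(), seed = 1) {
  stopifnot(n >= 1, inherits(op, "truncated_operator"))
  n <- as.integer(n)
  x <- matrix(0, nrow = grid$N^2, ncol = n)
  h <- matrix(0, nrow = grid$N^2, ncol = n)
  for (a in seq_len(n)) {
    xa <- square_ring_phantom(grid, cfg, seed = seed + a)
    ya <- simulate_noisy_data(op, xa, sigma, seed = seed + 1000000L + a)
    x[, a] <- xa
    h[, a] <- pinv_apply(op, ya)
  }
  structure(
    list(x = x, h = h, sigma = sigma, seed = as.integer(seed), cfg = cfg),
    class = "nett_dataset"
  )
}

#' @export
print.nett_dataset <- function(x, ...) {
  cat(
    "<nett_dataset> ", ncol(x$x), " pairs, N^2 = ", nrow(x$x),
    ", sigma = ", x$sigma, ", seed = ", x$seed, "\n",
    sep = ""
  )
  invisible(x)
}
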