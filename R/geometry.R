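#' Pixel grid on the square enclosing the unit disc
#'
#' Defines the discretization of the image domain used by the forward
#' operator: an `N` x `N` lattice of pixel centers
#' `c(i) = ((2*i1 - N - 1)/N, (2*i2 - N - 1)/N)` covering `[-1, 1]^2` with
#' spacing `2/N`.  The detection circle has radius 1 in these units, so the
#' lattice is symmetric under `r -> -r` and covers the unit disc where
#' phantoms live.
#'
#' Index pairs `(i1, i2)` are 1-based and flattened as `N*(i1-1) + i2`
#' (see [pixel_flat_index()]); all coefficient vectors in the package use
#' this ordering.
#'
#' @param N Number of pixels per axis (>= 2).
#' @return An object of class `grid_spec` with fields `N`, `spacing` and
#'   `centers` (an `N^2` x 2 matrix of pixel centers in flat-index order).
#' @export
#' @examples
#' g <- grid_spec(8)
#' range(g$centers)
grid_spec <- function(N) {
  stopifnot(length(N) == 1, is.finite(N), N == round(N))
  if (N < 2) stop("N must be at least 2", call. = FALSE)
  N <- as.integer(N)
  ax <- (2 * seq_len(N) - N - 1) / N
  # flat order N*(i1-1)+i2: i2 varies fastest
  centers <- cbind(
    x1 = rep(ax, each = N),
    x2 = rep(ax, times = N)
  )
  structure(
    list(N = N, spacing = 2 / N, centers = centers),
    class = "grid_spec"
  )
}

#' Circular sensor array and time sampling
#'
#' `Ns` point sensors sit at uniformly spaced angles on the unit circle
#' `S^1`; measurement times are `Nt` uniform samples of `[0, 2]` (the sound
#' speed is 1, so time 2 is the transit time across the disc diameter).
#'
#' @param Ns Number of sensors (>= 2).
#' @param Nt Number of time samples (>= 2).
#' @param angle_offset Angle of the first sensor in radians (default 0).
#' @return An object of class `sensor_geometry` with fields `Ns`, `Nt`,
#'   `locations` (`Ns` x 2 matrix on the unit circle) and `times`
#'   (increasing vector in `[0, 2]`).
#' @export
sensor_geometry <- function(Ns, Nt, angle_offset = 0) {
  stopifnot(length(Ns) == 1, length(Nt) == 1, is.finite(Ns), is.finite(Nt))
  if (Ns < 2 || Nt < 2) stop("Ns and Nt must be at least 2", call. = FALSE)
  Ns <- as.integer(Ns)
  Nt <- as.integer(Nt)
  th <- angle_offset + 2 * pi * (seq_len(Ns) - 1) / Ns
  structure(
    list(
      Ns = Ns, Nt = Nt,
      locations = cbind(x1 = cos(th), x2 = sin(th)),
      times = seq(0, 2, length.out = Nt)
    ),
    class = "sensor_geometry"
  )
}

#' Diagonal no-data stripe
#'
#' The masked region `I` is a stripe of the given width around one of the
#' two diagonals of the image square: points at perpendicular distance
#' `< width/2` from the line `x1 = x2` (`orientation = "main"`) or
#' `x1 = -x2` (`orientation = "anti"`).  Pixels inside `I` generate no
#' acoustic data, turning reconstruction into a joint wave-inversion and
#' inpainting problem.
#'
#' @param width Stripe width `w >= 0` in grid length units; `0` means no
#'   masking.
#' @param orientation `"main"` or `"anti"`.
#' @return An object of class `mask_spec`.
#' @export
mask_spec <- function(width = 0.34, orientation = c("main", "anti")) {
  stopifnot(length(width) == 1, is.finite(width))
  if (width < 0) stop("mask width must be non-negative", call. = FALSE)
  orientation <- match.arg(orientation)
  structure(list(width = width, orientation = orientation), class = "mask_spec")
}

#' Build grid and sensor geometry together
#'
#' Convenience constructor for the discretization used throughout:
#' pixel grid, sensor circle and time axis.
#'
#' @inheritParams grid_spec
#' @inheritParams sensor_geometry
#' @return A list with elements `grid` ([grid_spec]) and `sensors`
#'   ([sensor_geometry]).
#' @export
#' @examples
#' geo <- build_geometry(N = 32, Ns = 40, Nt = 32)
#' geo$grid$N
build_geometry <- function(N, Ns, Nt, angle_offset = 0) {
  list(grid = grid_spec(N), sensors = sensor_geometry(Ns, Nt, angle_offset))
}

#' Flat pixel index and its inverse
#'
#' Index pairs `(i1, i2)` in `{1..N}^2` map to the flat index
#' `N*(i1-1) + i2`; `pixel_index_pair()` inverts the map.
#'
#' @param i1,i2 Integer vectors of row/column indices in `1..N`.
#' @param k Integer vector of flat indices in `1..N^2`.
#' @param N Pixels per axis.
#' @return `pixel_flat_index()` returns an integer vector;
#'   `pixel_index_pair()` a two-column integer matrix.
#' @export
pixel_flat_index <- function(i1, i2, N) {
  as.integer(N) * (as.integer(i1) - 1L) + as.integer(i2)
}

#' @rdname pixel_flat_index
#' @export
pixel_index_pair <- function(k, N) {
  k <- as.integer(k)
  cbind(i1 = (k - 1L) %/% as.integer(N) + 1L, i2 = (k - 1L) %% as.integer(N) + 1L)
}

#' Indicator of the unmasked pixels
#'
#' Returns the diagonal of the masking matrix `M_I` as a vector of length
#' `N^2` in flat-index order: 1 where the pixel center lies outside the
#' stripe `I` (perpendicular distance >= `width/2` from the stripe axis),
#' 0 where the pixel is masked and generates no data.
#'
#' @param grid A [grid_spec].
#' @param mask A [mask_spec].
#' @return Numeric 0/1 vector of length `N^2`.
#' @export
#' @examples
#' g <- grid_spec(16)
#' sum(mask_indicator(g, mask_spec(0.34)) == 0)  # masked pixel count
mask_indicator <- function(grid, mask) {
  stopifnot(inherits(grid, "grid_spec"), inherits(mask, "mask_spec"))
  if (mask$width == 0) return(rep(1, grid$N^2))
  u <- if (mask$orientation == "main") c(1, -1) / sqrt(2) else c(1, 1) / sqrt(2)
  dist <- abs(grid$centers %*% u)
  as.numeric(dist >= mask$width / 2)
}

#' Convert between coefficient vectors and image matrices
#'
#' Coefficient vectors use the flat order `N*(i1-1) + i2`, i.e. the second
#' index varies fastest.  The image matrix has `x[i1, i2]` at row `i1`,
#' column `i2`.
#'
#' @param x Coefficient vector of length `N^2`, or an `N` x `N` matrix.
#' @param N Pixels per axis (inferred for matrices).
#' @return `coef_to_image()` returns an `N` x `N` matrix;
#'   `image_to_coef()` the flat coefficient vector.
#' @export
coef_to_image <- function(x, N = NULL) {
  if (is.matrix(x)) return(x)
  if (is.null(N)) N <- as.integer(round(sqrt(length(x))))
  if (length(x) != N * N) stop("length(x) must equal N^2", call. = FALSE)
  matrix(x, nrow = N, ncol = N, byrow = TRUE)
}

#' @rdname coef_to_image
#' @export
image_to_coef <- function(x) {
  if (!is.matrix(x)) return(as.numeric(x))
  as.numeric(t(x))
}
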