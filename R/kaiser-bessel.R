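#' Kaiser-Bessel basis parameters
#'
#' Generalized Kaiser-Bessel (KB) functions are the radially symmetric,
#' compactly supported basis functions standard in tomographic
#' discretization.  The profile with order `m`, taper `gamma` and support
#' radius `R` is
#' \deqn{\psi(\rho) = (1 - \rho^2/R^2)^{m/2}
#'   \, I_m(\gamma\sqrt{1 - \rho^2/R^2}) / I_m(\gamma), \quad \rho \le R,}
#' and 0 beyond `R`, where `I_m` is the modified Bessel function of the
#' first kind.  For `m >= 1` the profile vanishes continuously at the
#' support boundary; `m = 2` additionally has a continuous derivative
#' there, which keeps the simulated pressure traces smooth.
#'
#' @param m Order (integer >= 1); controls boundary smoothness.
#' @param gamma Window taper (> 0); larger values concentrate the blob.
#' @param R Support radius in grid length units (> 0).  A sensible default
#'   is about twice the pixel spacing.
#' @return An object of class `kb_params`.
#' @export
#' @examples
#' kb <- kb_params(m = 2, gamma = 3, R = 0.1)
#' kb_profile(c(0, 0.05, 0.1, 0.2), kb)
kb_params <- function(m = 2, gamma = 3, R) {
  stopifnot(length(m) == 1, length(gamma) == 1, length(R) == 1)
  if (m < 1 || m != round(m)) stop("m must be an integer >= 1", call. = FALSE)
  if (gamma <= 0) stop("gamma must be positive", call. = FALSE)
  if (R <= 0) stop("R must be positive", call. = FALSE)
  structure(list(m = as.integer(m), gamma = gamma, R = R), class = "kb_params")
}

#' Kaiser-Bessel radial profile
#'
#' Evaluates the KB profile at radial distances `rho`; returns 0 for
#' `rho > R` (the blob has compact support).
#'
#' @param rho Non-negative radial distances (vectorized).
#' @param kb A [kb_params] object.
#' @return Numeric vector of profile values; `kb_profile(0, kb)` is 1.
#' @export
kb_profile <- function(rho, kb) {
  stopifnot(inherits(kb, "kb_params"))
  out <- numeric(length(rho))
  inside <- rho <= kb$R
  if (any(inside)) {
    u <- sqrt(pmax(0, 1 - (rho[inside] / kb$R)^2))
    out[inside] <- u^kb$m * besselI(kb$gamma * u, kb$m) / besselI(kb$gamma, kb$m)
  }
  out
}

# rho * psi(rho), extended oddly; the 1D d'Alembert profile of the 3D wave
kb_g <- function(rho, kb) rho * kb_profile(abs(rho), kb)

#' Pressure trace of a Kaiser-Bessel source
#'
#' Solution of the 3D free-space wave equation with initial pressure
#' `psi(|r|)` (a KB blob at the origin) and zero initial velocity,
#' evaluated at distance `d` from the blob center and time `t` (sound
#' speed 1).  For a radial profile the Poisson-Kirchhoff spherical-mean
#' solution reduces to the closed form
#' \deqn{p(d, t) = \frac{1}{2d}\left[g(d + t) - \mathrm{sign}(t - d)\,
#'   g(|d - t|)\right], \qquad g(\rho) = \rho\,\psi(\rho),}
#' the standard substitution `v = r p` turning the radial 3D wave equation
#' into the 1D one with odd extension.  The trace vanishes whenever the
#' integration sphere of radius `t` around the sensor misses the support
#' ball (`t < d - R` or `t > d + R`).
#'
#' This "pseudo-3D" trace is what each column of the system matrix samples
#' on the sensor/time lattice.
#'
#' @param d Center-to-sensor distance(s), strictly positive.
#' @param t Time(s), non-negative.  `d` and `t` are recycled to a common
#'   length.
#' @param kb A [kb_params] object.
#' @return Numeric vector of pressure values; `kb_pressure(d, 0, kb)`
#'   equals `kb_profile(d, kb)`.
#' @export
#' @examples
#' kb <- kb_params(m = 2, gamma = 3, R = 0.05)
#' kb_pressure(0.8, c(0.7, 0.8, 0.9), kb)
kb_pressure <- function(d, t, kb) {
  stopifnot(inherits(kb, "kb_params"))
  n <- max(length(d), length(t))
  d <- rep_len(as.numeric(d), n)
  t <- rep_len(as.numeric(t), n)
  if (any(d < 1e-9)) {
    stop("kb_pressure requires positive sensor distance d", call. = FALSE)
  }
  if (any(t < 0)) stop("kb_pressure requires t >= 0", call. = FALSE)
  out <- numeric(n)
  # only points whose sphere intersects the support ball contribute
  act <- (abs(d - t) <= kb$R) | (d + t <= kb$R)
  if (any(act)) {
    da <- d[act]
    ta <- t[act]
    out[act] <- (kb_g(da + ta, kb) - sign(ta - da) * kb_g(abs(da - ta), kb)) /
      (2 * da)
  }
  out
}
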