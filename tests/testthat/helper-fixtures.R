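# shared fixtures and independent oracles used across the test files

# central finite-difference directional derivative of a scalar field
fd_directional <- function(f, x, v, h = 1e-6) {
  (f(x + h * v) - f(x - h * v)) / (2 * h)
}

# random dense operator with exact (untruncated) SVD factors
make_toy_op <- function(nr, nc, seed = 1, sigma_star = 0) {
  W <- withr::with_seed(seed, matrix(stats::rnorm(nr * nc), nr, nc))
  list(W = W, op = truncate_operator(W, sigma_star = sigma_star))
}

# small PAT operator shared by forward/solver tests; built once per run
small_pat <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      geo <- build_geometry(N = 16, Ns = 12, Nt = 16)
      sm <- assemble_system_matrix(geo$grid, geo$sensors)
      mv <- mask_indicator(geo$grid, mask_spec(0.34))
      cache <<- list(
        grid = geo$grid, sensors = geo$sensors, maskvec = mv,
        sm = sm, op = truncate_operator(sm, mv)
      )
    }
    cache
  }
})

# independent modified-Bessel-of-the-first-kind evaluation (power series),
# used as the special-function oracle
bessel_i_series <- function(x, m, terms = 60) {
  k <- 0:terms
  sum((x / 2)^(2 * k + m) / (factorial(k) * factorial(k + m)))
}

# spherical-mean quadrature + central finite difference in t: the
# independent oracle for the closed-form KB pressure trace
kb_pressure_oracle <- function(d, t, kb, h = 1e-5) {
  smean <- function(tt) {
    if (tt == 0) return(kb_profile(d, kb))
    f <- function(th) kb_profile(sqrt(d^2 + tt^2 - 2 * d * tt * cos(th)), kb) *
      sin(th) / 2
    stats::integrate(f, 0, pi, rel.tol = 1e-12, abs.tol = 1e-15)$value
  }
  tp <- t + h
  tm <- max(t - h, 0)
  (tp * smean(tp) - tm * smean(tm)) / (tp - tm)
}

# a U-Net with a non-trivial correction branch (fresh ones are exactly the
# identity because the final layer starts at zero)
nontrivial_unet <- function(N_unused = NULL, m = 1, base_channels = 4,
                            seed = 7) {
  net <- build_unet(network_spec(m = m, base_channels = base_channels),
    seed = seed
  )
  net$params$out$W[] <- withr::with_seed(
    seed + 1, stats::rnorm(length(net$params$out$W), sd = 0.3)
  )
  net$params$out$b <- 0.03
  net
}
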