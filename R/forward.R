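#' Assemble the PAT system matrix
#'
#' Builds the dense model matrix `W` of size `(Nt*Ns) x N^2` whose entry
#' in row `Nt*(k-1) + j`, column `N*(i1-1) + i2` is the pressure trace of
#' a Kaiser-Bessel blob at pixel center `c(i)`, sampled at sensor `s_k`
#' and time `t_j` (see [kb_pressure()]).  Rows are grouped sensor-major:
#' each sensor contributes a contiguous block of `Nt` time samples.
#'
#' The matrix is dense by design: the downstream pipeline factorizes
#' `W M_I` by SVD and reuses the factors, so sparse or matrix-free storage
#' would buy nothing.  A size cap refuses grids that would silently
#' exhaust memory.
#'
#' @param grid A [grid_spec].
#' @param sensors A [sensor_geometry].
#' @param kb A [kb_params]; defaults to `m = 2`, `gamma = 3`,
#'   `R = 2 * grid$spacing` when `NULL`.
#' @param max_N Largest grid size assembled without an explicit override
#'   (default 192).
#' @return An object of class `system_matrix` with fields `W`, `grid`,
#'   `sensors`, `kb`.
#' @export
#' @examples
#' geo <- build_geometry(N = 8, Ns = 6, Nt = 10)
#' sm <- assemble_system_matrix(geo$grid, geo$sensors)
#' dim(sm$W)
assemble_system_matrix <- function(grid, sensors, kb = NULL, max_N = 192) {
  stopifnot(inherits(grid, "grid_spec"), inherits(sensors, "sensor_geometry"))
  if (grid$N > max_N) {
    stop(
      "grid N = ", grid$N, " exceeds the dense-assembly cap (", max_N,
      "); raise max_N explicitly if you have the memory",
      call. = FALSE
    )
  }
  if (is.null(kb)) kb <- kb_params(m = 2, gamma = 3, R = 2 * grid$spacing)
  Npix <- grid$N^2
  Nt <- sensors$Nt
  tv <- sensors$times
  W <- matrix(0, nrow = Nt * sensors$Ns, ncol = Npix)
  for (k in seq_len(sensors$Ns)) {
    dx <- sensors$locations[k, 1] - grid$centers[, 1]
    dy <- sensors$locations[k, 2] - grid$centers[, 2]
    dist <- sqrt(dx * dx + dy * dy)
    # Nt x Npix block for this sensor; traces live in |d - t| <= R
    dd <- rep(dist, each = Nt)
    tt <- rep(tv, times = Npix)
    act <- which(abs(dd - tt) <= kb$R | dd + tt <= kb$R)
    blk <- numeric(Nt * Npix)
    if (length(act)) blk[act] <- kb_pressure(dd[act], tt[act], kb)
    W[(k - 1L) * Nt + seq_len(Nt), ] <- matrix(blk, nrow = Nt)
  }
  structure(
    list(W = W, grid = grid, sensors = sensors, kb = kb),
    class = "system_matrix"
  )
}

#' Truncated-SVD forward operator and pseudoinverse
#'
#' Forms the masked matrix `W M_I` (columns of masked pixels zeroed),
#' computes its singular value decomposition `U S V^T`, and zeroes all
#' singular values `<= sigma_star`.  The result packages the stabilized
#' forward map `A = U S* V^T` and its Moore-Penrose pseudoinverse
#' `A+ = V S*^+ U^T` in factored form, so products with `A`, `A^T`, `A+`
#' and the solver's reused inverse all cost two thin matrix-vector
#' multiplications.
#'
#' Truncation removes the near-null space the mask creates; without it the
#' pseudoinverse amplifies noise without bound.
#'
#' @param sm A `system_matrix` from [assemble_system_matrix()], or a plain
#'   numeric matrix (useful for toy problems and tests).
#' @param maskvec 0/1 vector from [mask_indicator()], or `NULL` for no
#'   masking.
#' @param sigma_star Truncation threshold.  Interpreted relative to the
#'   largest singular value when `relative = TRUE` (default
#'   `sigma_star = 1e-3`, i.e. `1e-3 * sigma_max`); absolute otherwise.
#' @param relative Whether `sigma_star` is relative to `sigma_max`.
#' @return An object of class `truncated_operator` with factors `U`, `d`
#'   (retained singular values, non-increasing), `V`, the threshold
#'   actually applied (`sigma_star`), the retained `rank`, all singular
#'   values of `W M_I` (`sv_full`), `maskvec`, and the originating
#'   geometry when available.
#' @export
truncate_operator <- function(sm, maskvec = NULL, sigma_star = 1e-3,
                              relative = TRUE) {
  W <- if (inherits(sm, "system_matrix")) sm$W else as.matrix(sm)
  stopifnot(is.numeric(sigma_star), sigma_star >= 0)
  n_coef <- ncol(W)
  if (is.null(maskvec)) maskvec <- rep(1, n_coef)
  if (length(maskvec) != n_coef) {
    stop("maskvec must have one entry per matrix column", call. = FALSE)
  }
  Wm <- sweep(W, 2L, maskvec, `*`)
  s <- tryCatch(
    La.svd(Wm),
    error = function(e) {
      stop("SVD of the masked system matrix failed: ", conditionMessage(e),
        call. = FALSE
      )
    }
  )
  thr <- if (relative) sigma_star * max(s$d, 0) else sigma_star
  keep <- which(s$d > thr)
  structure(
    list(
      U = s$u[, keep, drop = FALSE],
      d = s$d[keep],
      V = t(s$vt)[, keep, drop = FALSE],
      sigma_star = thr,
      rank = length(keep),
      sv_full = s$d,
      maskvec = maskvec,
      n_data = nrow(W),
      n_coef = n_coef,
      grid = if (inherits(sm, "system_matrix")) sm$grid else NULL,
      sensors = if (inherits(sm, "system_matrix")) sm$sensors else NULL,
      kb = if (inherits(sm, "system_matrix")) sm$kb else NULL
    ),
    class = "truncated_operator"
  )
}

#' @export
print.truncated_operator <- function(x, ...) {
  cat(
    "<truncated_operator> ", x$n_data, " x ", x$n_coef,
    ", rank ", x$rank, " (sigma* = ", format(x$sigma_star, digits = 4), ")\n",
    sep = ""
  )
  invisible(x)
}

check_conform <- function(x, len, what) {
  if (!is.numeric(x) || length(x) != len) {
    stop(what, " must be a numeric vector of length ", len, call. = FALSE)
  }
}

#' Apply the truncated operator and its companions
#'
#' Factored matrix-vector products with the stabilized forward map `A`,
#' its transpose, and the pseudoinverse `A+`.  All are linear and cost two
#' thin products with the stored SVD factors.
#'
#' @param op A `truncated_operator`.
#' @param x Coefficient vector of length `N^2`.
#' @param y Data vector of length `Nt*Ns`.
#' @return Numeric vector: `forward_apply()` returns data (`A x`),
#'   `adjoint_apply()` coefficients (`A^T y`), `pinv_apply()` coefficients
#'   (`A+ y`).
#' @export
#' @examples
#' op <- truncate_operator(matrix(rnorm(20 * 12), 20, 12), sigma_star = 0)
#' y <- forward_apply(op, rnorm(12))
forward_apply <- function(op, x) {
  stopifnot(inherits(op, "truncated_operator"))
  check_conform(x, op$n_coef, "x")
  drop(op$U %*% (op$d * crossprod(op$V, x)))
}

#' @rdname forward_apply
#' @export
adjoint_apply <- function(op, y) {
  stopifnot(inherits(op, "truncated_operator"))
  check_conform(y, op$n_data, "y")
  drop(op$V %*% (op$d * crossprod(op$U, y)))
}

#' @rdname forward_apply
#' @export
pinv_apply <- function(op, y) {
  stopifnot(inherits(op, "truncated_operator"))
  check_conform(y, op$n_data, "y")
  drop(op$V %*% (crossprod(op$U, y) / op$d))
}

#' Dense realization of the truncated operator
#'
#' Materializes `A` (or `A+`) as a dense matrix.  Intended for small
#' problems and verification; the pipeline itself always works with the
#' factors.
#'
#' @param op A `truncated_operator`.
#' @param what `"A"` or `"pinv"`.
#' @return A dense matrix.
#' @export
as_dense <- function(op, what = c("A", "pinv")) {
  stopifnot(inherits(op, "truncated_operator"))
  what <- match.arg(what)
  if (what == "A") {
    op$U %*% (op$d * t(op$V))
  } else {
    op$V %*% (t(op$U) / op$d)
  }
}

#' Simulate noisy measurement data
#'
#' Returns `A x + eta` where `eta` is i.i.d. zero-mean Gaussian noise with
#' standard deviation `sigma * max(|A x|)` — noise scaled to the peak
#' amplitude of the clean data, the convention used for the training and
#' test corpora (`sigma = 0.01` is "low", `0.1` "high" noise).
#'
#' @param op A `truncated_operator`.
#' @param x Coefficient vector.
#' @param sigma Relative noise level (>= 0); `0` returns `A x` exactly.
#' @param seed Integer seed; the draw is reproducible and leaves the
#'   global RNG state untouched.
#' @return Data vector of length `Nt*Ns`.
#' @export
simulate_noisy_data <- function(op, x, sigma, seed) {
  stopifnot(sigma >= 0)
  y0 <- forward_apply(op, x)
  if (sigma == 0) return(y0)
  sd <- sigma * max(abs(y0))
  eta <- withr::with_seed(as.integer(seed), stats::rnorm(length(y0), 0, sd))
  y0 + eta
}
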