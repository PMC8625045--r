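#' Solver configuration for the NETT functional
#'
#' Parameters of the forward-backward minimization of
#' `T(x) = ||A x - y||^2 / 2 + alpha * R(x)`.  Defaults follow the
#' package's standard reconstruction setup: 15 iterations with constant step size
#' 0.25 and a network-filtered pseudoinverse start.
#'
#' @param alpha Regularization weight (>= 0).  [default_alpha()] gives the
#'   per-noise-level values used by the study.
#' @param s Step size (> 0).
#' @param Niter Iteration count (>= 0; 0 returns the start unchanged).
#' @param init Start iterate: `"network-pinv"` (`Phi(A+ y)`, default),
#'   `"network-adjoint"` (`Phi(A^T y)`), `"pinv"` (`A+ y`) or `"zero"`.
#' @param reuse_inverse Realize the per-iteration linear solve through the
#'   operator's SVD factors, computed once and reused (default).  With
#'   `FALSE` a dense system is solved afresh every iteration — same
#'   result, used for verification.
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(alpha, s = 0.25, Niter = 15,
                          init = c("network-pinv", "network-adjoint", "pinv", "zero"),
                          reuse_inverse = TRUE) {
  stopifnot(alpha >= 0, s > 0, Niter >= 0, Niter == round(Niter))
  init <- match.arg(init)
  structure(
    list(
      alpha = alpha, s = s, Niter = as.integer(Niter), init = init,
      reuse_inverse = isTRUE(reuse_inverse)
    ),
    class = "solver_config"
  )
}

#' Regularization weight by noise level
#'
#' The per-noise-level defaults used by the reconstruction study:
#' `alpha = 0.015` for noise-free data, `0.016` for low noise
#' (`sigma = 0.01`) and `0.02` for high noise (`sigma = 0.1`); other
#' levels interpolate linearly in `sigma` between the bracketing values.
#'
#' @param sigma Relative noise level (>= 0).
#' @return Numeric `alpha`.
#' @export
default_alpha <- function(sigma) {
  stopifnot(all(sigma >= 0))
  vapply(sigma, function(s) {
    stats::approx(
      x = c(0, 0.01, 0.1), y = c(0.015, 0.016, 0.02),
      xout = min(s, 0.1), rule = 2
    )$y
  }, numeric(1))
}

#' NETT objective value
#'
#' `T(x) = ||A x - y||^2 / 2 + alpha * R(x)`: half squared data residual
#' plus the weighted learned regularizer.
#'
#' @param op A `truncated_operator`.
#' @param reg A [learned_regularizer()].
#' @param x Coefficient vector.
#' @param y Data vector.
#' @param alpha Regularization weight.
#' @return Scalar objective value.
#' @export
nett_objective <- function(op, reg, x, y, alpha) {
  r <- forward_apply(op, x) - y
  0.5 * sum(r * r) + alpha * regularizer_value(reg, x)
}

#' Minimize the NETT functional by forward-backward splitting
#'
#' Iterates
#' \deqn{x_{k+1} = (s A^T A + I)^{-1}\,(s A^T y + x_k -
#'   s\,\alpha\,R'(x_k)),}
#' an implicit (proximal) step on the quadratic data term combined with an
#' explicit gradient step on the regularizer, at constant step size `s`.
#' Because the step size is constant the linear solve is the same in every
#' iteration; by default it is realized through the operator's stored SVD
#' factors — set up once, each iteration then costs two thin
#' matrix-vector products plus one network gradient.
#'
#' The objective is recorded at the start and after every iteration
#' (trace length `Niter + 1`).
#'
#' @inheritParams nett_objective
#' @param cfg A [solver_config()].
#' @return An object of class `recon_result`: fields `x` (final iterate),
#'   `trace` (tibble with `iter`, `objective`, `fidelity`,
#'   `regularizer`), `fidelity`, `regularizer` (final values) and
#'   `config`.
#' @export
forward_backward_solve <- function(op, reg, y, cfg) {
  stopifnot(
    inherits(op, "truncated_operator"),
    inherits(reg, "learned_regularizer"),
    inherits(cfg, "solver_config")
  )
  check_conform(y, op$n_data, "y")
  x <- switch(cfg$init,
    "network-pinv" = as.numeric(network_apply(reg$phi, pinv_apply(op, y))),
    "network-adjoint" = as.numeric(network_apply(reg$phi, adjoint_apply(op, y))),
    "pinv" = pinv_apply(op, y),
    "zero" = numeric(op$n_coef)
  )
  s <- cfg$s
  alpha <- cfg$alpha
  if (cfg$reuse_inverse) {
    shrink <- 1 / (s * op$d^2 + 1) - 1
    apply_inv <- function(z) z + drop(op$V %*% (shrink * crossprod(op$V, z)))
  } else {
    AtA <- op$V %*% (op$d^2 * t(op$V))
    M <- s * AtA + diag(op$n_coef)
    apply_inv <- function(z) drop(solve(M, z))
  }
  s_Aty <- s * adjoint_apply(op, y)

  objective <- fidelity <- regterm <- numeric(cfg$Niter + 1L)
  record <- function(slot, x, re_val) {
    r <- forward_apply(op, x) - y
    fidelity[slot] <<- 0.5 * sum(r * r)
    regterm[slot] <<- re_val
    objective[slot] <<- fidelity[slot] + alpha * re_val
  }
  re <- regularizer_eval(reg, x)
  record(1L, x, re$value)
  for (k in seq_len(cfg$Niter)) {
    x <- apply_inv(s_Aty + x - s * alpha * re$gradient)
    if (!all(is.finite(x))) {
      stop("forward-backward iteration diverged at iteration ", k,
        call. = FALSE
      )
    }
    re <- regularizer_eval(reg, x)
    record(k + 1L, x, re$value)
  }
  structure(
    list(
      x = x,
      trace = tibble::tibble(
        iter = 0:cfg$Niter, objective = objective,
        fidelity = fidelity, regularizer = regterm
      ),
      fidelity = fidelity[cfg$Niter + 1L],
      regularizer = regterm[cfg$Niter + 1L],
      config = cfg
    ),
    class = "recon_result"
  )
}

#' @export
print.recon_result <- function(x, ...) {
  cat(
    "<recon_result> ", length(x$x), " coefficients, ",
    nrow(x$trace) - 1L, " iterations, final objective ",
    format(x$trace$objective[nrow(x$trace)], digits = 6), "\n",
    sep = ""
  )
  invisible(x)
}

#' Post-processing baseline reconstruction
#'
#' Applies the trained network once to the basic pseudoinverse
#' reconstruction: `Phi(A+ y)`.  This is the standard deep-learning
#' baseline NETT is compared against; unlike NETT it enforces no data
#' consistency.
#'
#' @inheritParams nett_objective
#' @return Coefficient vector.
#' @export
post_process <- function(op, reg, y) {
  stopifnot(inherits(reg, "learned_regularizer"))
  image_to_coef(coef_to_image(
    network_apply(reg$phi, coef_to_image(pinv_apply(op, y)))
  ))
}

#' Absolute Bregman distance
#'
#' \deqn{B_R(x, x^\star) = |R(x) - R(x^\star) -
#'   \langle R'(x^\star), x - x^\star\rangle|,}
#' the error measure under which convergence rates hold for possibly
#' non-convex regularizers (the absolute value keeps it non-negative
#' without convexity).  For `R(x) = ||x||^2` it reduces to
#' `||x - x*||^2` exactly.
#'
#' @param R_value Function returning `R(x)` for a coefficient vector.
#' @param R_grad Function returning the gradient of `R`.
#' @param x,x_star Coefficient vectors; `R` must be differentiable at
#'   `x_star`.
#' @return Non-negative scalar.
#' @export
#' @examples
#' bregman_distance(function(v) sum(v^2), function(v) 2 * v,
#'   x = c(1, 2), x_star = c(0, 0)
#' ) # == 5
bregman_distance <- function(R_value, R_grad, x, x_star) {
  abs(R_value(x) - R_value(x_star) - sum(R_grad(x_star) * (x - x_star)))
}
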