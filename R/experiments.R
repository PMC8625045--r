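#' Mean squared error
#'
#' @param x,x_ref Numeric vectors or matrices of equal shape.
#' @return Mean of squared entrywise differences.
#' @export
mse <- function(x, x_ref) {
  if (length(x) != length(x_ref)) {
    stop("mse: inputs must have equal shape", call. = FALSE)
  }
  mean((as.numeric(x) - as.numeric(x_ref))^2)
}

#' Reconstruction study: pseudoinverse vs post-processing vs NETT
#'
#' For every phantom and noise level, simulates data, reconstructs with
#' (i) the plain truncated pseudoinverse `A+ y`, (ii) the post-processing
#' network `Phi(A+ y)` for each supplied regularizer, and (iii) NETT via
#' [forward_backward_solve()] for each regularizer, and records the MSE
#' against the true phantom.  Everything is seeded; the per-measurement
#' seeds derive deterministically from `seed`.
#'
#' @param op A `truncated_operator`.
#' @param regs Named list of [learned_regularizer()] objects (names label
#'   the methods, e.g. `list(R1 = reg)` yields methods `post_R1`,
#'   `nett_R1`).
#' @param phantoms `N^2 x P` matrix of true phantoms (columns) or a
#'   single coefficient vector.
#' @param noise_levels Relative noise levels to test (default the study
#'   design `c(0, 0.01, 0.1)`).
#' @param alpha Function mapping a noise level to the NETT weight
#'   (default [default_alpha()]), or a numeric vector matching
#'   `noise_levels`.
#' @param s,Niter,init Solver settings (see [solver_config()]).
#' @param seed Master seed.
#' @return An object of class `study_report`: list with `table` (tibble:
#'   `phantom`, `sigma`, `method`, `mse`), `seed` and the solver
#'   settings.  `glance()` aggregates means; `autoplot()` draws the
#'   MSE-vs-noise curves.
#' @export
reconstruction_study <- function(op, regs, phantoms,
                                 noise_levels = c(0, 0.01, 0.1),
                                 alpha = default_alpha,
                                 s = 0.25, Niter = 15,
                                 init = "network-pinv", seed = 1) {
  stopifnot(inherits(op, "truncated_operator"), length(noise_levels) >= 1)
  if (!is.matrix(phantoms)) phantoms <- matrix(phantoms, ncol = 1)
  if (ncol(phantoms) < 1) stop("need at least one phantom", call. = FALSE)
  if (is.function(alpha)) {
    alphas <- vapply(noise_levels, alpha, numeric(1))
  } else {
    stopifnot(length(alpha) == length(noise_levels))
    alphas <- alpha
  }
  if (is.null(names(regs)) && length(regs) > 0) {
    names(regs) <- paste0("R", seq_along(regs))
  }
  rows <- list()
  for (pidx in seq_len(ncol(phantoms))) {
    xt <- phantoms[, pidx]
    for (nidx in seq_along(noise_levels)) {
      sig <- noise_levels[nidx]
      y <- simulate_noisy_data(
        op, xt, sig,
        seed = seed + 1009L * pidx + 97L * nidx
      )
      xr <- pinv_apply(op, y)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        phantom = pidx, sigma = sig, method = "pinv", mse = mse(xr, xt)
      )
      for (rn in names(regs)) {
        xp <- post_process(op, regs[[rn]], y)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          phantom = pidx, sigma = sig, method = paste0("post_", rn),
          mse = mse(xp, xt)
        )
        cfg <- solver_config(
          alpha = alphas[nidx], s = s, Niter = Niter, init = init
        )
        xn <- forward_backward_solve(op, regs[[rn]], y, cfg)$x
        rows[[length(rows) + 1L]] <- tibble::tibble(
          phantom = pidx, sigma = sig, method = paste0("nett_", rn),
          mse = mse(xn, xt)
        )
      }
    }
  }
  structure(
    list(
      table = dplyr::bind_rows(rows),
      seed = as.integer(seed),
      settings = list(
        noise_levels = noise_levels, alphas = alphas, s = s,
        Niter = Niter, init = init
      )
    ),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report> ", nrow(x$table), " reconstructions\n", sep = "")
  print(glance(x))
  invisible(x)
}

#' Toy-problem configuration for convergence-rate measurement
#'
#' Defines the controlled inverse problem on which Bregman-distance
#' convergence rates are measured: a diagonal operator with decaying
#' spectrum, a quadratic regularizer `R(x) = ||x||^2` (so the Tikhonov
#' minimizer is in closed form and Bregman values are solver-error-free),
#' a strictly decreasing noise-norm schedule `eps`, and the parameter
#' rule `alpha = alpha_scale * eps` — the optimal choice in the quadratic
#' case, where theory predicts `B_R(x_alpha, x+) = O(eps)` (log-log slope
#' 1 against the noise norm).
#'
#' The true solution either satisfies the source condition
#' `R'(x+) = A^T eta` (`solution = "source"`: `x+` is drawn in the range
#' of `A^T`) or deliberately violates it (`solution = "flat"`: equal mass
#' on all modes, including those with tiny singular values), which
#' degrades the measured rate.
#'
#' `n_modes`, when given, additionally truncates the operator used for
#' reconstruction at stage `k` to its first `n_modes[k]` spectral modes —
#' the discretization dimension growing along the noise schedule.  The
#' combined schedule must drive `(delta_k + discrepancy_k) / alpha_k`
#' to zero (checked before running; `delta = eps^2` since the data
#' discrepancy is a squared norm).
#'
#' @param singular_values Decreasing positive spectrum of the toy
#'   operator (needs >= 3 distinct values).  The default is geometric
#'   (severely ill-conditioned): for the measured slope to match the
#'   classical rate over several noise decades, the spectrum must
#'   realize the critical amplification `~ alpha^(-1/2)` at every noise
#'   level in the schedule, which a geometric spectrum does and
#'   slowly-decaying power-law spectra at small mode counts do not.
#' @param eps Strictly decreasing positive noise norms.
#' @param alpha_scale Proportionality constant of the rule
#'   `alpha = alpha_scale * eps`, or a function `eps -> alpha`.
#' @param n_rep Noise replications per `eps`.
#' @param solution `"source"` or `"flat"`.
#' @param n_modes Optional non-decreasing integer schedule of retained
#'   modes, one per `eps`.
#' @param seed Master seed.
#' @return An object of class `rates_config`.
#' @export
rates_config <- function(singular_values = 0.6^(0:29),
                         eps = 10^seq(-1, -4),
                         alpha_scale = 1,
                         n_rep = 20,
                         solution = c("source", "flat"),
                         n_modes = NULL,
                         seed = 1) {
  solution <- match.arg(solution)
  stopifnot(
    all(singular_values > 0), length(unique(singular_values)) >= 3,
    all(diff(singular_values) <= 0),
    all(eps > 0), all(diff(eps) < 0),
    n_rep >= 1
  )
  if (!is.null(n_modes)) {
    stopifnot(
      length(n_modes) == length(eps), all(diff(n_modes) >= 0),
      all(n_modes >= 1), all(n_modes <= length(singular_values))
    )
  }
  structure(
    list(
      singular_values = singular_values, eps = eps,
      alpha_scale = alpha_scale, n_rep = as.integer(n_rep),
      solution = solution, n_modes = n_modes, seed = as.integer(seed)
    ),
    class = "rates_config"
  )
}

rates_alpha <- function(cfg) {
  if (is.function(cfg$alpha_scale)) {
    vapply(cfg$eps, cfg$alpha_scale, numeric(1))
  } else {
    cfg$alpha_scale * cfg$eps
  }
}

# the joint (noise, regularization, discretization) schedule must satisfy
# alpha -> 0 and (delta + discrepancy)/alpha -> 0; err out before running
check_rate_schedule <- function(cfg) {
  alph <- rates_alpha(cfg)
  if (any(!is.finite(alph)) || any(alph <= 0)) {
    stop("rate schedule invalid: alpha must be positive and finite",
      call. = FALSE
    )
  }
  if (length(alph) > 1 && !all(diff(alph) < 0)) {
    stop("rate schedule invalid: alpha must decrease to 0 along the schedule",
      call. = FALSE
    )
  }
  sv <- cfg$singular_values
  xplus <- rates_solution(cfg)
  gam <- if (is.null(cfg$n_modes)) {
    rep(0, length(cfg$eps))
  } else {
    # discrepancy of the projected solution through the truncated operator
    vapply(cfg$n_modes, function(nk) {
      keep <- seq_len(nk)
      sum((sv[-keep] * xplus[-keep])^2)
    }, numeric(1))
  }
  v <- (cfg$eps^2 + gam) / alph
  if (v[length(v)] > v[1] + 1e-12) {
    stop(
      "rate schedule invalid: (delta + discrepancy)/alpha does not decrease",
      call. = FALSE
    )
  }
  invisible(list(alpha = alph, v = v))
}

# true solution of the toy problem (unit norm)
rates_solution <- function(cfg) {
  sv <- cfg$singular_values
  xp <- withr::with_seed(cfg$seed, {
    if (cfg$solution == "source") {
      sv * stats::rnorm(length(sv)) # x+ = A^T eta, source condition holds
    } else {
      rep(1, length(sv)) # equal mass on all modes: source condition fails
    }
  })
  xp / sqrt(sum(xp^2))
}

#' Measure Bregman-distance convergence rates on the toy problem
#'
#' Runs the schedule defined by a [rates_config()]: for every noise norm
#' `eps_k` and replication, draws noise of exact norm `eps_k`, sets
#' `alpha_k` by the parameter rule, computes the exact Tikhonov minimizer
#' `(A^T A + 2 alpha I)^{-1} A^T y` of the quadratic-regularizer
#' functional in closed form, and evaluates the absolute Bregman distance
#' `B_R(x_alpha, x+)` via [bregman_distance()].  The log-log slope of
#' `B` against `eps` is fitted by least squares over all replications.
#'
#' The schedule is validated before any computation (see
#' [rates_config()]); an inadmissible schedule is a configuration error.
#'
#' @param cfg A [rates_config()].
#' @return An object of class `rates_result`: list with `table` (tibble:
#'   `eps`, `rep`, `alpha`, `bregman`), `slope`, `intercept`, `config`.
#' @export
#' @examples
#' r <- rates_experiment(rates_config(n_rep = 3))
#' r$slope
rates_experiment <- function(cfg = rates_config()) {
  stopifnot(inherits(cfg, "rates_config"))
  sched <- check_rate_schedule(cfg)
  sv <- cfg$singular_values
  n <- length(sv)
  xplus <- rates_solution(cfg)
  y0 <- sv * xplus
  R_value <- function(v) sum(v^2)
  R_grad <- function(v) 2 * v
  rows <- vector("list", length(cfg$eps) * cfg$n_rep)
  idx <- 0L
  for (k in seq_along(cfg$eps)) {
    epsk <- cfg$eps[k]
    alphak <- sched$alpha[k]
    keep <- if (is.null(cfg$n_modes)) seq_len(n) else seq_len(cfg$n_modes[k])
    for (r in seq_len(cfg$n_rep)) {
      e <- withr::with_seed(
        cfg$seed + 131L * k + 7919L * r,
        stats::rnorm(n)
      )
      e <- e * (epsk / sqrt(sum(e^2)))
      y <- y0 + e
      # closed-form Tikhonov minimizer on the retained modes
      xa <- numeric(n)
      xa[keep] <- sv[keep] * y[keep] / (sv[keep]^2 + 2 * alphak)
      idx <- idx + 1L
      rows[[idx]] <- tibble::tibble(
        eps = epsk, rep = r, alpha = alphak,
        bregman = bregman_distance(R_value, R_grad, xa, xplus)
      )
    }
  }
  tab <- dplyr::bind_rows(rows)
  fit <- stats::lm(log(bregman) ~ log(eps), data = tab)
  structure(
    list(
      table = tab,
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      r_squared = summary(fit)$r.squared,
      config = cfg
    ),
    class = "rates_result"
  )
}

#' @export
print.rates_result <- function(x, ...) {
  cat(
    "<rates_result> fitted log-log slope ", format(x$slope, digits = 4),
    " over eps in [", format(min(x$config$eps)), ", ",
    format(max(x$config$eps)), "]\n",
    sep = ""
  )
  invisible(x)
}
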