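test_that("the NETT objective matches a hand-coded evaluation", {
  t0 <- make_toy_op(10, 6, seed = 12)
  x <- withr::with_seed(13, stats::rnorm(6))
  y <- withr::with_seed(14, stats::rnorm(10))
  reg <- learned_regularizer(zero_network(), beta = 0)
  alpha <- 0.3
  direct <- 0.5 * sum((t0$W %*% x - y)^2) + alpha * sum(x^2)
  expect_equal(nett_objective(t0$op, reg, x, y, alpha), direct,
    tolerance = 1e-12
  )
  # alpha = 0: pure half squared residual
  expect_equal(
    nett_objective(t0$op, reg, x, y, 0),
    0.5 * sum((t0$W %*% x - y)^2),
    tolerance = 1e-12
  )
  # consistent data and a vanishing regularizer give 0
  reg_id <- learned_regularizer(identity_network(), beta = 0)
  yc <- forward_apply(t0$op, x)
  expect_equal(nett_objective(t0$op, reg_id, x, yc, 1), 0, tolerance = 1e-20)
})

test_that("convex quadratic case converges to the closed-form minimizer", {
  t0 <- make_toy_op(12, 8, seed = 15)
  y <- withr::with_seed(16, stats::rnorm(12))
  alpha <- 0.2
  reg <- learned_regularizer(zero_network(), beta = 0)
  res <- forward_backward_solve(
    t0$op, reg, y, solver_config(alpha, s = 0.25, Niter = 2000, init = "zero")
  )
  closed <- solve(crossprod(t0$W) + 2 * alpha * diag(8), crossprod(t0$W, y))
  expect_lt(
    sqrt(sum((res$x - closed)^2)) / sqrt(sum(closed^2)), 1e-6
  )
  # objective trace is monotone for the convex problem at this step size
  expect_true(all(diff(res$trace$objective) <= 1e-10))
  expect_equal(nrow(res$trace), 2001L)
})

test_that("without regularization the solver recovers the pseudoinverse solution", {
  t0 <- make_toy_op(30, 16, seed = 17)
  y <- withr::with_seed(18, stats::rnorm(30))
  reg <- learned_regularizer(zero_network(), beta = 0)
  res <- forward_backward_solve(
    t0$op, reg, y, solver_config(alpha = 0, s = 0.25, Niter = 200, init = "pinv")
  )
  ref <- pinv_apply(t0$op, y)
  expect_lt(sqrt(sum((res$x - ref)^2)) / sqrt(sum(ref^2)), 1e-6)
})

test_that("zero iterations return the start iterate unchanged", {
  t0 <- make_toy_op(12, 9, seed = 19)
  y <- withr::with_seed(20, stats::rnorm(12))
  reg <- learned_regularizer(zero_network(), beta = 0)
  res <- forward_backward_solve(
    t0$op, reg, y, solver_config(alpha = 1, s = 0.25, Niter = 0, init = "pinv")
  )
  expect_equal(res$x, pinv_apply(t0$op, y))
  expect_equal(nrow(res$trace), 1L)
})

test_that("a converged iterate is a fixed point", {
  t0 <- make_toy_op(12, 8, seed = 21)
  y <- withr::with_seed(22, stats::rnorm(12))
  alpha <- 0.15
  reg <- learned_regularizer(zero_network(), beta = 0)
  res <- forward_backward_solve(
    t0$op, reg, y, solver_config(alpha, s = 0.25, Niter = 3000, init = "zero")
  )
  # one more iteration from the converged point barely moves it
  one <- forward_backward_solve(
    t0$op, reg, y, solver_config(alpha, s = 0.25, Niter = 1, init = "zero")
  )
  # rebuild manually: start the single iteration at the converged x
  shrink <- 1 / (0.25 * t0$op$d^2 + 1) - 1
  z <- 0.25 * adjoint_apply(t0$op, y) + res$x -
    0.25 * alpha * regularizer_gradient(reg, res$x)
  xnext <- z + drop(t0$op$V %*% (shrink * crossprod(t0$op$V, z)))
  expect_lt(sqrt(sum((xnext - res$x)^2)) / sqrt(sum(res$x^2)), 1e-8)
  expect_s3_class(one, "recon_result")
})

test_that("reused factorization and fresh solves give identical iterates", {
  t0 <- make_toy_op(14, 10, seed = 23)
  y <- withr::with_seed(24, stats::rnorm(14))
  reg <- learned_regularizer(zero_network(), beta = 0)
  cfg_a <- solver_config(alpha = 0.3, s = 0.25, Niter = 40, init = "zero")
  cfg_b <- solver_config(
    alpha = 0.3, s = 0.25, Niter = 40, init = "zero", reuse_inverse = FALSE
  )
  xa <- forward_backward_solve(t0$op, reg, y, cfg_a)$x
  xb <- forward_backward_solve(t0$op, reg, y, cfg_b)$x
  expect_lt(max(abs(xa - xb)), 1e-10)
})

test_that("the convex TV-regularized objective is minimized to optimizer accuracy", {
  # linear-network regularizer + smoothed TV: convex but not quadratic
  t0 <- make_toy_op(20, 16, seed = 25)
  L <- withr::with_seed(26, matrix(stats::rnorm(256, sd = 0.15), 16, 16))
  reg <- learned_regularizer(linear_network(L), beta = 0.5, eps = 1e-2)
  y <- withr::with_seed(27, stats::rnorm(20))
  cfg <- solver_config(alpha = 0.1, s = 0.25, Niter = 4000, init = "zero")
  res <- forward_backward_solve(t0$op, reg, y, cfg)
  obj <- function(x) nett_objective(t0$op, reg, x, y, 0.1)
  ref <- stats::optim(
    res$x, obj,
    gr = function(x) {
      drop(crossprod(as_dense(t0$op, "A"), forward_apply(t0$op, x) - y)) +
        0.1 * regularizer_gradient(reg, x)
    },
    method = "BFGS", control = list(maxit = 500, reltol = 1e-14)
  )
  expect_lt(obj(res$x) - ref$value, 1e-8)
})

test_that("divergent configurations raise an iteration-labelled error", {
  t0 <- make_toy_op(10, 6, seed = 28)
  y <- withr::with_seed(29, stats::rnorm(10))
  reg <- learned_regularizer(zero_network(), beta = 0)
  expect_error(
    forward_backward_solve(
      t0$op, reg, y, solver_config(alpha = 1e200, s = 0.25, Niter = 400, init = "pinv")
    ),
    "diverged at iteration"
  )
})

test_that("post-processing is the network applied to the basic reconstruction", {
  pat <- small_pat()
  x <- square_ring_phantom(pat$grid, ring_phantom_config(), seed = 30)
  y <- simulate_noisy_data(pat$op, x, 0.01, seed = 31)
  reg_id <- learned_regularizer(identity_network(), beta = 15)
  expect_equal(post_process(pat$op, reg_id, y), pinv_apply(pat$op, y))
  net <- nontrivial_unet(m = 1, base_channels = 2, seed = 32)
  reg <- learned_regularizer(net, beta = 15)
  expect_equal(
    post_process(pat$op, reg, y),
    image_to_coef(network_apply(net, coef_to_image(pinv_apply(pat$op, y))))
  )
})

test_that("absolute Bregman distance has its defining properties", {
  Rv <- function(v) sum(v^2)
  Rg <- function(v) 2 * v
  x <- withr::with_seed(33, stats::rnorm(10))
  xs <- withr::with_seed(34, stats::rnorm(10))
  expect_equal(bregman_distance(Rv, Rg, x, x), 0)
  # quadratic identity
  expect_equal(bregman_distance(Rv, Rg, x, xs), sum((x - xs)^2))
  # smoothed TV: direct evaluation with the finite-difference-checked gradient
  a <- withr::with_seed(35, stats::runif(64))
  b <- withr::with_seed(36, stats::runif(64))
  tv <- function(v) smoothed_tv(v, eps = 1e-2)
  tvg <- function(v) image_to_coef(smoothed_tv_grad(coef_to_image(v), eps = 1e-2))
  direct <- abs(tv(a) - tv(b) - sum(tvg(b) * (a - b)))
  expect_equal(bregman_distance(tv, tvg, a, b), direct)
  expect_gte(bregman_distance(tv, tvg, a, b), 0)
})
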