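test_that("a freshly built residual U-Net is the identity map", {
  # the final correction layer starts at zero, so Phi(x) = x exactly
  net <- build_unet(network_spec(m = 1, base_channels = 4), seed = 1)
  x <- withr::with_seed(2, matrix(stats::runif(16^2), 16, 16))
  expect_equal(network_apply(net, x), x)
})

test_that("network application is deterministic and shape-preserving", {
  for (m in 1:2) {
    net <- nontrivial_unet(m = m, base_channels = 4, seed = m)
    x <- withr::with_seed(3 + m, matrix(stats::runif(16^2), 16, 16))
    y1 <- network_apply(net, x)
    expect_equal(dim(y1), c(16L, 16L))
    expect_identical(network_apply(net, x), y1)
    expect_false(identical(y1, x))
  }
  net <- build_unet(network_spec(m = 3), seed = 1)
  expect_error(network_apply(net, matrix(0, 12, 12)), "divisible")
})

test_that("vector-Jacobian products match forward-mode finite differences", {
  for (m in 1:2) {
    net <- nontrivial_unet(m = m, base_channels = 4, seed = 10 + m)
    x <- withr::with_seed(20 + m, matrix(stats::rnorm(16^2), 16, 16))
    g <- withr::with_seed(30 + m, matrix(stats::rnorm(16^2), 16, 16))
    vjp <- network_vjp(net, x, g)
    for (k in 1:5) {
      v <- withr::with_seed(40 + 10 * m + k, matrix(stats::rnorm(16^2), 16, 16))
      fd <- fd_directional(function(z) sum(g * network_apply(net, z)), x, v)
      expect_equal(sum(vjp * v), fd, tolerance = 1e-5)
    }
  }
})

test_that("parameter flattening round-trips exactly", {
  net <- build_unet(network_spec(m = 2, base_channels = 4), seed = 5)
  v <- nettpat:::params_to_vec(net$params)
  back <- nettpat:::vec_to_params(v, net$params)
  expect_identical(back, net$params)
})

test_that("parameter gradients match finite differences", {
  net <- nontrivial_unet(m = 1, base_channels = 3, seed = 9)
  x <- withr::with_seed(61, matrix(stats::rnorm(64), 8, 8))
  g <- withr::with_seed(62, matrix(stats::rnorm(64), 8, 8))
  fw <- nettpat:::unet_forward(net, x, keep_cache = TRUE)
  bw <- nettpat:::unet_backward(net, fw$cache, g, want_params = TRUE)
  gp <- nettpat:::params_to_vec(bw$gparams)
  th <- nettpat:::params_to_vec(net$params)
  probes <- withr::with_seed(63, sample(length(th), 8))
  h <- 1e-5
  for (j in probes) {
    tp <- th
    tp[j] <- th[j] + h
    net$params <- nettpat:::vec_to_params(tp, net$params)
    f1 <- sum(g * nettpat:::unet_forward(net, x))
    tp[j] <- th[j] - h
    net$params <- nettpat:::vec_to_params(tp, net$params)
    f0 <- sum(g * nettpat:::unet_forward(net, x))
    net$params <- nettpat:::vec_to_params(th, net$params)
    expect_equal(gp[j], (f1 - f0) / (2 * h), tolerance = 1e-4)
  }
})

test_that("training reduces the loss on a small corpus", {
  pat <- small_pat()
  data <- generate_dataset(pat$grid, pat$op, n = 12, sigma = 0.01, seed = 7)
  reg <- train_regularizer(
    data,
    spec = network_spec(m = 1, base_channels = 4),
    cfg = train_config(epochs = 4, batch_size = 4, seed = 1)
  )
  hist <- attr(reg, "history")
  expect_equal(nrow(hist), 5L)
  expect_lt(min(hist$loss[-1]), hist$loss[1])
  expect_true(all(is.finite(hist$loss)))
  expect_s3_class(reg, "learned_regularizer")
})

test_that("epoch loss with gamma 0 is the mean artifact-term loss", {
  pat <- small_pat()
  data <- generate_dataset(pat$grid, pat$op, n = 3, sigma = 0.01, seed = 8)
  reg <- train_regularizer(
    data,
    spec = network_spec(m = 1, base_channels = 2),
    cfg = train_config(gamma = 0, epochs = 1, seed = 2)
  )
  hist <- attr(reg, "history")
  # epoch 0 evaluates the untrained network, which is the identity:
  # the first loss term is then mean_a ||h_a - x_a||_1 and the clean term
  # is absent
  expect_equal(
    hist$loss[1],
    mean(colSums(abs(data$h - data$x))),
    tolerance = 1e-10
  )
})

test_that("a single tiny-rate step does not increase the loss", {
  # the L1 loss must be differentiable at the identity initialization for
  # one-step descent: gamma = 0 (the clean term starts at its kinked
  # minimum) and an unmasked operator (masked pixels give exact zeros in
  # h - x, i.e. kinks at the starting point)
  geo <- build_geometry(N = 16, Ns = 12, Nt = 16)
  op <- truncate_operator(assemble_system_matrix(geo$grid, geo$sensors))
  data <- generate_dataset(geo$grid, op, n = 1, sigma = 0.01, seed = 9)
  worse <- 0
  for (s in 1:5) {
    reg <- train_regularizer(
      data,
      spec = network_spec(m = 1, base_channels = 2),
      cfg = train_config(
        learning_rate = 1e-6, gamma = 0, epochs = 1, batch_size = 1, seed = s
      )
    )
    hist <- attr(reg, "history")
    if (hist$loss[2] > hist$loss[1] * (1 + 1e-6)) worse <- worse + 1
  }
  expect_lte(worse, 1) # descent up to stochastic tolerance across seeds
})

test_that("training is reproducible for a fixed seed", {
  pat <- small_pat()
  data <- generate_dataset(pat$grid, pat$op, n = 4, sigma = 0.01, seed = 10)
  r1 <- train_regularizer(
    data,
    spec = network_spec(m = 1, base_channels = 2),
    cfg = train_config(epochs = 2, seed = 3)
  )
  r2 <- train_regularizer(
    data,
    spec = network_spec(m = 1, base_channels = 2),
    cfg = train_config(epochs = 2, seed = 3)
  )
  expect_identical(r1$phi$params, r2$phi$params)
  expect_identical(attr(r1, "history"), attr(r2, "history"))
})
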