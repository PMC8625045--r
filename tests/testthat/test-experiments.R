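test_that("mse matches a hand-coded loop", {
  x <- withr::with_seed(41, stats::rnorm(40))
  y <- withr::with_seed(42, stats::rnorm(40))
  expect_equal(mse(x, x), 0)
  expect_equal(mse(x + 0.3, x), 0.09, tolerance = 1e-12)
  acc <- 0
  for (i in seq_along(x)) acc <- acc + (x[i] - y[i])^2
  expect_equal(mse(x, y), acc / 40, tolerance = 1e-14)
  expect_error(mse(x, y[1:10]), "equal shape")
})

test_that("study table is complete and aggregates consistently", {
  pat <- small_pat()
  phs <- vapply(
    1:3,
    function(s) square_ring_phantom(pat$grid, ring_phantom_config(), seed = s),
    numeric(pat$op$n_coef)
  )
  reg <- learned_regularizer(nontrivial_unet(m = 1, base_channels = 2, seed = 2),
    beta = 15
  )
  rep <- reconstruction_study(
    pat$op, list(R1 = reg), phs,
    noise_levels = c(0, 0.01), Niter = 3, seed = 5
  )
  tab <- tidy(rep)
  # every phantom x noise x method cell is present exactly once
  expect_equal(nrow(tab), 3 * 2 * 3)
  expect_true(all(table(tab$phantom, tab$sigma, tab$method) == 1))
  expect_true(all(tab$mse >= 0))
  # report means equal recomputation from the stored per-item table
  g <- glance(rep)
  for (r in seq_len(nrow(g))) {
    sel <- tab$sigma == g$sigma[r] & tab$method == g$method[r]
    expect_equal(g$mean_mse[r], mean(tab$mse[sel]))
  }
})

test_that("NETT with identity network and alpha 0 degenerates to least squares", {
  pat <- small_pat()
  ph <- square_ring_phantom(pat$grid, ring_phantom_config(), seed = 9)
  reg_id <- learned_regularizer(identity_network(), beta = 0)
  rep <- reconstruction_study(
    pat$op, list(id = reg_id), ph,
    noise_levels = 0.01,
    alpha = 0, Niter = 50, init = "pinv", seed = 3
  )
  tab <- tidy(rep)
  m_pinv <- tab$mse[tab$method == "pinv"]
  m_nett <- tab$mse[tab$method == "nett_id"]
  expect_equal(m_nett, m_pinv, tolerance = 1e-6)
  # the post-processing column with an identity network IS the pseudoinverse
  expect_equal(tab$mse[tab$method == "post_id"], m_pinv, tolerance = 1e-12)
})

test_that("studies are reproducible from (config, seed)", {
  pat <- small_pat()
  ph <- square_ring_phantom(pat$grid, ring_phantom_config(), seed = 1)
  reg <- learned_regularizer(nontrivial_unet(m = 1, base_channels = 2, seed = 3),
    beta = 15
  )
  r1 <- reconstruction_study(pat$op, list(R1 = reg), ph,
    noise_levels = 0.01, Niter = 2, seed = 7
  )
  r2 <- reconstruction_study(pat$op, list(R1 = reg), ph,
    noise_levels = 0.01, Niter = 2, seed = 7
  )
  expect_identical(tidy(r1), tidy(r2))
})

test_that("default alphas follow the study design", {
  expect_equal(default_alpha(0), 0.015)
  expect_equal(default_alpha(0.01), 0.016)
  expect_equal(default_alpha(0.1), 0.02)
})

test_that("inadmissible rate schedules are rejected before running", {
  # alpha not decreasing to zero
  expect_error(
    rates_experiment(rates_config(alpha_scale = function(e) 0.5, n_rep = 1)),
    "alpha must decrease"
  )
  # discrepancy-to-alpha ratio increasing (alpha falls too fast)
  expect_error(
    rates_experiment(rates_config(alpha_scale = function(e) e^3, n_rep = 1)),
    "does not decrease"
  )
  # invalid eps schedules are caught at construction
  expect_error(rates_config(eps = c(0.1, 0.1)))
  expect_error(rates_config(eps = c(0.1, -0.01)))
})

test_that("exact data with vanishing regularization attains the true solution", {
  cfg <- rates_config(n_rep = 1, seed = 4)
  sv <- cfg$singular_values
  xp <- nettpat:::rates_solution(cfg)
  y0 <- sv * xp
  for (alpha in c(1e-8, 1e-12)) {
    xa <- sv * y0 / (sv^2 + 2 * alpha)
    B <- bregman_distance(function(v) sum(v^2), function(v) 2 * v, xa, xp)
    expect_lt(B, alpha * 1e3) # -> 0 as alpha -> 0 with exact data
  }
})

test_that("the quadratic-case Bregman rate is recovered under the source condition", {
  r <- rates_experiment(rates_config(n_rep = 5, seed = 11))
  expect_gt(r$slope, 0.75)
  expect_lt(r$slope, 1.25)
  expect_equal(nrow(tidy(r)), 4 * 5)
  # Bregman distance for the quadratic regularizer is the squared distance
  expect_true(all(tidy(r)$bregman >= 0))
})

test_that("violating the source condition degrades the measured rate", {
  rs <- rates_experiment(rates_config(n_rep = 5, seed = 11))
  rf <- rates_experiment(rates_config(n_rep = 5, seed = 11, solution = "flat"))
  expect_lt(rf$slope, rs$slope - 0.3)
})

test_that("a growing discretization schedule is accepted and measured", {
  cfg <- rates_config(
    n_rep = 3, seed = 13,
    n_modes = c(15, 20, 25, 30)
  )
  r <- rates_experiment(cfg)
  expect_true(is.finite(r$slope))
  expect_equal(nrow(tidy(r)), 12)
})

test_that("rate experiments are bit-reproducible", {
  r1 <- rates_experiment(rates_config(n_rep = 3, seed = 21))
  r2 <- rates_experiment(rates_config(n_rep = 3, seed = 21))
  expect_identical(tidy(r1), tidy(r2))
  expect_identical(r1$slope, r2$slope)
})
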