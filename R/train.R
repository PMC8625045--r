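#' Training configuration for the regularizer network
#'
#' Default training setup: Adam with learning rate
#' 0.01, clean-image term weight `gamma = 0.1`, minibatches of 8.
#'
#' @param learning_rate Adam step size (> 0).
#' @param gamma Weight of the clean-image loss term (>= 0).  The loss per
#'   pair is `||Phi(h_a) - x_a||_1 + gamma * ||Phi(x_a) - x_a||_1`: the
#'   network must map artifact reconstructions `h_a` back to the phantom
#'   and leave clean phantoms (almost) unchanged.
#' @param epochs Number of passes over the dataset.
#' @param batch_size Minibatch size.
#' @param seed Seed governing weight initialization and shuffling.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.01, gamma = 0.1, epochs = 50,
                         batch_size = 8, seed = 1) {
  stopifnot(learning_rate > 0, gamma >= 0, epochs >= 1, batch_size >= 1)
  structure(
    list(
      learning_rate = learning_rate, gamma = gamma,
      epochs = as.integer(epochs), batch_size = as.integer(batch_size),
      seed = as.integer(seed)
    ),
    class = "train_config"
  )
}

# mean training loss of the current parameters over the whole dataset
dataset_loss <- function(net, data, gamma, N) {
  tot <- 0
  for (a in seq_len(ncol(data$x))) {
    xi <- coef_to_image(data$x[, a], N)
    hi <- coef_to_image(data$h[, a], N)
    tot <- tot + sum(abs(unet_forward(net, hi) - xi))
    if (gamma > 0) tot <- tot + gamma * sum(abs(unet_forward(net, xi) - xi))
  }
  tot / ncol(data$x)
}

#' Train the learned regularizer network
#'
#' Minimizes the two-term L1 loss
#' `sum_a ||Phi(h_a) - x_a||_1 + gamma * ||Phi(x_a) - x_a||_1`
#' over minibatches with Adam.  Epoch losses are evaluated on the full
#' dataset after each epoch (epoch 0 = untrained network) and the
#' parameters with the lowest epoch loss are returned.  Fully seeded:
#' initialization, shuffling and hence the trained weights are
#' reproducible.
#'
#' @param data A `nett_dataset` from [generate_dataset()].
#' @param spec A [network_spec()].
#' @param cfg A [train_config()].
#' @param beta,eps Passed to [learned_regularizer()] for the returned
#'   object.
#' @param verbose Print per-epoch losses.
#' @return A [learned_regularizer()] whose `phi` is the trained
#'   `unet_network`; the training curve is attached as attribute
#'   `history` (tibble with `epoch`, `loss`).
#' @export
train_regularizer <- function(data, spec = network_spec(),
                              cfg = train_config(), beta = 15, eps = 0.25,
                              verbose = FALSE) {
  stopifnot(inherits(data, "nett_dataset"))
  n <- ncol(data$x)
  if (n < 1) stop("dataset is empty", call. = FALSE)
  N <- as.integer(round(sqrt(nrow(data$x))))
  net <- build_unet(spec, seed = cfg$seed)
  theta <- params_to_vec(net$params)
  # Adam state
  mom <- numeric(length(theta))
  vel <- numeric(length(theta))
  b1 <- 0.9
  b2 <- 0.999
  ae <- 1e-8
  step <- 0L

  losses <- numeric(cfg$epochs + 1L)
  losses[1L] <- dataset_loss(net, data, cfg$gamma, N)
  best_loss <- losses[1L]
  best_theta <- theta

  withr::with_seed(cfg$seed + 1L, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = cfg$batch_size)) {
        batch <- ord[start:min(start + cfg$batch_size - 1L, n)]
        gsum <- numeric(length(theta))
        for (a in batch) {
          xi <- coef_to_image(data$x[, a], N)
          hi <- coef_to_image(data$h[, a], N)
          fw <- unet_forward(net, hi, keep_cache = TRUE)
          bw <- unet_backward(net, fw$cache, sign(fw$y - xi))
          gsum <- gsum + params_to_vec(bw$gparams)
          if (cfg$gamma > 0) {
            fw2 <- unet_forward(net, xi, keep_cache = TRUE)
            bw2 <- unet_backward(net, fw2$cache, cfg$gamma * sign(fw2$y - xi))
            gsum <- gsum + params_to_vec(bw2$gparams)
          }
        }
        g <- gsum / length(batch)
        step <- step + 1L
        mom <- b1 * mom + (1 - b1) * g
        vel <- b2 * vel + (1 - b2) * g * g
        mhat <- mom / (1 - b1^step)
        vhat <- vel / (1 - b2^step)
        theta <- theta - cfg$learning_rate * mhat / (sqrt(vhat) + ae)
        net$params <- vec_to_params(theta, net$params)
      }
      losses[ep + 1L] <- dataset_loss(net, data, cfg$gamma, N)
      if (!is.finite(losses[ep + 1L])) {
        stop("training diverged: non-finite loss at epoch ", ep,
          call. = FALSE
        )
      }
      if (verbose) {
        message(sprintf("epoch %d: loss %.4f", ep, losses[ep + 1L]))
      }
      if (losses[ep + 1L] < best_loss) {
        best_loss <- losses[ep + 1L]
        best_theta <- theta
      }
    }
  })
  net$params <- vec_to_params(best_theta, net$params)
  reg <- learned_regularizer(net, beta = beta, eps = eps)
  attr(reg, "history") <- tibble::tibble(
    epoch = 0:cfg$epochs, loss = losses
  )
  reg
}
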