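# Minimal convolutional-network engine.
#
# Feature maps are (H*W) x C matrices in R's column-major pixel order.
# 3x3 convolutions are im2col gathers followed by one BLAS matmul; the
# backward passes are exact (no numerical differentiation anywhere), which
# gives both parameter gradients for training and the input-space
# vector-Jacobian products the regularizer gradient needs.

.idx_cache <- new.env(parent = emptyenv())

# 9-column neighbor index map for same-padded 3x3 convs, plus 2x2 pooling
# child maps; 0 marks out-of-bounds (zero padding)
conv_indices <- function(H, W) {
  key <- paste0(H, "x", W)
  if (!is.null(.idx_cache[[key]])) return(.idx_cache[[key]])
  ii <- rep(seq_len(H), times = W)
  jj <- rep(seq_len(W), each = H)
  offs <- expand.grid(di = -1:1, dj = -1:1)
  idx <- matrix(0L, H * W, 9L)
  for (k in seq_len(9)) {
    ni <- ii + offs$di[k]
    nj <- jj + offs$dj[k]
    ok <- ni >= 1 & ni <= H & nj >= 1 & nj <= W
    v <- integer(H * W)
    v[ok] <- ni[ok] + (nj[ok] - 1L) * H
    idx[, k] <- v
  }
  pool <- NULL
  if (H %% 2 == 0 && W %% 2 == 0) {
    h2 <- H %/% 2
    w2 <- W %/% 2
    a <- rep(seq_len(h2), times = w2)
    b <- rep(seq_len(w2), each = h2)
    child <- function(da, db) (2L * a - 1L + da) + (2L * b - 2L + db) * H
    pool <- list(child(0L, 0L), child(1L, 0L), child(0L, 1L), child(1L, 1L))
  }
  out <- list(idx = idx, pool = pool, H = H, W = W)
  .idx_cache[[key]] <- out
  out
}

conv3_fwd <- function(X, K, b, idx) {
  cin <- ncol(X)
  Xa <- rbind(0, X)
  Xcol <- matrix(0, nrow(X), 9L * cin)
  for (k in 1:9) {
    Xcol[, ((k - 1L) * cin + 1L):(k * cin)] <- Xa[idx[, k] + 1L, , drop = FALSE]
  }
  Y <- Xcol %*% K
  Y <- sweep(Y, 2L, b, `+`)
  list(Y = Y, Xcol = Xcol)
}

conv3_bwd <- function(dY, Xcol, K, idx, cin, want_params) {
  gW <- if (want_params) crossprod(Xcol, dY) else NULL
  gb <- if (want_params) colSums(dY) else NULL
  dXcol <- tcrossprod(dY, K)
  dXa <- matrix(0, nrow(dY) + 1L, cin)
  for (k in 1:9) {
    blk <- dXcol[, ((k - 1L) * cin + 1L):(k * cin), drop = FALSE]
    rows <- idx[, k] + 1L
    dXa[rows, ] <- dXa[rows, , drop = FALSE] + blk
  }
  list(dX = dXa[-1L, , drop = FALSE], gW = gW, gb = gb)
}

pool_fwd <- function(X, pool) {
  (X[pool[[1]], , drop = FALSE] + X[pool[[2]], , drop = FALSE] +
    X[pool[[3]], , drop = FALSE] + X[pool[[4]], , drop = FALSE]) / 4
}

pool_bwd <- function(dY, pool, HW) {
  dX <- matrix(0, HW, ncol(dY))
  for (k in 1:4) dX[pool[[k]], ] <- dY / 4
  dX
}

upsample_fwd <- function(X, pool, HW) {
  Y <- matrix(0, HW, ncol(X))
  for (k in 1:4) Y[pool[[k]], ] <- X
  Y
}

upsample_bwd <- function(dY, pool) {
  dY[pool[[1]], , drop = FALSE] + dY[pool[[2]], , drop = FALSE] +
    dY[pool[[3]], , drop = FALSE] + dY[pool[[4]], , drop = FALSE]
}

#' Residual U-Net architecture specification
#'
#' A canonical encoder-decoder with `m` down-/upsampling stages:
#' two 3x3 convolution + ReLU blocks per scale, 2x2 mean pooling down,
#' nearest-neighbor upsampling with concatenating skip connections up,
#' channel counts doubling per scale from `base_channels`, and a final
#' 1x1 convolution whose output is *added* to the input (residual
#' connection), so the network computes an artifact correction.  Deeper
#' `m` means a larger receptive field and more parameters.
#'
#' Inputs must be `N x N` with `N` divisible by `2^m`.
#'
#' @param m Number of down-/upsampling stages (>= 1).
#' @param base_channels Channels at the finest scale (default 8, a width
#'   sized for single-CPU experimentation; widen for production use).
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(m = 1, base_channels = 8) {
  stopifnot(m >= 1, m == round(m), base_channels >= 1)
  structure(
    list(m = as.integer(m), base_channels = as.integer(base_channels)),
    class = "network_spec"
  )
}

he_init <- function(n_in, n_out, fan) {
  matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / fan)), n_in, n_out)
}

#' Initialize a residual U-Net
#'
#' Draws He-normal weights for all 3x3 convolutions and zero-initializes
#' the final 1x1 correction layer, so the freshly built network is exactly
#' the identity map — training starts from "no correction".
#'
#' @param spec A [network_spec].
#' @param seed Integer seed for the weight draw.
#' @return An object of class `unet_network`.
#' @export
build_unet <- function(spec = network_spec(), seed = 1) {
  stopifnot(inherits(spec, "network_spec"))
  m <- spec$m
  c0 <- spec$base_channels
  conv <- function(cin, cout) {
    list(W = he_init(9L * cin, cout, fan = 9L * cin), b = numeric(cout))
  }
  params <- withr::with_seed(as.integer(seed), {
    enc <- lapply(seq_len(m), function(l) {
      cin <- if (l == 1) 1L else c0 * 2L^(l - 2L)
      cl <- c0 * 2L^(l - 1L)
      list(conv1 = conv(cin, cl), conv2 = conv(cl, cl))
    })
    cm <- c0 * 2L^(m - 1L)
    bott <- list(conv1 = conv(cm, 2L * cm), conv2 = conv(2L * cm, 2L * cm))
    dec <- lapply(seq_len(m), function(l) {
      cl <- c0 * 2L^(l - 1L)
      list(conv1 = conv(3L * cl, cl), conv2 = conv(cl, cl))
    })
    out <- list(W = matrix(0, c0, 1L), b = numeric(1L))
    list(enc = enc, bott = bott, dec = dec, out = out)
  })
  structure(list(spec = spec, params = params, seed = as.integer(seed)),
    class = c("unet_network", "nett_network")
  )
}

check_unet_input <- function(net, x) {
  if (!is.matrix(x) || nrow(x) != ncol(x)) {
    stop("network input must be a square matrix", call. = FALSE)
  }
  if (nrow(x) %% 2L^net$spec$m != 0) {
    stop("input size must be divisible by 2^m", call. = FALSE)
  }
}

# forward pass; returns output image and (optionally) the caches needed
# for the backward pass
unet_forward <- function(net, x, keep_cache = FALSE) {
  check_unet_input(net, x)
  m <- net$spec$m
  p <- net$params
  H <- nrow(x)
  X <- matrix(as.vector(x), ncol = 1L)
  cache <- if (keep_cache) list(enc = vector("list", m), dec = vector("list", m))
  skips <- vector("list", m)
  dims <- vector("list", m + 1L)
  for (l in seq_len(m)) {
    ci <- conv_indices(H, H)
    dims[[l]] <- ci
    f1 <- conv3_fwd(X, p$enc[[l]]$conv1$W, p$enc[[l]]$conv1$b, ci$idx)
    A1 <- pmax(f1$Y, 0)
    f2 <- conv3_fwd(A1, p$enc[[l]]$conv2$W, p$enc[[l]]$conv2$b, ci$idx)
    A2 <- pmax(f2$Y, 0)
    if (keep_cache) {
      cache$enc[[l]] <- list(Xcol1 = f1$Xcol, A1 = A1, Xcol2 = f2$Xcol, A2 = A2)
    }
    skips[[l]] <- A2
    X <- pool_fwd(A2, ci$pool)
    H <- H %/% 2L
  }
  ci <- conv_indices(H, H)
  dims[[m + 1L]] <- ci
  f1 <- conv3_fwd(X, p$bott$conv1$W, p$bott$conv1$b, ci$idx)
  A1 <- pmax(f1$Y, 0)
  f2 <- conv3_fwd(A1, p$bott$conv2$W, p$bott$conv2$b, ci$idx)
  B <- pmax(f2$Y, 0)
  if (keep_cache) {
    cache$bott <- list(Xcol1 = f1$Xcol, A1 = A1, Xcol2 = f2$Xcol, A2 = B)
  }
  for (l in rev(seq_len(m))) {
    H <- H * 2L
    ci <- dims[[l]]
    up <- upsample_fwd(B, ci$pool, H * H)
    Xc <- cbind(up, skips[[l]])
    f1 <- conv3_fwd(Xc, p$dec[[l]]$conv1$W, p$dec[[l]]$conv1$b, ci$idx)
    A1 <- pmax(f1$Y, 0)
    f2 <- conv3_fwd(A1, p$dec[[l]]$conv2$W, p$dec[[l]]$conv2$b, ci$idx)
    B <- pmax(f2$Y, 0)
    if (keep_cache) {
      cache$dec[[l]] <- list(
        Xcol1 = f1$Xcol, A1 = A1, Xcol2 = f2$Xcol, A2 = B, cin1 = ncol(Xc)
      )
    }
  }
  corr <- sweep(B %*% p$out$W, 2L, p$out$b, `+`)
  y <- x + matrix(corr, nrow(x), ncol(x))
  if (keep_cache) {
    cache$outB <- B
    cache$dims <- dims
    cache$N <- nrow(x)
    list(y = y, cache = cache)
  } else {
    y
  }
}

# reverse pass: given dL/dy (same shape as the output image), returns the
# input gradient dL/dx and, when requested, all parameter gradients
unet_backward <- function(net, cache, gy, want_params = TRUE) {
  m <- net$spec$m
  p <- net$params
  dims <- cache$dims
  gp <- if (want_params) {
    list(
      enc = vector("list", m), bott = NULL, dec = vector("list", m),
      out = NULL
    )
  }
  G <- matrix(as.vector(gy), ncol = 1L)
  # residual: y = x + conv1x1(B)
  dcorr <- G
  if (want_params) {
    gp$out <- list(W = crossprod(cache$outB, dcorr), b = sum(dcorr))
  }
  dB <- tcrossprod(dcorr, p$out$W) # (HW x 1) %*% (1 x c0)
  dskip <- vector("list", m)
  for (l in seq_len(m)) { # decoder, finest to coarsest
    ci <- dims[[l]]
    cc <- cache$dec[[l]]
    dA2 <- dB * (cc$A2 > 0)
    b2 <- conv3_bwd(dA2, cc$Xcol2, p$dec[[l]]$conv2$W, ci$idx,
      cin = ncol(cc$A1), want_params = want_params
    )
    dA1 <- b2$dX * (cc$A1 > 0)
    b1 <- conv3_bwd(dA1, cc$Xcol1, p$dec[[l]]$conv1$W, ci$idx,
      cin = cc$cin1, want_params = want_params
    )
    if (want_params) {
      gp$dec[[l]] <- list(
        conv1 = list(W = b1$gW, b = b1$gb),
        conv2 = list(W = b2$gW, b = b2$gb)
      )
    }
    cup <- ncol(b1$dX) - ncol(cache$enc[[l]]$A2)
    dskip[[l]] <- b1$dX[, (cup + 1L):ncol(b1$dX), drop = FALSE]
    dB <- upsample_bwd(b1$dX[, seq_len(cup), drop = FALSE], ci$pool)
  }
  # bottleneck
  ci <- dims[[m + 1L]]
  cc <- cache$bott
  dA2 <- dB * (cc$A2 > 0)
  b2 <- conv3_bwd(dA2, cc$Xcol2, p$bott$conv2$W, ci$idx,
    cin = ncol(cc$A1), want_params = want_params
  )
  dA1 <- b2$dX * (cc$A1 > 0)
  cin_b <- ncol(cache$enc[[m]]$A2)
  b1 <- conv3_bwd(dA1, cc$Xcol1, p$bott$conv1$W, ci$idx,
    cin = cin_b, want_params = want_params
  )
  if (want_params) {
    gp$bott <- list(
      conv1 = list(W = b1$gW, b = b1$gb),
      conv2 = list(W = b2$gW, b = b2$gb)
    )
  }
  dX <- b1$dX
  for (l in rev(seq_len(m))) { # encoder, coarsest to finest
    ci <- dims[[l]]
    cc <- cache$enc[[l]]
    HW <- nrow(cc$A2)
    dA2 <- pool_bwd(dX, ci$pool, HW) + dskip[[l]]
    dA2 <- dA2 * (cc$A2 > 0)
    b2 <- conv3_bwd(dA2, cc$Xcol2, p$enc[[l]]$conv2$W, ci$idx,
      cin = ncol(cc$A1), want_params = want_params
    )
    dA1 <- b2$dX * (cc$A1 > 0)
    cin1 <- if (l == 1) 1L else ncol(cache$enc[[l - 1L]]$A2)
    b1 <- conv3_bwd(dA1, cc$Xcol1, p$enc[[l]]$conv1$W, ci$idx,
      cin = cin1, want_params = want_params
    )
    if (want_params) {
      gp$enc[[l]] <- list(
        conv1 = list(W = b1$gW, b = b1$gb),
        conv2 = list(W = b2$gW, b = b2$gb)
      )
    }
    dX <- b1$dX
  }
  gx <- matrix(as.vector(gy), cache$N, cache$N) + # identity (residual) path
    matrix(dX, cache$N, cache$N)
  list(gx = gx, gparams = gp)
}

#' Apply a network to an image
#'
#' Generic over the network kinds used in the package: the trained
#' residual U-Net, and the degenerate networks (`zero`, `identity`,
#' `linear`) used for convex-case verification.
#'
#' @param net A network object (`unet_network`, [zero_network()],
#'   [identity_network()], [linear_network()]).
#' @param x Square image matrix (or coefficient vector of length `N^2`).
#' @return Image matrix of the same shape as `x` (matrix in, matrix out).
#' @export
network_apply <- function(net, x) UseMethod("network_apply")

#' @export
network_apply.unet_network <- function(net, x) {
  vec <- !is.matrix(x)
  img <- coef_to_image(x)
  y <- unet_forward(net, img, keep_cache = FALSE)
  if (vec) image_to_coef(y) else y
}

#' Vector-Jacobian product of a network
#'
#' Returns `t(J_Phi(x)) %*% g`, the adjoint-Jacobian action at `x` applied
#' to `g`.  For the residual U-Net this is the exact reverse-mode
#' derivative, including the identity path of the residual connection.
#'
#' @inheritParams network_apply
#' @param g Cotangent with the same shape as the network output.
#' @return Gradient with the shape of `x`.
#' @export
network_vjp <- function(net, x, g) UseMethod("network_vjp")

#' @export
network_vjp.unet_network <- function(net, x, g) {
  vec <- !is.matrix(x)
  fw <- unet_forward(net, coef_to_image(x), keep_cache = TRUE)
  bw <- unet_backward(net, fw$cache, coef_to_image(g), want_params = FALSE)
  if (vec) image_to_coef(bw$gx) else bw$gx
}

#' Degenerate networks for analysis and testing
#'
#' `zero_network()` maps every input to 0 (so the learned penalty term
#' becomes `||x||^2`); `identity_network()` maps every input to itself
#' (penalty 0); `linear_network(L)` applies a fixed matrix `L` to the
#' coefficient vector.  With any of these, the NETT functional is convex
#' and has a closed-form minimizer, which the solver tests exploit.
#'
#' @param L Square matrix acting on coefficient vectors.
#' @return A network object usable with [network_apply()] /
#'   [network_vjp()] and [learned_regularizer()].
#' @export
zero_network <- function() {
  structure(list(), class = c("zero_network", "nett_network"))
}

#' @rdname zero_network
#' @export
identity_network <- function() {
  structure(list(), class = c("identity_network", "nett_network"))
}

#' @rdname zero_network
#' @export
linear_network <- function(L) {
  stopifnot(is.matrix(L), nrow(L) == ncol(L))
  structure(list(L = L), class = c("linear_network", "nett_network"))
}

#' @export
network_apply.zero_network <- function(net, x) {
  if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else numeric(length(x))
}

#' @export
network_vjp.zero_network <- function(net, x, g) {
  if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else numeric(length(x))
}

#' @export
network_apply.identity_network <- function(net, x) x

#' @export
network_vjp.identity_network <- function(net, x, g) g

#' @export
network_apply.linear_network <- function(net, x) {
  vec <- !is.matrix(x)
  v <- image_to_coef(coef_to_image(x))
  y <- drop(net$L %*% v)
  if (vec) y else coef_to_image(y)
}

#' @export
network_vjp.linear_network <- function(net, x, g) {
  vec <- !is.matrix(g)
  v <- image_to_coef(coef_to_image(g))
  y <- drop(crossprod(net$L, v))
  if (vec) y else coef_to_image(y)
}

# ---- parameter (un)flattening for the optimizer --------------------------

params_to_vec <- function(p) {
  unlist(p, use.names = FALSE)
}

vec_to_params <- function(v, template) {
  pos <- 0L
  walk <- function(b) {
    if (is.list(b)) {
      lapply(b, walk)
    } else {
      n <- length(b)
      out <- v[(pos + 1L):(pos + n)]
      pos <<- pos + n
      if (is.matrix(b)) dim(out) <- dim(b)
      out
    }
  }
  out <- walk(template)
  stopifnot(pos == length(v))
  out
}
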