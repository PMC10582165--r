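## Convolutional-autoencoder denoiser.
##
## Architecture (fixed topology, configurable widths): an encoder of two
## 3x3 convolution + ReLU stages each followed by 2x2 max-pooling, and a
## decoder of two 3x3 convolution + ReLU stages each followed by 2x2
## nearest-neighbour upsampling, closed by a single-filter 3x3 convolution
## with linear output. Trained with Adam on mean-squared reconstruction
## error between denoised and clean patches. Everything (im2col
## convolutions, pooling routing, backpropagation) is implemented here in
## plain vectorized R; the network is small enough that this trains in
## seconds at desk scale.
##
## Tensors are arrays [N, H, W, C]; images live on [0, 1] inside the net.

dn_pad1 <- function(x) {
  d <- dim(x)
  xp <- array(0, c(d[1], d[2] + 2L, d[3] + 2L, d[4]))
  xp[, 2L:(d[2] + 1L), 2L:(d[3] + 1L), ] <- x
  xp
}

## im2col for a 3x3 same-padding convolution: [N*H*W, 9*Cin]
dn_im2col <- function(x) {
  d <- dim(x)
  xp <- dn_pad1(x)
  cols <- vector("list", 9L)
  k <- 1L
  for (kj in 1:3) for (ki in 1:3) {
    sl <- xp[, ki:(ki + d[2] - 1L), kj:(kj + d[3] - 1L), , drop = FALSE]
    dim(sl) <- c(d[1] * d[2] * d[3], d[4])
    cols[[k]] <- sl
    k <- k + 1L
  }
  do.call(cbind, cols)
}

## weight layout: Wmat [9*Cin, Cout], rows ordered as dn_im2col's columns
dn_conv_fwd <- function(x, Wmat, b) {
  d <- dim(x)
  Xc <- dn_im2col(x)
  Y <- Xc %*% Wmat
  Y <- sweep(Y, 2, b, `+`)
  dim(Y) <- c(d[1], d[2], d[3], length(b))
  list(y = Y, Xc = Xc)
}

## gradient wrt input = same-conv of dY with the spatially flipped kernel
## and swapped in/out channels
dn_flip_weights <- function(Wmat, Cin, Cout) {
  ## Wmat rows are ordered (cin within tap, taps (ki,kj) in column-major 3x3):
  ## reorganize into [tap, cin, cout], flip taps, swap channel roles
  Wt <- array(0, c(9L, Cin, Cout))
  for (tap in 1:9)
    Wt[tap, , ] <- Wmat[((tap - 1L) * Cin + 1L):(tap * Cin), , drop = FALSE]
  Wf <- Wt[9:1, , , drop = FALSE]              # 180-degree spatial flip
  out <- matrix(0, 9L * Cout, Cin)
  for (tap in 1:9)
    out[((tap - 1L) * Cout + 1L):(tap * Cout), ] <- t(Wf[tap, , ])
  out
}

dn_conv_bwd <- function(dY, cache_Xc, x_dim, Wmat) {
  Cin <- x_dim[4]; Cout <- ncol(Wmat)
  dYc <- dY
  dim(dYc) <- c(prod(dim(dY)[1:3]), Cout)
  dW <- crossprod(cache_Xc, dYc)
  db <- colSums(dYc)
  Wb <- dn_flip_weights(Wmat, Cin, Cout)
  dX <- dn_conv_fwd(dY, Wb, numeric(Cin))$y
  list(dX = dX, dW = dW, db = db)
}

dn_relu_fwd <- function(x) list(y = pmax(x, 0), mask = x > 0)
dn_relu_bwd <- function(dY, mask) dY * mask

## 2x2 non-overlapping max-pool; ties route to the first window position
dn_pool_fwd <- function(x) {
  d <- dim(x)
  io <- seq(1L, d[2], 2L); jo <- seq(1L, d[3], 2L)
  s <- list(x[, io, jo, , drop = FALSE], x[, io + 1L, jo, , drop = FALSE],
            x[, io, jo + 1L, , drop = FALSE], x[, io + 1L, jo + 1L, , drop = FALSE])
  y <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  taken <- array(FALSE, dim(y))
  masks <- vector("list", 4L)
  for (k in 1:4) {
    masks[[k]] <- (s[[k]] == y) & !taken
    taken <- taken | masks[[k]]
  }
  list(y = y, masks = masks, in_dim = d)
}

dn_pool_bwd <- function(dY, cache) {
  d <- cache$in_dim
  io <- seq(1L, d[2], 2L); jo <- seq(1L, d[3], 2L)
  dX <- array(0, d)
  dX[, io, jo, ] <- dY * cache$masks[[1]]
  dX[, io + 1L, jo, ] <- dY * cache$masks[[2]]
  dX[, io, jo + 1L, ] <- dY * cache$masks[[3]]
  dX[, io + 1L, jo + 1L, ] <- dY * cache$masks[[4]]
  dX
}

dn_up_fwd <- function(x) {
  d <- dim(x)
  y <- array(0, c(d[1], 2L * d[2], 2L * d[3], d[4]))
  io <- seq(1L, 2L * d[2], 2L); jo <- seq(1L, 2L * d[3], 2L)
  y[, io, jo, ] <- x; y[, io + 1L, jo, ] <- x
  y[, io, jo + 1L, ] <- x; y[, io + 1L, jo + 1L, ] <- x
  y
}

dn_up_bwd <- function(dY) {
  d <- dim(dY)
  io <- seq(1L, d[2], 2L); jo <- seq(1L, d[3], 2L)
  dY[, io, jo, , drop = FALSE] + dY[, io + 1L, jo, , drop = FALSE] +
    dY[, io, jo + 1L, , drop = FALSE] + dY[, io + 1L, jo + 1L, , drop = FALSE]
}

#' Denoiser architecture specification
#'
#' @param filters Length-2 integer vector: channel widths of the two encoder
#'   convolution stages (mirrored by the decoder). Default `c(8, 8)`.
#' @param kernel Convolution kernel side; fixed at 3 in this implementation.
#' @return An object of class `denoiser_spec`.
#' @export
denoiser_spec <- function(filters = c(8L, 8L), kernel = 3L) {
  if (kernel != 3L) stop("denoiser_spec: only 3x3 kernels are implemented")
  if (length(filters) != 2L || any(filters < 1L))
    stop("denoiser_spec: filters must be two positive widths")
  structure(list(filters = as.integer(filters), kernel = 3L),
            class = "denoiser_spec")
}

dn_init <- function(spec) {
  f1 <- spec$filters[1]; f2 <- spec$filters[2]
  mk <- function(cin, cout) {
    list(W = matrix(stats::rnorm(9L * cin * cout, 0, sqrt(2 / (9 * cin))),
                    9L * cin, cout),
         b = numeric(cout))
  }
  list(conv1 = mk(1L, f1), conv2 = mk(f1, f2),   # encoder
       conv3 = mk(f2, f2), conv4 = mk(f2, f1),   # decoder
       conv5 = mk(f1, 1L))                       # single-filter output
}

dn_forward <- function(x, par, keep = FALSE) {
  c1 <- dn_conv_fwd(x, par$conv1$W, par$conv1$b); r1 <- dn_relu_fwd(c1$y)
  p1 <- dn_pool_fwd(r1$y)
  c2 <- dn_conv_fwd(p1$y, par$conv2$W, par$conv2$b); r2 <- dn_relu_fwd(c2$y)
  p2 <- dn_pool_fwd(r2$y)
  c3 <- dn_conv_fwd(p2$y, par$conv3$W, par$conv3$b); r3 <- dn_relu_fwd(c3$y)
  u1 <- dn_up_fwd(r3$y)
  c4 <- dn_conv_fwd(u1, par$conv4$W, par$conv4$b); r4 <- dn_relu_fwd(c4$y)
  u2 <- dn_up_fwd(r4$y)
  c5 <- dn_conv_fwd(u2, par$conv5$W, par$conv5$b)
  out <- list(y = c5$y)
  if (keep) out$cache <- list(x = x, c1 = c1, r1 = r1, p1 = p1, c2 = c2,
                              r2 = r2, p2 = p2, c3 = c3, r3 = r3, u1 = u1,
                              c4 = c4, r4 = r4, u2 = u2, c5 = c5)
  out
}

dn_backward <- function(dY, cache, par) {
  g <- list()
  b5 <- dn_conv_bwd(dY, cache$c5$Xc, dim(cache$u2), par$conv5$W)
  g$conv5 <- b5[c("dW", "db")]
  d <- dn_up_bwd(b5$dX)
  d <- dn_relu_bwd(d, cache$r4$mask)
  b4 <- dn_conv_bwd(d, cache$c4$Xc, dim(cache$u1), par$conv4$W)
  g$conv4 <- b4[c("dW", "db")]
  d <- dn_up_bwd(b4$dX)
  d <- dn_relu_bwd(d, cache$r3$mask)
  b3 <- dn_conv_bwd(d, cache$c3$Xc, dim(cache$p2$y), par$conv3$W)
  g$conv3 <- b3[c("dW", "db")]
  d <- dn_pool_bwd(b3$dX, cache$p2)
  d <- dn_relu_bwd(d, cache$r2$mask)
  b2 <- dn_conv_bwd(d, cache$c2$Xc, dim(cache$p1$y), par$conv2$W)
  g$conv2 <- b2[c("dW", "db")]
  d <- dn_pool_bwd(b2$dX, cache$p1)
  d <- dn_relu_bwd(d, cache$r1$mask)
  b1 <- dn_conv_bwd(d, cache$c1$Xc, dim(cache$x), par$conv1$W)
  g$conv1 <- b1[c("dW", "db")]
  g
}

## coerce patches (list of matrices, or array [P, P, N]) to [N, P, P, 1] in [0, 1]
dn_stack <- function(patches, L) {
  if (is.list(patches)) {
    P <- nrow(patches[[1]])
    x <- array(0, c(length(patches), P, P, 1L))
    for (i in seq_along(patches)) x[i, , , 1L] <- patches[[i]]
  } else {
    d <- dim(patches)
    x <- aperm(array(patches, c(d[1], d[2], d[3], 1L)), c(3, 1, 2, 4))
  }
  x / (L - 1)
}

#' Train the convolutional-autoencoder denoiser
#'
#' @param clean_patches,noisy_patches Matched patch sets: lists of square
#'   matrices or arrays `[side, side, n]`, side divisible by 4, at least 100
#'   pairs, intensities on the `[0, L-1]` scale.
#' @param spec A [denoiser_spec()].
#' @param epochs Training epochs (default 20).
#' @param seed Seed for initialization and minibatch order; training is
#'   deterministic given the seed.
#' @param lr Adam learning rate (default 5e-3).
#' @param batch_size Minibatch size (default 32).
#' @param bit_depth Gray levels of the patch scale (default 256).
#' @return An object of class `denoiser` carrying the trained weights and
#'   the per-epoch loss history.
#' @export
train_denoiser <- function(clean_patches, noisy_patches, spec = denoiser_spec(),
                           epochs = 20L, seed = 1L, lr = 5e-3,
                           batch_size = 32L, bit_depth = 256L) {
  n <- if (is.list(clean_patches)) length(clean_patches) else dim(clean_patches)[3]
  nn <- if (is.list(noisy_patches)) length(noisy_patches) else dim(noisy_patches)[3]
  if (n != nn) stop("train_denoiser: clean and noisy patch counts differ")
  if (n < 100L) stop("train_denoiser: need at least 100 patch pairs")
  xc <- dn_stack(clean_patches, bit_depth)
  xn <- dn_stack(noisy_patches, bit_depth)
  P <- dim(xc)[2]
  if (P %% 4L != 0L)
    stop("train_denoiser: patch side must be divisible by 4 (two pooling stages)")

  with_seed(seed, {
    par <- dn_init(spec)
    adam <- lapply(par, function(p) list(mW = 0 * p$W, vW = 0 * p$W,
                                         mb = 0 * p$b, vb = 0 * p$b))
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    t_step <- 0L
    loss_hist <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_m <- 0L
      for (start in seq(1L, n, batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        xb <- xn[idx, , , , drop = FALSE]
        yb <- xc[idx, , , , drop = FALSE]
        fw <- dn_forward(xb, par, keep = TRUE)
        err <- fw$y - yb
        loss <- mean(err^2)
        grads <- dn_backward(2 * err / length(err), fw$cache, par)
        t_step <- t_step + 1L
        for (ly in names(par)) {
          a <- adam[[ly]]; g <- grads[[ly]]
          a$mW <- beta1 * a$mW + (1 - beta1) * g$dW
          a$vW <- beta2 * a$vW + (1 - beta2) * g$dW^2
          a$mb <- beta1 * a$mb + (1 - beta1) * g$db
          a$vb <- beta2 * a$vb + (1 - beta2) * g$db^2
          corr1 <- 1 - beta1^t_step; corr2 <- 1 - beta2^t_step
          par[[ly]]$W <- par[[ly]]$W - lr * (a$mW / corr1) /
            (sqrt(a$vW / corr2) + eps)
          par[[ly]]$b <- par[[ly]]$b - lr * (a$mb / corr1) /
            (sqrt(a$vb / corr2) + eps)
          adam[[ly]] <- a
        }
        ep_loss <- ep_loss + loss * length(idx)
        ep_m <- ep_m + length(idx)
      }
      loss_hist[ep] <- ep_loss / ep_m
    }
    structure(list(spec = spec, weights = par, loss = loss_hist,
                   bit_depth = as.integer(bit_depth), trained = TRUE),
              class = "denoiser")
  })
}

#' @export
print.denoiser <- function(x, ...) {
  cat(sprintf("<denoiser> conv widths %s, %d epochs, final loss %.3g\n",
              paste(x$spec$filters, collapse = "/"), length(x$loss),
              x$loss[length(x$loss)]))
  invisible(x)
}

#' Apply a trained denoiser to a slice
#'
#' The slice is mirror-padded to dimensions divisible by 4, passed through
#' the autoencoder, cropped back, and re-quantized to the input's bit depth.
#'
#' @param image A [slice_image()].
#' @param denoiser A trained [train_denoiser()] object.
#' @return Denoised `slice_image`, same dimensions and bit depth.
#' @export
denoise <- function(image, denoiser) {
  if (!inherits(denoiser, "denoiser") || !isTRUE(denoiser$trained))
    stop("denoise: needs a trained denoiser")
  X <- px(image)
  L <- attr(image, "bit_depth") %||% 256L
  n <- nrow(X); m <- ncol(X)
  pr <- (4 - n %% 4) %% 4; pc <- (4 - m %% 4) %% 4
  if (pr > 0 || pc > 0) {
    Xp <- pad_sym(X, max(pr, pc))
    off <- max(pr, pc)
    X <- Xp[(off + 1):(off + n + pr), (off + 1):(off + m + pc), drop = FALSE]
  }
  xb <- array(X / (L - 1), c(1L, nrow(X), ncol(X), 1L))
  y <- dn_forward(xb, denoiser$weights)$y[1, , , 1]
  y <- y[seq_len(n), seq_len(m), drop = FALSE] * (L - 1)
  quantize_slice(reslice(image, y))
}
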