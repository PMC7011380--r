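# Neural-network layer primitives (pure R, vectorized over the batch).
#
# Activations travel as 3-D arrays [batch, time, channels] until flattened.
# Each layer is an environment holding `params` (named list of arrays),
# `grads` (same shapes, filled by backward), a `forward(x, training)` and a
# `backward(dy)` closure, plus per-parameter Adam state. Gate order inside
# the fused LSTM weight matrix is [forget | input | candidate | output].

slice_t <- function(X, t) {
  m <- X[, t, , drop = FALSE]
  dim(m) <- c(dim(X)[1], dim(X)[3])
  m
}

new_layer <- function(kind, params = list()) {
  env <- new.env(parent = emptyenv())
  env$kind <- kind
  env$params <- params
  env$grads <- NULL
  env
}

glorot <- function(n_in, n_out, nrow, ncol) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

## ---- embedding ------------------------------------------------------------

layer_embedding <- function(init) {
  ly <- new_layer("embedding", list(E = init))
  ly$forward <- function(x, training = FALSE) {
    # x: integer token matrix [n, T], values 0-based
    ly$tokens <- x
    n <- nrow(x); tt <- ncol(x); d <- ncol(ly$params$E)
    out <- ly$params$E[as.vector(x) + 1L, , drop = FALSE]
    dim(out) <- c(n, tt, d)
    out
  }
  ly$backward <- function(dy) {
    n <- dim(dy)[1]; tt <- dim(dy)[2]; d <- dim(dy)[3]
    dy2 <- matrix(dy, n * tt, d)
    grp <- as.vector(ly$tokens)
    acc <- rowsum(dy2, grp)
    dE <- matrix(0, nrow(ly$params$E), d)
    dE[as.integer(rownames(acc)) + 1L, ] <- acc
    ly$grads <- list(E = dE)
    NULL  # tokens have no gradient
  }
  ly
}

## ---- bidirectional LSTM ---------------------------------------------------

# One-directional LSTM forward over X [n, T, d]; W ((u+d) x 4u), layout
# [h, x] rows, [f|i|g|o] gate columns. The input projection x_t W_x is
# hoisted out of the time loop as one (nT x d) matmul.
lstm_forward_dir <- function(X, W, b, u) {
  n <- dim(X)[1]; tt <- dim(X)[2]; d <- dim(X)[3]
  W_h <- W[1:u, , drop = FALSE]
  W_x <- W[(u + 1):(u + d), , drop = FALSE]
  Xm <- matrix(X, n * tt, d)
  Gx <- Xm %*% W_x
  brep <- rep(b, each = n)
  i1 <- 1:u; i2 <- (u + 1):(2 * u)
  i3 <- (2 * u + 1):(3 * u); i4 <- (3 * u + 1):(4 * u)
  H <- array(0, c(n, tt, u))
  h <- matrix(0, n, u); cc <- matrix(0, n, u)
  cache <- vector("list", tt)
  for (t in seq_len(tt)) {
    rows <- ((t - 1L) * n + 1L):(t * n)
    gmat <- Gx[rows, , drop = FALSE] + h %*% W_h + brep
    f <- sigmoid(gmat[, i1, drop = FALSE])
    i <- sigmoid(gmat[, i2, drop = FALSE])
    g <- tanh(gmat[, i3, drop = FALSE])
    o <- sigmoid(gmat[, i4, drop = FALSE])
    c_prev <- cc
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    cache[[t]] <- list(h_prev = h, f = f, i = i, g = g, o = o,
                       c_prev = c_prev, tanh_c = tc)
    h <- o * tc
    H[, t, ] <- h
  }
  list(H = H, cache = cache, Xm = Xm, W_h = W_h, W_x = W_x)
}

# Backward of the one-directional pass. dH: external gradient on every
# hidden state [n, T, u]. Returns dX, dW, db.
lstm_backward_dir <- function(dH, fwd, u, d_in) {
  n <- dim(dH)[1]; tt <- dim(dH)[2]
  dGstack <- matrix(0, n * tt, 4L * u)
  dW_h <- matrix(0, u, 4L * u)
  dh_carry <- matrix(0, n, u); dc_next <- matrix(0, n, u)
  for (t in rev(seq_len(tt))) {
    cs <- fwd$cache[[t]]
    dh <- slice_t(dH, t) + dh_carry
    dpre_o <- (dh * cs$tanh_c) * cs$o * (1 - cs$o)
    dc <- dh * cs$o * (1 - cs$tanh_c^2) + dc_next
    dpre_f <- (dc * cs$c_prev) * cs$f * (1 - cs$f)
    dpre_i <- (dc * cs$g) * cs$i * (1 - cs$i)
    dpre_g <- (dc * cs$i) * (1 - cs$g^2)
    dG <- cbind(dpre_f, dpre_i, dpre_g, dpre_o)
    dGstack[((t - 1L) * n + 1L):(t * n), ] <- dG
    dW_h <- dW_h + crossprod(cs$h_prev, dG)
    dh_carry <- tcrossprod(dG, fwd$W_h)
    dc_next <- dc * cs$f
  }
  dX <- tcrossprod(dGstack, fwd$W_x)
  dim(dX) <- c(n, tt, d_in)
  list(dX = dX,
       dW = rbind(dW_h, crossprod(fwd$Xm, dGstack)),
       db = colSums(dGstack))
}

rev_time <- function(X) X[, dim(X)[2]:1, , drop = FALSE]

layer_bilstm <- function(d_in, units, out_dim) {
  u <- units
  ly <- new_layer("bilstm", list(
    W_fwd = glorot(u + d_in, u, u + d_in, 4 * u),
    b_fwd = numeric(4 * u),
    W_bwd = glorot(u + d_in, u, u + d_in, 4 * u),
    b_bwd = numeric(4 * u),
    V = glorot(u, out_dim, u, out_dim),
    V2 = glorot(u, out_dim, u, out_dim)))
  ly$units <- u; ly$d_in <- d_in; ly$out_dim <- out_dim
  ly$forward <- function(x, training = FALSE) {
    p <- ly$params
    fwd <- lstm_forward_dir(x, p$W_fwd, p$b_fwd, u)
    bwd <- lstm_forward_dir(rev_time(x), p$W_bwd, p$b_bwd, u)
    Ab <- rev_time(bwd$H)               # align to original positions
    n <- dim(x)[1]; tt <- dim(x)[2]
    Afm <- matrix(fwd$H, n * tt, u)
    Abm <- matrix(Ab, n * tt, u)
    y <- tanh(Afm %*% p$V + Abm %*% p$V2)
    dim(y) <- c(n, tt, ly$out_dim)
    ly$cache <- list(fwd = fwd, bwd = bwd, Afm = Afm, Abm = Abm, y = y)
    y
  }
  ly$backward <- function(dy) {
    p <- ly$params; cs <- ly$cache
    n <- dim(dy)[1]; tt <- dim(dy)[2]
    dprem <- matrix(dy * (1 - cs$y^2), n * tt, ly$out_dim)
    dAf <- tcrossprod(dprem, p$V); dim(dAf) <- c(n, tt, u)
    dAb <- tcrossprod(dprem, p$V2); dim(dAb) <- c(n, tt, u)
    bf <- lstm_backward_dir(dAf, cs$fwd, u, ly$d_in)
    bb <- lstm_backward_dir(rev_time(dAb), cs$bwd, u, ly$d_in)
    ly$grads <- list(W_fwd = bf$dW, b_fwd = bf$db,
                     W_bwd = bb$dW, b_bwd = bb$db,
                     V = crossprod(cs$Afm, dprem),
                     V2 = crossprod(cs$Abm, dprem))
    bf$dX + rev_time(bb$dX)
  }
  ly
}

## ---- 1-D convolution (same padding, stride 1) -----------------------------

layer_conv1d <- function(c_in, c_out, kernel, activation = c("linear", "relu")) {
  activation <- match.arg(activation)
  ly <- new_layer("conv", list(
    W = glorot(kernel * c_in, c_out, kernel * c_in, c_out),
    b = numeric(c_out)))
  ly$kernel <- kernel; ly$c_in <- c_in; ly$c_out <- c_out
  ly$activation <- activation
  pad_l <- (kernel - 1L) %/% 2L
  ly$forward <- function(x, training = FALSE) {
    n <- dim(x)[1]; tt <- dim(x)[2]; k <- kernel
    Xp <- array(0, c(n, tt + k - 1L, c_in))
    Xp[, pad_l + seq_len(tt), ] <- x
    Xcol <- array(0, c(n, tt, k * c_in))
    for (kk in seq_len(k)) {
      Xcol[, , ((kk - 1L) * c_in + 1L):(kk * c_in)] <-
        Xp[, kk:(kk + tt - 1L), , drop = FALSE]
    }
    dim(Xcol) <- c(n * tt, k * c_in)
    pre <- Xcol %*% ly$params$W + rep(ly$params$b, each = n * tt)
    out <- if (activation == "relu") pre * (pre > 0) else pre
    ly$cache <- list(Xcol = Xcol, n = n, tt = tt,
                     mask = if (activation == "relu") pre > 0 else NULL)
    dim(out) <- c(n, tt, c_out)
    out
  }
  ly$backward <- function(dy) {
    cs <- ly$cache; n <- cs$n; tt <- cs$tt; k <- kernel
    dpre <- matrix(dy, n * tt, c_out)
    if (!is.null(cs$mask)) dpre <- dpre * cs$mask
    ly$grads <- list(W = crossprod(cs$Xcol, dpre), b = colSums(dpre))
    dXcol <- tcrossprod(dpre, ly$params$W)
    dim(dXcol) <- c(n, tt, k * c_in)
    dXp <- array(0, c(n, tt + k - 1L, c_in))
    for (kk in seq_len(k)) {
      dXp[, kk:(kk + tt - 1L), ] <- dXp[, kk:(kk + tt - 1L), , drop = FALSE] +
        dXcol[, , ((kk - 1L) * c_in + 1L):(kk * c_in), drop = FALSE]
    }
    dXp[, pad_l + seq_len(tt), , drop = FALSE]
  }
  ly
}

## ---- batch normalization --------------------------------------------------

layer_batchnorm <- function(channels, momentum = 0.9, eps = 1e-5) {
  ly <- new_layer("batchnorm", list(gamma = rep(1, channels),
                                    beta = rep(0, channels)))
  ly$channels <- channels
  ly$running_mean <- rep(0, channels)
  ly$running_var <- rep(1, channels)
  ly$forward <- function(x, training = FALSE) {
    dims <- dim(x)
    M <- matrix(x, prod(dims[-length(dims)]), ly$channels)
    if (training) {
      mu <- colMeans(M)
      v <- colMeans(M^2) - mu^2
      ly$running_mean <- momentum * ly$running_mean + (1 - momentum) * mu
      ly$running_var <- momentum * ly$running_var + (1 - momentum) * v
    } else {
      mu <- ly$running_mean
      v <- ly$running_var
    }
    inv <- 1 / sqrt(v + eps)
    N <- nrow(M)
    xhat <- (M - rep(mu, each = N)) * rep(inv, each = N)
    out <- xhat * rep(ly$params$gamma, each = N) +
      rep(ly$params$beta, each = N)
    ly$cache <- list(xhat = xhat, inv = inv, dims = dims,
                     training = training)
    dim(out) <- dims
    out
  }
  ly$backward <- function(dy) {
    cs <- ly$cache
    N <- nrow(cs$xhat)
    dY <- matrix(dy, N, ly$channels)
    ly$grads <- list(gamma = colSums(dY * cs$xhat), beta = colSums(dY))
    dxhat <- dY * rep(ly$params$gamma, each = N)
    if (cs$training) {
      s1 <- colSums(dxhat)
      s2 <- colSums(dxhat * cs$xhat)
      dM <- (dxhat - rep(s1 / N, each = N) -
               cs$xhat * rep(s2 / N, each = N)) * rep(cs$inv, each = N)
    } else {
      dM <- dxhat * rep(cs$inv, each = N)
    }
    dim(dM) <- cs$dims
    dM
  }
  ly
}

## ---- activation / dropout / flatten ---------------------------------------

layer_relu <- function() {
  ly <- new_layer("relu")
  ly$forward <- function(x, training = FALSE) {
    ly$mask <- x > 0
    x * ly$mask
  }
  ly$backward <- function(dy) {
    ly$grads <- list()
    dy * ly$mask
  }
  ly
}

layer_dropout <- function(rate) {
  ly <- new_layer("dropout")
  ly$rate <- rate
  ly$forward <- function(x, training = FALSE) {
    if (!training || rate == 0) {
      ly$mask <- NULL
      return(x)
    }
    m <- array(stats::runif(length(x)) >= rate, dim(x)) / (1 - rate)
    ly$mask <- m
    x * m
  }
  ly$backward <- function(dy) {
    ly$grads <- list()
    if (is.null(ly$mask)) dy else dy * ly$mask
  }
  ly
}

layer_flatten <- function() {
  ly <- new_layer("flatten")
  ly$forward <- function(x, training = FALSE) {
    ly$dims <- dim(x)
    matrix(x, dim(x)[1], prod(dim(x)[-1]))
  }
  ly$backward <- function(dy) {
    ly$grads <- list()
    dim(dy) <- ly$dims
    dy
  }
  ly
}

## ---- dense ----------------------------------------------------------------

layer_dense <- function(d_in, d_out, activation = c("linear", "relu")) {
  activation <- match.arg(activation)
  ly <- new_layer("dense", list(W = glorot(d_in, d_out, d_in, d_out),
                                b = numeric(d_out)))
  ly$activation <- activation
  ly$forward <- function(x, training = FALSE) {
    pre <- x %*% ly$params$W + rep(ly$params$b, each = nrow(x))
    ly$cache <- list(x = x, mask = if (activation == "relu") pre > 0)
    if (activation == "relu") pre * (pre > 0) else pre
  }
  ly$backward <- function(dy) {
    cs <- ly$cache
    if (!is.null(cs$mask)) dy <- dy * cs$mask
    ly$grads <- list(W = crossprod(cs$x, dy), b = colSums(dy))
    tcrossprod(dy, ly$params$W)
  }
  ly
}

## ---- heads and losses -----------------------------------------------------

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Two-class cross-entropy on logits; returns loss and gradient on logits.
loss_softmax_xent <- function(logits, labels) {
  n <- nrow(logits)
  p <- softmax_rows(logits)
  idx <- cbind(seq_len(n), labels + 1L)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  onehot <- matrix(0, n, ncol(logits))
  onehot[idx] <- 1
  list(loss = loss, grad = (p - onehot) / n, prob = p)
}

# MSE on the sigmoid of a single logit column against frequencies.
loss_sigmoid_mse <- function(logits, target) {
  n <- nrow(logits)
  p <- sigmoid(logits[, 1L])
  loss <- mean((p - target)^2)
  g <- matrix(2 * (p - target) * p * (1 - p) / n, n, 1L)
  list(loss = loss, grad = g, prob = p)
}

## ---- network plumbing -----------------------------------------------------

forward_network <- function(layers, tokens, training = FALSE) {
  x <- tokens
  for (ly in layers) x <- ly$forward(x, training)
  x
}

backward_network <- function(layers, dy) {
  for (ly in rev(layers)) dy <- ly$backward(dy)
  invisible(dy)
}

n_parameters <- function(layers) {
  sum(vapply(layers, function(ly) sum(lengths(ly$params)), numeric(1)))
}

# One Adam update across every parameter of every layer. `step` is the
# global 1-based step counter used for bias correction.
adam_step <- function(layers, lr, step, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  bc1 <- 1 - beta1^step
  bc2 <- 1 - beta2^step
  for (ly in layers) {
    if (is.null(ly$grads) || !length(ly$grads)) next
    if (is.null(ly$opt)) {
      ly$opt <- list(m = lapply(ly$params, function(p) p * 0),
                     v = lapply(ly$params, function(p) p * 0))
    }
    for (nm in names(ly$grads)) {
      g <- ly$grads[[nm]]
      ly$opt$m[[nm]] <- beta1 * ly$opt$m[[nm]] + (1 - beta1) * g
      ly$opt$v[[nm]] <- beta2 * ly$opt$v[[nm]] + (1 - beta2) * g^2
      mhat <- ly$opt$m[[nm]] / bc1
      vhat <- ly$opt$v[[nm]] / bc2
      ly$params[[nm]] <- ly$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  invisible(NULL)
}

#' Forward pass of a bidirectional LSTM on one sequence
#'
#' Reference implementation of the gated recurrence: for each direction,
#' forget gate `f_t = sigmoid(W_f [h_{t-1}, x_t] + b_f)`, input gate `i_t`,
#' candidate `Ctilde_t = tanh(W_C [h_{t-1}, x_t] + b_C)`, cell state
#' `C_t = f_t * C_{t-1} + i_t * Ctilde_t`, output gate `o_t`, hidden state
#' `h_t = o_t * tanh(C_t)`; each position then combines the forward state
#' `A_t` and backward state `A'_t` as `y_t = tanh(V A_t + V' A'_t)`.
#'
#' @param inputs Numeric matrix, one row per position (`T x d`).
#' @param params List with `W_f`, `W_i`, `W_C`, `W_o` (each
#'   `(units + d) x units`, acting on `[h, x]`), `b_f`, `b_i`, `b_C`, `b_o`
#'   (length `units`), and combination matrices `V`, `V2`
#'   (`units x out_dim`). The same parameters are used for both directions
#'   unless `W_f_bwd` etc. are supplied.
#' @return Numeric matrix `T x out_dim` of combined outputs.
#' @export
bilstm_forward <- function(inputs, params) {
  u <- ncol(params$W_f)
  d <- nrow(params$W_f) - u
  if (ncol(inputs) != d) {
    stopf("input width %d does not match parameter input dimension %d",
          ncol(inputs), d)
  }
  fuse <- function(sfx) {
    list(W = cbind(params[[paste0("W_f", sfx)]], params[[paste0("W_i", sfx)]],
                   params[[paste0("W_C", sfx)]], params[[paste0("W_o", sfx)]]),
         b = c(params[[paste0("b_f", sfx)]], params[[paste0("b_i", sfx)]],
               params[[paste0("b_C", sfx)]], params[[paste0("b_o", sfx)]]))
  }
  pf <- fuse("")
  pb <- if (!is.null(params$W_f_bwd)) fuse("_bwd") else pf
  tt <- nrow(inputs)
  X <- array(inputs, c(1L, tt, d))  # [1, t, j] = inputs[t, j]
  Af <- lstm_forward_dir(X, pf$W, pf$b, u)$H
  Ab <- rev_time(lstm_forward_dir(rev_time(X), pb$W, pb$b, u)$H)
  out <- matrix(0, tt, ncol(params$V))
  for (t in seq_len(tt)) {
    out[t, ] <- tanh(slice_t(Af, t) %*% params$V +
                       slice_t(Ab, t) %*% params$V2)
  }
  out
}
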