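# Internal neural-network primitives: 1D convolution over the atom axis,
# batched (optionally bidirectional) LSTM stacks backed by the C++ kernels,
# batch normalization, and an Adam optimizer over nested parameter lists.
# Array layouts follow the kernels: sequences are (features, batch, time),
# voxel stacks are (n_voxels, channels, batch).

# ---- conv1d (same padding, linear) ------------------------------------------

# X: (T, C_in, B) array; W: (k, C_in, C_out); returns (T, C_out, B)
conv1d_forward <- function(X, W, b) {
  dims <- dim(X)
  T_ <- dims[1]; B <- dims[3]
  k <- dim(W)[1]
  C_out <- dim(W)[3]
  pad <- (k - 1L) %/% 2L
  Xf <- matrix(aperm(X, c(1, 3, 2)), T_ * B, dims[2])
  Yf <- matrix(rep(b, each = T_ * B), T_ * B, C_out)
  for (d in seq_len(k)) {
    off <- d - pad - 1L
    src <- seq_len(T_) + off
    ok <- src >= 1 & src <= T_
    if (!any(ok)) next
    rows_dst <- which(ok)
    rows_src <- src[ok]
    # per-sample row offsets in the flattened layout
    idx_dst <- as.vector(outer(rows_dst, (seq_len(B) - 1L) * T_, "+"))
    idx_src <- as.vector(outer(rows_src, (seq_len(B) - 1L) * T_, "+"))
    Yf[idx_dst, ] <- Yf[idx_dst, ] + Xf[idx_src, , drop = FALSE] %*% W[d, , ]
  }
  aperm(array(Yf, c(T_, B, C_out)), c(1, 3, 2))
}

conv1d_backward <- function(X, W, dY) {
  dims <- dim(X)
  T_ <- dims[1]; B <- dims[3]
  k <- dim(W)[1]
  pad <- (k - 1L) %/% 2L
  Xf <- matrix(aperm(X, c(1, 3, 2)), T_ * B, dims[2])
  dYf <- matrix(aperm(dY, c(1, 3, 2)), T_ * B, dim(W)[3])
  dW <- array(0, dim(W))
  dXf <- matrix(0, T_ * B, dims[2])
  for (d in seq_len(k)) {
    off <- d - pad - 1L
    src <- seq_len(T_) + off
    ok <- src >= 1 & src <= T_
    if (!any(ok)) next
    idx_dst <- as.vector(outer(which(ok), (seq_len(B) - 1L) * T_, "+"))
    idx_src <- as.vector(outer(src[ok], (seq_len(B) - 1L) * T_, "+"))
    dW[d, , ] <- crossprod(Xf[idx_src, , drop = FALSE],
                           dYf[idx_dst, , drop = FALSE])
    dXf[idx_src, ] <- dXf[idx_src, ] +
      dYf[idx_dst, , drop = FALSE] %*% t(W[d, , ])
  }
  list(dX = aperm(array(dXf, c(T_, B, dims[2])), c(1, 3, 2)),
       dW = dW, db = colSums(dYf))
}

# ---- LSTM stack --------------------------------------------------------------

init_lstm_dir <- function(n_in, h, scale = 0.08) {
  W <- matrix(runif(4 * h * n_in, -scale, scale), 4 * h, n_in)
  U <- matrix(runif(4 * h * h, -scale, scale), 4 * h, h)
  b <- numeric(4 * h)
  b[(h + 1):(2 * h)] <- 1  # forget-gate bias
  list(W = W, U = U, b = b)
}

# one (optionally bidirectional) LSTM layer; X is (n_in, B, T)
lstm_layer_forward <- function(X, par, bidirectional) {
  fw <- cpp_lstm_forward(X, par$f$W, par$f$U, par$f$b, FALSE)
  if (bidirectional) {
    bw <- cpp_lstm_backward_dirforward(X, par)
    H <- abind_rows(fw$H, bw$H)
    list(H = H, fw = fw, bw = bw)
  } else {
    list(H = fw$H, fw = fw, bw = NULL)
  }
}

cpp_lstm_backward_dirforward <- function(X, par) {
  cpp_lstm_forward(X, par$b$W, par$b$U, par$b$b, TRUE)
}

abind_rows <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1] + db[1], da[2], da[3]))
  out[seq_len(da[1]), , ] <- a
  out[da[1] + seq_len(db[1]), , ] <- b
  out
}

lstm_layer_backward <- function(X, par, cache, dH, bidirectional) {
  h <- ncol(par$f$U)
  if (bidirectional) {
    g_f <- cpp_lstm_backward(X, par$f$W, par$f$U, cache$fw$G, cache$fw$C,
                             cache$fw$H, dH[seq_len(h), , , drop = FALSE],
                             FALSE)
    g_b <- cpp_lstm_backward(X, par$b$W, par$b$U, cache$bw$G, cache$bw$C,
                             cache$bw$H, dH[h + seq_len(h), , , drop = FALSE],
                             TRUE)
    list(dX = g_f$dX + g_b$dX,
         grads = list(f = list(W = g_f$dW, U = g_f$dU, b = as.vector(g_f$db)),
                      b = list(W = g_b$dW, U = g_b$dU, b = as.vector(g_b$db))))
  } else {
    g_f <- cpp_lstm_backward(X, par$f$W, par$f$U, cache$fw$G, cache$fw$C,
                             cache$fw$H, dH, FALSE)
    list(dX = g_f$dX,
         grads = list(f = list(W = g_f$dW, U = g_f$dU, b = as.vector(g_f$db))))
  }
}

init_lstm_branch <- function(n_in, h, bidirectional, n_out = 3L) {
  dirs <- if (bidirectional) 2L else 1L
  branch <- list(
    l1 = list(f = init_lstm_dir(n_in, h)),
    l2 = list(f = init_lstm_dir(h * dirs, h)),
    head = list(W = matrix(0, n_out, h * dirs), b = numeric(n_out))
  )
  if (bidirectional) {
    branch$l1$b <- init_lstm_dir(n_in, h)
    branch$l2$b <- init_lstm_dir(h * dirs, h)
  }
  branch
}

# two-layer LSTM + linear head emitting one n_out vector per time step;
# X: (n_in, B, T) -> delta (n_out, B, T)
branch_forward <- function(X, par, bidirectional) {
  c1 <- lstm_layer_forward(X, par$l1, bidirectional)
  c2 <- lstm_layer_forward(c1$H, par$l2, bidirectional)
  dims <- dim(c2$H)
  Hf <- matrix(c2$H, dims[1], dims[2] * dims[3])
  delta <- array(par$head$W %*% Hf + par$head$b, c(nrow(par$head$W),
                                                   dims[2], dims[3]))
  list(delta = delta, c1 = c1, c2 = c2, X = X)
}

branch_backward <- function(cache, par, dDelta, bidirectional) {
  dims <- dim(cache$c2$H)
  dDf <- matrix(dDelta, dim(dDelta)[1], dims[2] * dims[3])
  Hf <- matrix(cache$c2$H, dims[1], dims[2] * dims[3])
  dW_head <- dDf %*% t(Hf)
  db_head <- rowSums(dDf)
  dH2 <- array(t(par$head$W) %*% dDf, dims)
  g2 <- lstm_layer_backward(cache$c1$H, par$l2, cache$c2, dH2, bidirectional)
  g1 <- lstm_layer_backward(cache$X, par$l1, cache$c1, g2$dX, bidirectional)
  list(dX = g1$dX,
       grads = list(l1 = g1$grads, l2 = g2$grads,
                    head = list(W = dW_head, b = db_head)))
}

# project a displacement field D (n x 3) onto the orthogonal complement of
# the rigid subspace generated by the configuration P (n x 3): global
# translations and infinitesimal rotations about P's centroid. Both steps
# are orthogonal projectors, so the map is linear and self-adjoint.
project_out_rigid <- function(D, P) {
  n <- nrow(D)
  D <- sweep(D, 2, colMeans(D))
  r <- sweep(P, 2, colMeans(P))
  A <- sum(r^2) * diag(3) - crossprod(r)
  if (n >= 3 && abs(det(A)) > 1e-8) {
    b <- c(sum(r[, 2] * D[, 3] - r[, 3] * D[, 2]),
           sum(r[, 3] * D[, 1] - r[, 1] * D[, 3]),
           sum(r[, 1] * D[, 2] - r[, 2] * D[, 1]))
    w <- solve(A, b)
    D <- D - cbind(w[2] * r[, 3] - w[3] * r[, 2],
                   w[3] * r[, 1] - w[1] * r[, 3],
                   w[1] * r[, 2] - w[2] * r[, 1])
  }
  D
}

# ---- batch norm --------------------------------------------------------------

bn_init <- function(C) {
  list(gamma = rep(1, C), beta = rep(0, C),
       run_mean = rep(0, C), run_var = rep(1, C))
}

# X: (n, C, B) cube flattened over (n, B) per channel
bn_forward <- function(X, par, training, momentum = 0.9, eps = 1e-5) {
  d <- dim(X)
  Xm <- matrix(aperm(X, c(1, 3, 2)), d[1] * d[3], d[2])
  if (training) {
    mu <- colMeans(Xm)
    v <- colMeans(Xm^2) - mu^2
    par$run_mean <- momentum * par$run_mean + (1 - momentum) * mu
    par$run_var <- momentum * par$run_var + (1 - momentum) * v
  } else {
    mu <- par$run_mean
    v <- par$run_var
  }
  istd <- 1 / sqrt(v + eps)
  Xhat <- sweep(Xm, 2, mu) %*% diag(istd, length(istd))
  Y <- sweep(Xhat %*% diag(par$gamma, length(istd)), 2, par$beta, "+")
  list(Y = aperm(array(Y, c(d[1], d[3], d[2])), c(1, 3, 2)),
       Xhat = Xhat, istd = istd, par = par, dims = d)
}

bn_backward <- function(cache, par, dY) {
  d <- cache$dims
  dYm <- matrix(aperm(dY, c(1, 3, 2)), d[1] * d[3], d[2])
  n <- nrow(dYm)
  dgamma <- colSums(dYm * cache$Xhat)
  dbeta <- colSums(dYm)
  dXhat <- dYm %*% diag(par$gamma, d[2])
  dXm <- (dXhat - matrix(dbeta / n * par$gamma, n, d[2], byrow = TRUE) -
            cache$Xhat * matrix(dgamma / n * par$gamma, n, d[2], byrow = TRUE)) %*%
    diag(cache$istd, d[2])
  list(dX = aperm(array(dXm, c(d[1], d[3], d[2])), c(1, 3, 2)),
       dgamma = dgamma, dbeta = dbeta)
}

# ---- Adam over nested parameter lists ---------------------------------------

zero_like <- function(p) {
  if (is.list(p)) lapply(p, zero_like) else p * 0
}

adam_init <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_apply <- function(p, g, m, v, lr, t, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  if (is.list(p)) {
    out_p <- p; out_m <- m; out_v <- v
    for (nm in names(p)) {
      if (is.null(g[[nm]])) next
      r <- adam_apply(p[[nm]], g[[nm]], m[[nm]], v[[nm]], lr, t, beta1, beta2,
                      eps)
      out_p[[nm]] <- r$p; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
    }
    list(p = out_p, m = out_m, v = out_v)
  } else {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
}

adam_step <- function(params, grads, state, lr) {
  state$t <- state$t + 1L
  r <- adam_apply(params, grads, state$m, state$v, lr, state$t)
  list(params = r$p, state = list(m = r$m, v = r$v, t = state$t))
}

grad_global_norm <- function(g) {
  if (is.list(g)) sqrt(sum(vapply(g, function(x) grad_global_norm(x)^2, 0)))
  else sqrt(sum(g^2))
}

grad_scale <- function(g, s) {
  if (is.list(g)) lapply(g, grad_scale, s = s) else g * s
}

grad_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a)) {
    out <- a
    for (nm in names(a)) out[[nm]] <- grad_add(a[[nm]], b[[nm]])
    out
  } else a + b
}
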