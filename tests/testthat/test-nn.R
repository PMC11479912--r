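# central-difference checks of the hand-written layer gradients; these
# guard every training result in the package

numeric_grad <- function(f, x, ii, eps = 1e-6) {
  x1 <- x; x1[ii] <- x1[ii] + eps
  x0 <- x; x0[ii] <- x0[ii] - eps
  (f(x1) - f(x0)) / (2 * eps)
}

test_that("LSTM forward/backward gradients match central differences", {
  set.seed(1)
  h <- 4; nin <- 3; B <- 2; T <- 5
  par <- tcrcost:::init_lstm_dir(nin, h, scale = 0.3)
  X <- array(rnorm(nin * B * T), c(nin, B, T))
  Rw <- array(rnorm(h * B * T), c(h, B, T))
  for (rev in c(FALSE, TRUE)) {
    fw <- tcrcost:::cpp_lstm_forward(X, par$W, par$U, par$b, rev)
    g <- tcrcost:::cpp_lstm_backward(X, par$W, par$U, fw$G, fw$C, fw$H, Rw,
                                     rev)
    loss_x <- function(Xp) {
      sum(tcrcost:::cpp_lstm_forward(Xp, par$W, par$U, par$b, rev)$H * Rw)
    }
    loss_w <- function(Wp) {
      sum(tcrcost:::cpp_lstm_forward(X, Wp, par$U, par$b, rev)$H * Rw)
    }
    loss_u <- function(Up) {
      sum(tcrcost:::cpp_lstm_forward(X, par$W, Up, par$b, rev)$H * Rw)
    }
    for (r in 1:5) {
      ii <- sample(length(X), 1)
      expect_equal(g$dX[ii], numeric_grad(loss_x, X, ii), tolerance = 1e-5)
      jj <- sample(length(par$W), 1)
      expect_equal(g$dW[jj], numeric_grad(loss_w, par$W, jj), tolerance = 1e-5)
      kk <- sample(length(par$U), 1)
      expect_equal(g$dU[kk], numeric_grad(loss_u, par$U, kk), tolerance = 1e-5)
    }
  }
})

test_that("atom-axis convolution gradients match central differences", {
  set.seed(2)
  W <- array(rnorm(5 * 3 * 3) * 0.3, c(5, 3, 3))
  b <- rnorm(3) * 0.1
  X <- array(rnorm(10 * 3 * 2), c(10, 3, 2))
  Rw <- array(rnorm(10 * 3 * 2), c(10, 3, 2))
  g <- tcrcost:::conv1d_backward(X, W, Rw)
  loss_x <- function(Xp) sum(tcrcost:::conv1d_forward(Xp, W, b) * Rw)
  loss_w <- function(Wp) sum(tcrcost:::conv1d_forward(X, Wp, b) * Rw)
  for (r in 1:6) {
    ii <- sample(length(X), 1)
    expect_equal(g$dX[ii], numeric_grad(loss_x, X, ii), tolerance = 1e-5)
    jj <- sample(length(W), 1)
    expect_equal(g$dW[jj], numeric_grad(loss_w, W, jj), tolerance = 1e-5)
  }
})

test_that("3D convolution gradients match central differences", {
  set.seed(3)
  for (stride in c(1L, 2L)) {
    D <- 4L; Cin <- 2L; Cout <- 3L; B <- 2L
    X <- array(rnorm(D^3 * Cin * B), c(D^3, Cin, B))
    W <- matrix(rnorm(27 * Cin * Cout) * 0.3, 27 * Cin, Cout)
    b <- rnorm(Cout) * 0.1
    Y <- tcrcost:::cpp_conv3d_forward(X, W, b, D, stride)
    Rw <- array(rnorm(length(Y)), dim(Y))
    g <- tcrcost:::cpp_conv3d_backward(X, W, Rw, D, stride)
    loss_x <- function(Xp) {
      sum(tcrcost:::cpp_conv3d_forward(Xp, W, b, D, stride) * Rw)
    }
    loss_w <- function(Wp) {
      sum(tcrcost:::cpp_conv3d_forward(X, Wp, b, D, stride) * Rw)
    }
    for (r in 1:6) {
      ii <- sample(length(X), 1)
      expect_equal(g$dX[ii], numeric_grad(loss_x, X, ii), tolerance = 1e-5)
      jj <- sample(length(W), 1)
      expect_equal(g$dW[jj], numeric_grad(loss_w, W, jj), tolerance = 1e-5)
    }
  }
})

test_that("whole binding network gradients match central differences", {
  set.seed(4)
  cfg <- binding_config(channels = c(8, 4, 6, 6, 8), strides = c(2, 1, 1, 2),
                        fc_hidden = 5, grid_size = 8, input_pool = 1, seed = 2)
  model <- init_binding_model(cfg)
  B <- 3
  X <- array(rnorm(8^3 * 8 * B), c(8^3, 8, B))
  y <- c(1, 0, 1)
  loss_of <- function(m) {
    out <- tcrcost:::binding_forward(m, X, cfg, training = TRUE,
                                     want_cache = TRUE)
    p <- pmin(pmax(out$prob, 1e-12), 1 - 1e-12)
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }
  out <- tcrcost:::binding_forward(model, X, cfg, training = TRUE,
                                   want_cache = TRUE)
  gr <- tcrcost:::binding_backward(model, out, cfg, (out$prob - y) / B)
  setrec <- function(m, pth, ii, d) {
    if (length(pth) == 1) { m[[pth]][ii] <- m[[pth]][ii] + d; m }
    else { m[[pth[1]]] <- setrec(m[[pth[1]]], pth[-1], ii, d); m }
  }
  paths <- list(c("conv1", "W"), c("conv3", "W"), c("bn2", "gamma"),
                c("proj", "W"), c("fc1", "W"), c("fc2", "b"))
  eps <- 1e-5
  for (pth in paths) {
    ga <- gr
    for (k in pth) ga <- ga[[k]]
    ii <- sample(length(ga), 1)
    num <- (loss_of(setrec(model, pth, ii, eps)) -
              loss_of(setrec(model, pth, ii, -eps))) / (2 * eps)
    expect_equal(ga[ii], num, tolerance = 1e-4)
  }
})

test_that("correction network parameter gradients match central differences", {
  scfg <- synth_config(n_complexes = 2, cdr3a_len = 11, cdr3b_len = 11,
                       peptide_len = 8, seed = 11)
  pairs <- make_correction_pairs(scfg, n = 2)
  # full backpropagation so the analytic gradient matches the total loss
  cfg <- correction_config(lstm_hidden = 5, seed = 3,
                           staged_gradients = FALSE)
  set.seed(5)
  rand_fill <- function(p, sc = 0.05) {
    if (is.list(p)) lapply(p, rand_fill, sc = sc)
    else p + rnorm(length(p)) * sc
  }
  model <- rand_fill(init_correction_model(cfg))
  prep <- lapply(1:2, function(i) {
    al <- align_atom_order(pairs$precise[[i]], pairs$predicted[[i]])
    list(x = pad_truncate(al$predicted)$coords,
         meta = tcrcost:::sample_meta(al$predicted, cfg),
         refs = tcrcost:::sample_refs(al$precise, cfg))
  })
  X <- array(0, c(400, 3, 2))
  for (j in 1:2) X[, , j] <- prep[[j]]$x
  meta <- lapply(prep, `[[`, "meta")
  refs <- lapply(prep, `[[`, "refs")
  total_loss <- function(m) {
    o <- tcrcost:::forward_correction(m, X, meta, cfg)
    tcrcost:::correction_losses(o, meta, refs, cfg, grad = FALSE)$total
  }
  o <- tcrcost:::forward_correction(model, X, meta, cfg, want_cache = TRUE)
  ls <- tcrcost:::correction_losses(o, meta, refs, cfg, grad = TRUE)
  gr <- tcrcost:::backward_correction(model, o, meta, cfg, ls$Gm, ls$Gs,
                                      ls$Ga)
  setrec <- function(m, pth, ii, d) {
    if (length(pth) == 1) { m[[pth]][ii] <- m[[pth]][ii] + d; m }
    else { m[[pth[1]]] <- setrec(m[[pth[1]]], pth[-1], ii, d); m }
  }
  paths <- list(c("conv", "W"), c("main", "l1", "f", "W"),
                c("side", "head", "W"), c("all", "l2", "b", "U"))
  eps <- 1e-6
  for (pth in paths) {
    ga <- gr
    for (k in pth) ga <- ga[[k]]
    ii <- sample(length(ga), 1)
    num <- (total_loss(setrec(model, pth, ii, eps)) -
              total_loss(setrec(model, pth, ii, -eps))) / (2 * eps)
    expect_equal(ga[ii], num, tolerance = 1e-4)
  }
})

test_that("batch normalization backward matches central differences", {
  set.seed(6)
  par <- tcrcost:::bn_init(3)
  par$gamma <- runif(3, 0.5, 1.5)
  par$beta <- rnorm(3)
  X <- array(rnorm(10 * 3 * 4), c(10, 3, 4))
  Rw <- array(rnorm(10 * 3 * 4), c(10, 3, 4))
  fw <- tcrcost:::bn_forward(X, par, training = TRUE)
  g <- tcrcost:::bn_backward(fw, par, Rw)
  loss_x <- function(Xp) {
    sum(tcrcost:::bn_forward(Xp, par, training = TRUE)$Y * Rw)
  }
  for (r in 1:6) {
    ii <- sample(length(X), 1)
    expect_equal(g$dX[ii], numeric_grad(loss_x, X, ii, eps = 1e-5),
                 tolerance = 1e-4)
  }
})
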