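#' Configuration of the binding classifier
#'
#' A residual 3D convolutional network over the feature voxel grid: four
#' 3x3x3 convolution layers, each followed by batch normalization and ReLU,
#' with one residual block spanning layers 2-3 (the block input is added to
#' the third layer's output before its ReLU; a 1x1x1 projection is used
#' when the channel counts differ), then a two-layer fully connected head
#' ending in a sigmoid binding probability. Channels are z-score-normalized
#' with training-set statistics stored in the checkpoint.
#'
#' @param channels Channel schedule `c(in, c1, c2, c3, c4)`.
#' @param strides Per-layer strides; layers 2 and 3 (the residual block)
#'   must have stride 1.
#' @param fc_hidden Hidden units of the fully connected head.
#' @param input_pool Integer average-pooling factor applied to the grid
#'   before the first convolution (1 = none).
#' @param epochs,learning_rate,batch_size Training schedule (Adam, binary
#'   cross-entropy).
#' @param threshold Decision threshold on the predicted probability.
#' @param grid_size Expected voxel grid edge (default 48).
#' @param seed Integer seed.
#' @return A list of class `binding_config`.
#' @export
binding_config <- function(channels = c(8, 32, 64, 128, 128),
                           strides = c(2, 1, 1, 2), fc_hidden = 64L,
                           input_pool = 1L, epochs = 20L,
                           learning_rate = 1e-3, batch_size = 16L,
                           threshold = 0.5, grid_size = 48L, seed = 1L) {
  if (length(channels) != 5) {
    abort("channels must be c(in, c1, c2, c3, c4)", class = "tcrcost_bad_config")
  }
  if (length(strides) != 4 || strides[2] != 1 || strides[3] != 1) {
    abort("strides must have length 4 with stride 1 inside the residual block",
          class = "tcrcost_bad_config")
  }
  structure(list(channels = as.integer(channels), conv_layers = 4L,
                 residual_blocks = 1L, strides = as.integer(strides),
                 fc_hidden = as.integer(fc_hidden),
                 input_pool = as.integer(input_pool),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), threshold = threshold,
                 grid_size = as.integer(grid_size), seed = as.integer(seed)),
            class = "binding_config")
}

binding_dims <- function(cfg) {
  D0 <- cfg$grid_size %/% cfg$input_pool
  D <- D0
  dims <- integer(4)
  for (l in 1:4) {
    D <- (D + 2 - 3) %/% cfg$strides[l] + 1
    dims[l] <- D
  }
  list(D0 = D0, dims = dims)
}

#' Initialize an untrained binding model
#'
#' @param cfg A [binding_config()].
#' @param zero Start all weights at zero (useful to verify that the empty
#'   model outputs probability 0.5)?
#' @return A nested parameter list of class `binding_model`.
#' @export
init_binding_model <- function(cfg, zero = FALSE) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  ch <- cfg$channels
  he <- function(nin, nout) {
    if (zero) matrix(0, nin, nout)
    else matrix(rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
  }
  model <- list()
  for (l in 1:4) {
    model[[paste0("conv", l)]] <- list(W = he(27 * ch[l], ch[l + 1]),
                                       b = numeric(ch[l + 1]))
    model[[paste0("bn", l)]] <- bn_init(ch[l + 1])
  }
  if (ch[2] != ch[4]) {
    model$proj <- list(W = he(ch[2], ch[4]))
  }
  dd <- binding_dims(cfg)
  n_flat <- dd$dims[4]^3 * ch[5]
  model$fc1 <- list(W = he(n_flat, cfg$fc_hidden), b = numeric(cfg$fc_hidden))
  model$fc2 <- list(W = he(cfg$fc_hidden, 1L), b = numeric(1))
  structure(model, class = "binding_model")
}

# forward pass; X is (nvox, C_in, B) already pooled and normalized
binding_forward <- function(model, X, cfg, training = FALSE,
                            want_cache = FALSE) {
  dd <- binding_dims(cfg)
  cache <- list(X = X)
  H <- X
  D <- dd$D0
  for (l in 1:4) {
    conv <- model[[paste0("conv", l)]]
    Z <- cpp_conv3d_forward(H, conv$W, conv$b, D, cfg$strides[l])
    bn <- bn_forward(Z, model[[paste0("bn", l)]], training)
    A <- bn$Y
    if (l == 3) {
      skip_in <- cache$H1
      if (!is.null(model$proj)) {
        sk <- apply_proj(skip_in, model$proj$W)
      } else {
        sk <- skip_in
      }
      A <- A + sk
      cache$skip <- sk
    }
    R <- pmax(A, 0)
    if (want_cache) {
      cache[[paste0("in", l)]] <- H
      cache[[paste0("z", l)]] <- Z
      cache[[paste0("bncache", l)]] <- bn
      cache[[paste0("pre", l)]] <- A
      cache[[paste0("act", l)]] <- R
    }
    if (l == 1) cache$H1 <- R
    H <- R
    D <- dd$dims[l]
  }
  B <- dim(H)[3]
  n_flat <- prod(dim(H)[1:2])
  Hf <- matrix(H, n_flat, B)
  Z5 <- crossprod(model$fc1$W, Hf) + model$fc1$b
  A5 <- pmax(Z5, 0)
  logit <- as.vector(crossprod(model$fc2$W, A5) + model$fc2$b)
  prob <- 1 / (1 + exp(-logit))
  out <- list(prob = prob, logit = logit, bn_updated = list())
  if (training) {
    for (l in 1:4) out$bn_updated[[paste0("bn", l)]] <-
        if (want_cache) cache[[paste0("bncache", l)]]$par else NULL
  }
  if (want_cache) {
    cache$Hf <- Hf; cache$Z5 <- Z5; cache$A5 <- A5
    out$cache <- cache
  }
  out
}

# 1x1x1 projection: per-voxel channel mixing
apply_proj <- function(H, W) {
  d <- dim(H)
  out <- array(0, c(d[1], ncol(W), d[3]))
  for (b in seq_len(d[3])) out[, , b] <- H[, , b] %*% W
  out
}

binding_backward <- function(model, out, cfg, dlogit) {
  cache <- out$cache
  dd <- binding_dims(cfg)
  grads <- list()
  B <- length(dlogit)
  dA5 <- model$fc2$W %*% matrix(dlogit, 1, B)
  grads$fc2 <- list(W = cache$A5 %*% matrix(dlogit, B, 1),
                    b = sum(dlogit))
  dZ5 <- dA5 * (cache$Z5 > 0)
  grads$fc1 <- list(W = cache$Hf %*% t(dZ5), b = rowSums(dZ5))
  dHf <- model$fc1$W %*% dZ5
  dH <- array(dHf, dim(cache$act4))
  dskip_carry <- NULL
  for (l in 4:1) {
    dR <- dH
    if (l == 1 && !is.null(dskip_carry)) dR <- dR + dskip_carry
    dA <- dR * (cache[[paste0("pre", l)]] > 0)
    if (l == 3) {
      # split into batch-norm path and skip path
      if (!is.null(model$proj)) {
        H1 <- cache$H1
        d <- dim(H1)
        dWp <- matrix(0, nrow(model$proj$W), ncol(model$proj$W))
        dskip_carry <- array(0, d)
        for (b in seq_len(d[3])) {
          dWp <- dWp + crossprod(H1[, , b], dA[, , b])
          dskip_carry[, , b] <- dA[, , b] %*% t(model$proj$W)
        }
        grads$proj <- list(W = dWp)
      } else {
        dskip_carry <- dA
      }
    }
    bnb <- bn_backward(cache[[paste0("bncache", l)]],
                       model[[paste0("bn", l)]], dA)
    grads[[paste0("bn", l)]] <- list(gamma = bnb$dgamma, beta = bnb$dbeta)
    Din <- if (l == 1) dd$D0 else dd$dims[l - 1]
    cb <- cpp_conv3d_backward(cache[[paste0("in", l)]],
                              model[[paste0("conv", l)]]$W, bnb$dX,
                              Din, cfg$strides[l])
    grads[[paste0("conv", l)]] <- list(W = cb$dW, b = as.vector(cb$db))
    dH <- cb$dX
  }
  grads
}

#' Peptide-swap negative samples
#'
#' For each positive complex, the peptide segment is replaced by the
#' peptide of another positive (drawn uniformly among samples with a
#' different peptide identity, seeded), rigidly translated so its centroid
#' coincides with the original peptide's centroid. Exactly one negative is
#' generated per positive (1:1 class ratio) and a negative never reproduces
#' its positive's (tcr, peptide) pairing.
#'
#' @param positives A tibble with columns `structure`, `tcr_id`,
#'   `peptide_id` (labels are ignored; all rows are treated as positives).
#' @param seed Integer seed.
#' @return A tibble of the same shape with `label = 0` and swapped peptides.
#' @export
make_negatives <- function(positives, seed = 1L) {
  if (length(unique(positives$peptide_id)) < 2) {
    abort("peptide swap needs at least two distinct peptides",
          class = "tcrcost_swap_error")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  n <- nrow(positives)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ok <- which(positives$peptide_id != positives$peptide_id[i])
    donor <- if (length(ok) == 1) ok else sample(ok, 1)
    s <- positives$structure[[i]]
    d <- positives$structure[[donor]]
    pep_old <- s[s$segment == "peptide", , drop = FALSE]
    pep_new <- d[d$segment == "peptide", , drop = FALSE]
    shift <- colMeans(as.matrix(pep_old[, c("x", "y", "z")])) -
      colMeans(as.matrix(pep_new[, c("x", "y", "z")]))
    pep_new$x <- pep_new$x + shift[1]
    pep_new$y <- pep_new$y + shift[2]
    pep_new$z <- pep_new$z + shift[3]
    base <- s[s$segment != "peptide", , drop = FALSE]
    off <- max(base$residue_index) + 1L
    pep_new$residue_index <- off + match(pep_new$residue_index,
                                         unique(pep_new$residue_index)) - 1L
    swapped <- tcr_structure(dplyr::bind_rows(base, pep_new))
    rows[[i]] <- tibble(tcr_id = positives$tcr_id[i],
                        peptide_id = positives$peptide_id[donor],
                        label = 0L, structure = list(swapped))
  }
  dplyr::bind_rows(rows)
}

# build the (nvox, C, n) input stack from a sample tibble
binding_input_stack <- function(data, cfg) {
  pooled <- lapply(data$structure, function(s) {
    pool_voxel_grid(voxelize(s, grid_size = cfg$grid_size), cfg$input_pool)
  })
  nvox <- nrow(pooled[[1]])
  X <- array(0, c(nvox, length(FEATURE_NAMES), length(pooled)))
  for (i in seq_along(pooled)) X[, , i] <- pooled[[i]]
  X
}

normalize_stack <- function(X, stats) {
  for (c in seq_len(dim(X)[2])) {
    X[, c, ] <- (X[, c, ] - stats$mean[c]) / stats$sd[c]
  }
  X
}

#' Train the binding classifier
#'
#' @param data A tibble with columns `label` (0/1, both classes present)
#'   and `structure` (list of [tcr_structure()]), e.g. from
#'   [make_binding_dataset()] possibly augmented with [make_negatives()].
#' @param cfg A [binding_config()].
#' @return An object of class `tcrcost_binding` with elements `model`,
#'   `config`, `stats` (channel normalization) and `trace` (per-epoch loss
#'   and training accuracy).
#' @export
train_binding <- function(data, cfg = binding_config()) {
  y <- as.numeric(data$label)
  if (length(unique(y)) < 2) {
    abort("training data must contain both classes",
          class = "tcrcost_single_class")
  }
  X <- binding_input_stack(data, cfg)
  ch_mean <- apply(X, 2, mean)
  ch_sd <- pmax(apply(X, 2, stats::sd), 1e-8)
  stats <- list(mean = ch_mean, sd = ch_sd)
  X <- normalize_stack(X, stats)
  model <- init_binding_model(cfg)
  state <- adam_init(model)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  n <- length(y)
  trace <- vector("list", cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    splits <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    ep_loss <- 0
    correct <- 0
    for (batch in splits) {
      B <- length(batch)
      Xb <- X[, , batch, drop = FALSE]
      yb <- y[batch]
      out <- binding_forward(model, Xb, cfg, training = TRUE,
                             want_cache = TRUE)
      for (l in 1:4) {
        model[[paste0("bn", l)]] <- out$cache[[paste0("bncache", l)]]$par
      }
      p <- pmin(pmax(out$prob, 1e-12), 1 - 1e-12)
      loss <- -mean(yb * log(p) + (1 - yb) * log(1 - p))
      check_finite(loss, "binary cross-entropy")
      dlogit <- (p - yb) / B
      grads <- binding_backward(model, out, cfg, dlogit)
      st <- adam_step(model, grads, state, cfg$learning_rate)
      # keep the (non-trainable) running statistics
      for (l in 1:4) {
        st$params[[paste0("bn", l)]]$run_mean <- model[[paste0("bn", l)]]$run_mean
        st$params[[paste0("bn", l)]]$run_var <- model[[paste0("bn", l)]]$run_var
      }
      model <- st$params
      state <- st$state
      ep_loss <- ep_loss + loss * B / n
      correct <- correct + sum((out$prob >= cfg$threshold) == (yb == 1))
    }
    trace[[epoch]] <- tibble(epoch = epoch, loss = ep_loss,
                             train_acc = correct / n)
  }
  structure(list(model = model, config = cfg, stats = stats,
                 trace = dplyr::bind_rows(trace)),
            class = "tcrcost_binding")
}

#' Predict binding probabilities
#'
#' @param fit A `tcrcost_binding` object.
#' @param newdata A [tcr_structure()], a `voxel_grid`, or a tibble with a
#'   `structure` list-column.
#' @return A numeric vector of probabilities in `[0, 1]`.
#' @export
predict_binding <- function(fit, newdata) {
  cfg <- fit$config
  if (inherits(newdata, "voxel_grid")) {
    d <- dim(newdata$grid)
    if (d[1] != cfg$grid_size) {
      abort(sprintf("expected a %d^3 grid, got %d^3", cfg$grid_size, d[1]),
            class = "tcrcost_bad_grid")
    }
    pooled <- list(pool_voxel_grid(newdata, cfg$input_pool))
  } else if (inherits(newdata, "tcr_structure")) {
    pooled <- list(pool_voxel_grid(voxelize(newdata, grid_size = cfg$grid_size),
                                   cfg$input_pool))
  } else {
    pooled <- lapply(newdata$structure, function(s) {
      pool_voxel_grid(voxelize(s, grid_size = cfg$grid_size), cfg$input_pool)
    })
  }
  X <- array(0, c(nrow(pooled[[1]]), length(FEATURE_NAMES), length(pooled)))
  for (i in seq_along(pooled)) X[, , i] <- pooled[[i]]
  if (!is.null(fit$stats)) X <- normalize_stack(X, fit$stats)
  binding_forward(fit$model, X, cfg, training = FALSE)$prob
}

#' @export
tidy.tcrcost_binding <- function(x, ...) x$trace

#' @export
glance.tcrcost_binding <- function(x, ...) {
  last <- x$trace[nrow(x$trace), ]
  tibble(epochs = nrow(x$trace), final_loss = last$loss,
         final_train_acc = last$train_acc,
         channels = paste(x$config$channels, collapse = "-"))
}

#' @export
print.tcrcost_binding <- function(x, ...) {
  cat(sprintf("<tcrcost_binding: channels %s, %d epochs, final loss %.4f, train acc %.3f>\n",
              paste(x$config$channels, collapse = "-"), nrow(x$trace),
              x$trace$loss[nrow(x$trace)], x$trace$train_acc[nrow(x$trace)]))
  invisible(x)
}

#' @export
autoplot.tcrcost_binding <- function(object, ...) {
  df <- tidyr::pivot_longer(object$trace, -"epoch", names_to = "metric",
                            values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, title = "Binding training trace") +
    ggplot2::theme_minimal()
}
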