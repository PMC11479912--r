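#' Configuration of the structure-correction network
#'
#' The correction model applies a shared 1D convolution along the atom axis
#' (3 coordinate channels, residual), splits atoms into main and side chains,
#' corrects each chain with a two-layer (optionally bidirectional) LSTM whose
#' hidden state is projected to a per-atom 3-vector displacement, recombines
#' the chains into the original atom order and applies a final two-layer
#' LSTM over the whole structure. All correctors are additive-residual:
#' corrected coordinates are the input coordinates plus a predicted
#' displacement, so a zero-weight model is the identity.
#'
#' @param conv_kernel Odd kernel width of the atom-axis convolution.
#' @param lstm_hidden Hidden units per LSTM direction.
#' @param variant Architecture variant: `"TCRCOST"` (both chain correctors),
#'   `"LSTM_MAIN"` (main-chain corrector only), `"LSTM_SIDE"` (side-chain
#'   corrector only) or `"LSTM_ALL"` (whole-structure corrector only).
#' @param loss_mode `"TCRCOST"` uses the geometric losses implied by the
#'   variant (frame-aligned point error for the main chain, the
#'   distance-difference loss for the side chain, and the whole-structure
#'   loss); `"MSE"` replaces them with mean squared coordinate error;
#'   `"L_MAIN_ONLY"` / `"L_SIDE_ONLY"` train on a single geometric term.
#' @param epochs,learning_rate,batch_size Training schedule (Adam).
#' @param lr_decay `"cosine"` anneals the learning rate from its initial
#'   value to 1/100 of it over the epochs; `"constant"` disables decay.
#'   Annealing damps the end-of-training oscillation of the L1 geometry
#'   terms, whose gradients do not shrink near the optimum.
#' @param bidirectional Process atoms in both directions (default `TRUE`)?
#' @param residual Additive-residual output head (default) or absolute
#'   coordinates?
#' @param clamp Optional clamp (Angstrom) on frame-aligned deviations.
#' @param angle_unit Unit of the bond-angle penalty inside the
#'   whole-structure loss; the default `"radians"` keeps the angle term on
#'   the same numeric scale as the frame-aligned and bond-length terms
#'   (degrees are available but let the angle term dominate the gradient).
#' @param input_scale Coordinate scale (Angstrom) used to normalize the
#'   network's input: the recurrent correctors see centred coordinates
#'   divided by this value and their displacement outputs are multiplied
#'   by it, keeping gate pre-activations in their sensitive range.
#' @param loss_smooth_eps Numerical smoothing (Angstrom / radians) of the
#'   absolute-value and norm kinks in the training losses:
#'   `|x| -> sqrt(x^2 + eps^2)`. The loss value changes by at most `eps`
#'   per term, but the gradients decay as residuals vanish instead of
#'   oscillating at the optimizer's step-size floor. Set to 0 for the
#'   exact (kinked) losses.
#' @param staged_gradients When `TRUE` (default) the whole-structure loss
#'   trains only the final corrector: its gradient is stopped at the
#'   recombined coordinates instead of flowing back into the chain
#'   branches, which are trained by their own losses. This mirrors the
#'   staged design — chains are pre-corrected first, then the assembled
#'   structure is adjusted — and avoids the whole-structure term swamping
#'   the chain objectives on shared weights. `FALSE` backpropagates
#'   everything everywhere.
#' @param term_weights Named weights for the active loss terms.
#' @param max_atoms,main_capacity Padded input length and main-chain slots.
#' @param seed Integer seed controlling initialization and batching.
#'
#' @return A list of class `correction_config`.
#' @export
correction_config <- function(conv_kernel = 5L, lstm_hidden = 128L,
                              variant = c("TCRCOST", "LSTM_MAIN", "LSTM_SIDE",
                                          "LSTM_ALL"),
                              loss_mode = c("TCRCOST", "MSE", "L_MAIN_ONLY",
                                            "L_SIDE_ONLY"),
                              epochs = 60L, learning_rate = 1e-3,
                              lr_decay = c("cosine", "constant"),
                              batch_size = 16L, bidirectional = TRUE,
                              residual = TRUE, clamp = Inf,
                              angle_unit = c("radians", "degrees"),
                              input_scale = 10, loss_smooth_eps = 0.01,
                              staged_gradients = TRUE,
                              term_weights = c(l_main = 1, l_side = 1,
                                               l_all = 1, mse = 1),
                              max_atoms = 400L, main_capacity = 150L,
                              seed = 1L) {
  variant <- match.arg(variant)
  loss_mode <- match.arg(loss_mode)
  angle_unit <- match.arg(angle_unit)
  lr_decay <- match.arg(lr_decay)
  if (conv_kernel %% 2L != 1L) {
    abort("conv_kernel must be odd", class = "tcrcost_bad_config")
  }
  structure(list(conv_kernel = as.integer(conv_kernel),
                 lstm_hidden = as.integer(lstm_hidden),
                 lstm_layers = 2L, variant = variant, loss_mode = loss_mode,
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 lr_decay = lr_decay,
                 batch_size = as.integer(batch_size),
                 bidirectional = isTRUE(bidirectional),
                 residual = isTRUE(residual), clamp = clamp,
                 angle_unit = angle_unit, input_scale = input_scale,
                 loss_smooth_eps = loss_smooth_eps,
                 staged_gradients = isTRUE(staged_gradients),
                 term_weights = term_weights,
                 max_atoms = as.integer(max_atoms),
                 main_capacity = as.integer(main_capacity),
                 seed = as.integer(seed)),
            class = "correction_config")
}

uses_main_branch <- function(cfg) cfg$variant %in% c("TCRCOST", "LSTM_MAIN")
uses_side_branch <- function(cfg) cfg$variant %in% c("TCRCOST", "LSTM_SIDE")

active_terms <- function(cfg) {
  switch(cfg$loss_mode,
         MSE = "mse",
         L_MAIN_ONLY = "l_main",
         L_SIDE_ONLY = "l_side",
         TCRCOST = switch(cfg$variant,
                          TCRCOST = c("l_main", "l_side", "l_all"),
                          LSTM_MAIN = c("l_main", "l_all"),
                          LSTM_SIDE = c("l_side", "l_all"),
                          LSTM_ALL = "l_all"))
}

#' Initialize an untrained correction model
#'
#' LSTM weights are drawn uniformly in a small range (forget-gate bias 1);
#' the convolution and all output heads start at zero, so the untrained
#' model is exactly the identity on the input coordinates.
#'
#' @param cfg A [correction_config()].
#' @return A nested parameter list of class `correction_model`.
#' @export
init_correction_model <- function(cfg) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  h <- cfg$lstm_hidden
  model <- list(conv = list(W = array(0, c(cfg$conv_kernel, 3, 3)),
                            b = numeric(3)))
  if (uses_main_branch(cfg)) {
    model$main <- init_lstm_branch(3L, h, cfg$bidirectional)
  }
  if (uses_side_branch(cfg)) {
    model$side <- init_lstm_branch(3L, h, cfg$bidirectional)
  }
  model$all <- init_lstm_branch(3L, h, cfg$bidirectional)
  structure(model, class = "correction_model")
}

# per-sample metadata shared by forward/backward/losses
sample_meta <- function(s, cfg) {
  s <- canonicalize_structure(s)
  idx <- mask_indices(s)
  main_names <- s$atom_name[idx$main]
  all_names <- s$atom_name
  list(n = nrow(s),
       main_idx = idx$main, side_idx = idx$side,
       n_main = length(idx$main), n_side = length(idx$side),
       m_iN = which(main_names == "N"), m_iCA = which(main_names == "CA"),
       m_iC = which(main_names == "C"),
       a_iN = which(all_names == "N"), a_iCA = which(all_names == "CA"),
       a_iC = which(all_names == "C"))
}

# forward pass over a batch; X is (max_atoms, 3, B), meta a list of
# sample_meta() entries. The network sees centred coordinates on a fixed
# 1/input_scale scale (gates stay in their sensitive range); displacements
# are scaled back to Angstrom before the residual addition, so outputs
# remain in the original frame.
forward_correction <- function(model, X, meta, cfg, want_cache = FALSE) {
  A <- cfg$max_atoms
  Mcap <- cfg$main_capacity
  sc <- cfg$input_scale
  B <- dim(X)[3]
  Xn <- X
  ctr <- matrix(0, B, 3)
  for (b in seq_len(B)) {
    n <- meta[[b]]$n
    ctr[b, ] <- colMeans(X[seq_len(n), , b, drop = FALSE][, , 1, drop = TRUE])
    Xn[seq_len(n), , b] <- (X[seq_len(n), , b] -
                              matrix(ctr[b, ], n, 3, byrow = TRUE)) / sc
    if (n < A) Xn[(n + 1):A, , b] <- 0
  }
  conv_out <- conv1d_forward(Xn, model$conv$W, model$conv$b)
  Cctx <- Xn + conv_out
  for (b in seq_len(B)) {
    n <- meta[[b]]$n
    if (n < A) Cctx[(n + 1):A, , b] <- 0
  }
  # recurrent branches only run up to the longest real sequence in the
  # batch; trailing padded slots stay zero in the outputs
  Lm <- max(vapply(meta, function(m) m$n_main, 0L), 1L)
  Ls <- max(vapply(meta, function(m) m$n_side, 0L), 1L)
  La <- max(vapply(meta, function(m) m$n, 0L), 1L)
  gather <- function(src, which_idx, cap) {
    out <- array(0, c(3, B, cap))
    for (b in seq_len(B)) {
      ii <- meta[[b]][[which_idx]]
      if (length(ii) > 0) out[, b, seq_along(ii)] <- t(src[ii, , b])
    }
    out
  }
  Xm_ctx <- gather(Cctx, "main_idx", Lm)
  Xs_ctx <- gather(Cctx, "side_idx", Ls)
  Xm_orig <- gather(X, "main_idx", Lm)
  Xs_orig <- gather(X, "side_idx", Ls)
  to_mat <- function(arr, cap) {
    T_ <- dim(arr)[3]
    out <- array(0, c(cap, 3, B))
    for (b in seq_len(B)) out[seq_len(T_), , b] <- t(arr[, b, ])
    out
  }
  # Displacement fields are projected onto the orthogonal complement of the
  # rigid subspace (translations plus infinitesimal rotations about the
  # input configuration). The training losses are rigid-invariant, so these
  # six directions are flat and the branches would otherwise drift apart
  # rigidly; the projector is built from the (constant) input coordinates,
  # so it is linear, self-adjoint and shared by the backward pass.
  center_delta <- function(delta, orig, len_field) {
    for (b in seq_len(B)) {
      n <- meta[[b]][[len_field]]
      if (n > 1) {
        delta[, b, seq_len(n)] <-
          t(project_out_rigid(t(delta[, b, seq_len(n)]),
                              t(orig[, b, seq_len(n)])))
      }
    }
    delta
  }
  bm <- bs <- NULL
  if (uses_main_branch(cfg)) {
    bm <- branch_forward(Xm_ctx, model$main, cfg$bidirectional)
    bm$delta_c <- center_delta(bm$delta, Xm_orig, "n_main")
    Dm <- if (cfg$residual) Xm_orig + sc * bm$delta_c else sc * bm$delta_c
  } else {
    Dm <- Xm_orig
  }
  if (uses_side_branch(cfg)) {
    bs <- branch_forward(Xs_ctx, model$side, cfg$bidirectional)
    bs$delta_c <- center_delta(bs$delta, Xs_orig, "n_side")
    Ds <- if (cfg$residual) Xs_orig + sc * bs$delta_c else sc * bs$delta_c
  } else {
    Ds <- Xs_orig
  }
  O_main <- to_mat(Dm, Mcap)
  O_side <- to_mat(Ds, A)
  for (b in seq_len(B)) {
    nm <- meta[[b]]$n_main; ns <- meta[[b]]$n_side
    if (nm < Mcap) O_main[(nm + 1):Mcap, , b] <- 0
    if (ns < A) O_side[(ns + 1):A, , b] <- 0
  }
  R_all <- array(0, c(A, 3, B))
  for (b in seq_len(B)) {
    m <- meta[[b]]
    if (m$n_main > 0) R_all[m$main_idx, , b] <- O_main[seq_len(m$n_main), , b]
    if (m$n_side > 0) R_all[m$side_idx, , b] <- O_side[seq_len(m$n_side), , b]
  }
  Xa <- array(0, c(3, B, La))
  for (b in seq_len(B)) {
    n <- meta[[b]]$n
    Ra_n <- (R_all[seq_len(n), , b] -
               matrix(ctr[b, ], n, 3, byrow = TRUE)) / sc
    Xa[, b, seq_len(n)] <- t(Ra_n)
  }
  Xo_all <- array(0, c(3, B, La))
  for (b in seq_len(B)) {
    n <- meta[[b]]$n
    Xo_all[, b, seq_len(n)] <- t(X[seq_len(n), , b])
  }
  ba <- branch_forward(Xa, model$all, cfg$bidirectional)
  ba$delta_c <- center_delta(ba$delta, Xo_all, "n")
  O_all <- if (cfg$residual) R_all + sc * to_mat(ba$delta_c, A) else
    sc * to_mat(ba$delta_c, A)
  for (b in seq_len(B)) {
    n <- meta[[b]]$n
    if (n < A) O_all[(n + 1):A, , b] <- 0
  }
  out <- list(O_main = O_main, O_side = O_side, O_all = O_all)
  if (want_cache) {
    out$cache <- list(X = X, Xn = Xn, Cctx = Cctx, bm = bm, bs = bs, ba = ba,
                      Xm_orig = Xm_orig, Xs_orig = Xs_orig, Xo_all = Xo_all,
                      R_all = R_all, Lm = Lm, Ls = Ls, La = La)
  }
  out
}

backward_correction <- function(model, out, meta, cfg, Gm, Gs, Ga) {
  A <- cfg$max_atoms
  Mcap <- cfg$main_capacity
  sc <- cfg$input_scale
  B <- dim(Ga)[3]
  cache <- out$cache
  to_seq <- function(arr, len, scale = 1) {
    o <- array(0, c(3, B, len))
    for (b in seq_len(B)) o[, b, ] <- t(arr[seq_len(len), , b]) * scale
    o
  }
  # the rigid projection is self-adjoint, so the backward pass applies the
  # same projector to the incoming displacement gradients
  center_grad <- function(dDelta, orig, len_field) {
    for (b in seq_len(B)) {
      n <- meta[[b]][[len_field]]
      if (n > 1) {
        dDelta[, b, seq_len(n)] <-
          t(project_out_rigid(t(dDelta[, b, seq_len(n)]),
                              t(orig[, b, seq_len(n)])))
      }
    }
    dDelta
  }
  ga <- branch_backward(cache$ba, model$all,
                        center_grad(to_seq(Ga, cache$La, sc), cache$Xo_all,
                                    "n"),
                        cfg$bidirectional)
  dR_all <- Ga * as.numeric(cfg$residual)
  # the whole-structure branch consumed (R_all - centre) / input_scale
  for (b in seq_len(B)) {
    dR_all[seq_len(cache$La), , b] <- dR_all[seq_len(cache$La), , b] +
      t(ga$dX[, b, ]) / sc
  }
  Gm_tot <- Gm
  Gs_tot <- Gs
  if (!isTRUE(cfg$staged_gradients)) {
    for (b in seq_len(B)) {
      m <- meta[[b]]
      if (m$n_main > 0) {
        Gm_tot[seq_len(m$n_main), , b] <- Gm_tot[seq_len(m$n_main), , b] +
          dR_all[m$main_idx, , b]
      }
      if (m$n_side > 0) {
        Gs_tot[seq_len(m$n_side), , b] <- Gs_tot[seq_len(m$n_side), , b] +
          dR_all[m$side_idx, , b]
      }
    }
  }
  grads <- list()
  dC <- array(0, c(A, 3, B))
  if (uses_main_branch(cfg)) {
    gm <- branch_backward(cache$bm, model$main,
                          center_grad(to_seq(Gm_tot, cache$Lm, sc),
                                      cache$Xm_orig, "n_main"),
                          cfg$bidirectional)
    grads$main <- gm$grads
    for (b in seq_len(B)) {
      m <- meta[[b]]
      if (m$n_main > 0) {
        dC[m$main_idx, , b] <- dC[m$main_idx, , b] +
          t(gm$dX[, b, seq_len(m$n_main)])
      }
    }
  }
  if (uses_side_branch(cfg)) {
    gs <- branch_backward(cache$bs, model$side,
                          center_grad(to_seq(Gs_tot, cache$Ls, sc),
                                      cache$Xs_orig, "n_side"),
                          cfg$bidirectional)
    grads$side <- gs$grads
    for (b in seq_len(B)) {
      m <- meta[[b]]
      if (m$n_side > 0) {
        dC[m$side_idx, , b] <- dC[m$side_idx, , b] +
          t(gs$dX[, b, seq_len(m$n_side)])
      }
    }
  }
  grads$all <- ga$grads
  cb <- conv1d_backward(cache$Xn, model$conv$W, dC)
  grads$conv <- list(W = cb$dW, b = cb$db)
  grads
}

# reference-side caches for the training losses
sample_refs <- function(precise, cfg) {
  rb <- backbone_points(precise)
  list(bb_cache = fape_ref_cache(rb$N, rb$CA, rb$C),
       geom = bond_geometry(precise),
       Dr = side_distance_matrix(precise),
       X = structure_coords(canonicalize_structure(precise)))
}

# losses + gradients for one forward batch; returns per-term means and the
# gradient arrays w.r.t. O_main / O_side / O_all
correction_losses <- function(out, meta, refs, cfg, grad = TRUE) {
  B <- dim(out$O_all)[3]
  terms <- active_terms(cfg)
  w <- cfg$term_weights
  Mcap <- cfg$main_capacity; A <- cfg$max_atoms
  Gm <- array(0, c(Mcap, 3, B))
  Gs <- array(0, c(A, 3, B))
  Ga <- array(0, c(A, 3, B))
  vals <- setNames(numeric(length(terms)), terms)
  for (b in seq_len(B)) {
    m <- meta[[b]]
    rf <- refs[[b]]
    eps <- if (is.null(cfg$loss_smooth_eps)) 0 else cfg$loss_smooth_eps
    if ("l_main" %in% terms) {
      fp <- fape_backbone(out$O_main[m$m_iN, , b], out$O_main[m$m_iCA, , b],
                          out$O_main[m$m_iC, , b], rf$bb_cache, grad = grad,
                          clamp = cfg$clamp, smooth_eps = eps)
      v <- if (grad) fp$value else fp
      check_finite(v, "l_main")
      vals["l_main"] <- vals["l_main"] + v
      if (grad) {
        sc <- w[["l_main"]] / B
        Gm[m$m_iN, , b] <- Gm[m$m_iN, , b] + sc * fp$dN
        Gm[m$m_iCA, , b] <- Gm[m$m_iCA, , b] + sc * fp$dCA
        Gm[m$m_iC, , b] <- Gm[m$m_iC, , b] + sc * fp$dC
      }
    }
    if ("l_side" %in% terms && m$n_side >= 2) {
      sg <- lside_with_grad(out$O_side[seq_len(m$n_side), , b], rf$Dr,
                            smooth_eps = eps)
      check_finite(sg$value, "l_side")
      vals["l_side"] <- vals["l_side"] + sg$value
      if (grad) {
        Gs[seq_len(m$n_side), , b] <- Gs[seq_len(m$n_side), , b] +
          (w[["l_side"]] / B) * sg$dX
      }
    }
    if ("l_all" %in% terms) {
      fa <- fape_backbone(out$O_all[m$a_iN, , b], out$O_all[m$a_iCA, , b],
                          out$O_all[m$a_iC, , b], rf$bb_cache, grad = grad,
                          clamp = cfg$clamp, smooth_eps = eps)
      bp <- bond_penalty(out$O_all[m$a_iN, , b], out$O_all[m$a_iCA, , b],
                         out$O_all[m$a_iC, , b], rf$geom, grad = grad,
                         angle_scale = if (cfg$angle_unit == "degrees")
                           180 / pi else 1, smooth_eps = eps)
      v <- (if (grad) fa$value else fa) + (if (grad) bp$value else bp)
      check_finite(v, "l_all")
      vals["l_all"] <- vals["l_all"] + v
      if (grad) {
        sc <- w[["l_all"]] / B
        Ga[m$a_iN, , b] <- Ga[m$a_iN, , b] + sc * (fa$dN + bp$dN)
        Ga[m$a_iCA, , b] <- Ga[m$a_iCA, , b] + sc * (fa$dCA + bp$dCA)
        Ga[m$a_iC, , b] <- Ga[m$a_iC, , b] + sc * (fa$dC + bp$dC)
      }
    }
    if ("mse" %in% terms) {
      n <- m$n
      diff <- out$O_all[seq_len(n), , b] - rf$X
      v <- mean(diff^2)
      check_finite(v, "mse")
      vals["mse"] <- vals["mse"] + v
      if (grad) {
        Ga[seq_len(n), , b] <- Ga[seq_len(n), , b] +
          (w[["mse"]] / B) * 2 * diff / (3 * n)
      }
    }
  }
  vals <- vals / B
  list(values = vals, total = sum(w[terms] * vals), Gm = Gm, Gs = Gs, Ga = Ga)
}

check_finite <- function(v, term) {
  if (!is.finite(v)) {
    abort(sprintf("non-finite loss in term %s", term),
          class = "tcrcost_nan_loss")
  }
  invisible(v)
}

#' Train the structure-correction network
#'
#' @param pairs A tibble with list-columns `predicted` and `precise`
#'   ([tcr_structure()] objects, atom-aligned; see
#'   [make_correction_pairs()]), or a plain list of
#'   `list(predicted =, precise =)` pairs.
#' @param cfg A [correction_config()].
#' @return An object of class `tcrcost_correction` with elements `model`,
#'   `config` and `trace` (per-epoch tibble of the active loss terms).
#'   [tidy()] returns the trace, [glance()] a one-row summary and
#'   [autoplot()] the training curves.
#' @export
train_correction <- function(pairs, cfg = correction_config()) {
  if (is.data.frame(pairs)) {
    pairs <- lapply(seq_len(nrow(pairs)), function(i) {
      list(predicted = pairs$predicted[[i]], precise = pairs$precise[[i]])
    })
  }
  if (length(pairs) < 1) abort("need at least one training pair")
  prepped <- lapply(pairs, function(p) {
    al <- align_atom_order(p$precise, p$predicted)
    if (nrow(al$predicted) > cfg$max_atoms) {
      abort(sprintf("training pair exceeds %d atoms", cfg$max_atoms),
            class = "tcrcost_capacity")
    }
    pc <- pad_truncate(al$predicted, cfg$max_atoms)
    list(x = pc$coords, meta = sample_meta(al$predicted, cfg),
         refs = sample_refs(al$precise, cfg))
  })
  n <- length(prepped)
  model <- init_correction_model(cfg)
  state <- adam_init(model)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  terms <- active_terms(cfg)
  trace <- vector("list", cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    lr <- if (identical(cfg$lr_decay, "cosine")) {
      frac <- (epoch - 1) / max(cfg$epochs - 1, 1)
      cfg$learning_rate * (0.01 + 0.99 * (1 + cos(pi * frac)) / 2)
    } else {
      cfg$learning_rate
    }
    ord <- sample.int(n)
    splits <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    epoch_vals <- setNames(numeric(length(terms)), terms)
    epoch_total <- 0
    for (batch in splits) {
      B <- length(batch)
      X <- array(0, c(cfg$max_atoms, 3, B))
      for (j in seq_along(batch)) X[, , j] <- prepped[[batch[j]]]$x
      meta <- lapply(prepped[batch], `[[`, "meta")
      refs <- lapply(prepped[batch], `[[`, "refs")
      out <- forward_correction(model, X, meta, cfg, want_cache = TRUE)
      ls <- correction_losses(out, meta, refs, cfg, grad = TRUE)
      grads <- backward_correction(model, out, meta, cfg, ls$Gm, ls$Gs, ls$Ga)
      gn <- grad_global_norm(grads)
      if (is.finite(gn) && gn > 5) grads <- grad_scale(grads, 5 / gn)
      st <- adam_step(model, grads, state, lr)
      model <- st$params
      state <- st$state
      epoch_vals <- epoch_vals + ls$values * B / n
      epoch_total <- epoch_total + ls$total * B / n
    }
    trace[[epoch]] <- tibble(epoch = epoch, loss = epoch_total,
                             !!!as.list(epoch_vals))
  }
  structure(list(model = model, config = cfg,
                 trace = dplyr::bind_rows(trace)),
            class = "tcrcost_correction")
}

#' Correct a predicted structure with a trained model
#'
#' Atom content (names, residues, elements) is preserved; only coordinates
#' change. Structures longer than the model's input capacity are truncated
#' with a warning and the dropped tail atoms are not returned.
#'
#' Because all geometric training losses are invariant to rigid motion of
#' the output, the network only determines the corrected structure up to a
#' global rotation and translation. `anchor = TRUE` (the default) fixes
#' this gauge by least-squares rigid alignment of the corrected
#' coordinates onto the *input* coordinates — no reference structure is
#' involved, so the step is available at inference on new predictions.
#'
#' @param fit A `tcrcost_correction` object from [train_correction()], or a
#'   bare `correction_model`.
#' @param predicted A [tcr_structure()].
#' @param cfg Configuration (defaults to the fit's).
#' @param anchor Rigidly re-anchor the output onto the input pose?
#' @return The corrected [tcr_structure()].
#' @export
correct_structure <- function(fit, predicted, cfg = NULL, anchor = TRUE) {
  if (inherits(fit, "tcrcost_correction")) {
    model <- fit$model
    if (is.null(cfg)) cfg <- fit$config
  } else {
    model <- fit
    if (is.null(cfg)) cfg <- correction_config()
  }
  s <- canonicalize_structure(predicted)
  n_keep <- min(nrow(s), cfg$max_atoms)
  # both capacities bind: total atoms and main-chain slots
  cum_main <- cumsum(s$is_main_chain)
  over_main <- which(cum_main > cfg$main_capacity)
  if (length(over_main) > 0) n_keep <- min(n_keep, over_main[1] - 1L)
  if (n_keep < nrow(s)) {
    warn(sprintf("structure truncated from %d to %d atoms; tail atoms dropped",
                 nrow(s), n_keep))
    s <- s[seq_len(n_keep), ]
  }
  pc <- suppressMessages(pad_truncate(s, cfg$max_atoms))
  X <- array(pc$coords, c(cfg$max_atoms, 3, 1))
  meta <- list(sample_meta(s, cfg))
  out <- forward_correction(model, X, meta, cfg)
  corrected <- out$O_all[seq_len(nrow(s)), , 1]
  if (anchor) corrected <- kabsch_onto(corrected, pc$coords[seq_len(nrow(s)), ])
  set_structure_coords(s, corrected)
}

#' Forward pass of the correction network on padded coordinates
#'
#' @param fit A `tcrcost_correction` fit or bare `correction_model`.
#' @param coords A `padded_coords` object (see [pad_truncate()]).
#' @param masks A `chain_masks` object (see [build_chain_masks()]); its
#'   index attributes define the main/side split.
#' @param s The structure the coordinates came from (used to locate backbone
#'   atoms); required for exact per-branch outputs.
#' @param cfg Configuration (defaults to the fit's).
#' @return A list with `O_main` (`main_capacity x 3`), `O_side`
#'   (`max_atoms x 3`) and `O_all` (`max_atoms x 3`) corrected coordinates.
#' @export
correction_apply <- function(fit, coords, masks, s, cfg = NULL) {
  if (inherits(fit, "tcrcost_correction")) {
    model <- fit$model
    if (is.null(cfg)) cfg <- fit$config
  } else {
    model <- fit
    if (is.null(cfg)) cfg <- correction_config()
  }
  X <- array(coords$coords, c(cfg$max_atoms, 3, 1))
  out <- forward_correction(model, X, list(sample_meta(s, cfg)), cfg)
  list(O_main = out$O_main[, , 1], O_side = out$O_side[, , 1],
       O_all = out$O_all[, , 1])
}

#' @export
tidy.tcrcost_correction <- function(x, ...) x$trace

#' @export
glance.tcrcost_correction <- function(x, ...) {
  last <- x$trace[nrow(x$trace), ]
  tibble(epochs = nrow(x$trace), final_loss = last$loss,
         variant = x$config$variant, loss_mode = x$config$loss_mode,
         lstm_hidden = x$config$lstm_hidden)
}

#' @export
print.tcrcost_correction <- function(x, ...) {
  cat(sprintf("<tcrcost_correction: variant %s, loss %s, %d epochs, final loss %.4f>\n",
              x$config$variant, x$config$loss_mode, nrow(x$trace),
              x$trace$loss[nrow(x$trace)]))
  invisible(x)
}

#' @export
autoplot.tcrcost_correction <- function(object, ...) {
  df <- tidyr::pivot_longer(object$trace, -"epoch", names_to = "term",
                            values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss", colour = NULL,
                  title = "Correction training trace") +
    ggplot2::theme_minimal()
}

#' Save or load a fitted model
#'
#' Checkpoints are self-describing: the file stores the full configuration
#' together with the weights (and, for binding models, the normalization
#' statistics).
#'
#' @param fit A `tcrcost_correction` or `tcrcost_binding` object.
#' @param path Checkpoint file path.
#' @return `path` (save) or the restored fit object (load).
#' @export
save_model <- function(fit, path) {
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
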