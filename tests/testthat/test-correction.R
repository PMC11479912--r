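scfg_small <- synth_config(n_complexes = 4, cdr3a_len = 11, cdr3b_len = 11,
                           peptide_len = 8, seed = 101)

test_that("the forward pass honours the output shape contract", {
  cfg <- correction_config(lstm_hidden = 4, seed = 1)
  model <- init_correction_model(cfg)
  pairs <- make_correction_pairs(scfg_small, n = 1)
  s <- pairs$predicted[[1]]
  pc <- pad_truncate(s)
  masks <- build_chain_masks(s)
  out <- correction_apply(model, pc, masks, s, cfg)
  expect_equal(dim(out$O_main), c(150, 3))
  expect_equal(dim(out$O_side), c(400, 3))
  expect_equal(dim(out$O_all), c(400, 3))
  expect_true(all(is.finite(out$O_all)))
  # padded rows stay zero
  expect_true(all(out$O_all[!pc$mask, ] == 0))
})

test_that("a zero-weight model with residual head is the identity", {
  cfg <- correction_config(lstm_hidden = 4, seed = 1)
  model <- init_correction_model(cfg)
  zero_fill <- function(p) if (is.list(p)) lapply(p, zero_fill) else p * 0
  model_zero <- zero_fill(model)
  s <- make_correction_pairs(scfg_small, n = 1)$predicted[[1]]
  pc <- pad_truncate(s)
  out <- correction_apply(model_zero, pc, build_chain_masks(s), s, cfg)
  expect_equal(out$O_all[pc$mask, ], pc$coords[pc$mask, ])
  # the default initialization also starts at the identity (zero heads)
  out2 <- correction_apply(model, pc, build_chain_masks(s), s, cfg)
  expect_equal(out2$O_all[pc$mask, ], pc$coords[pc$mask, ])
})

test_that("forward passes are deterministic for a fixed model and input", {
  cfg <- correction_config(lstm_hidden = 6, seed = 9)
  set.seed(42)
  jitter <- function(p) if (is.list(p)) lapply(p, jitter) else
    p + rnorm(length(p)) * 0.05
  model <- jitter(init_correction_model(cfg))
  s <- make_correction_pairs(scfg_small, n = 1)$predicted[[1]]
  pc <- pad_truncate(s)
  m <- build_chain_masks(s)
  a <- correction_apply(model, pc, m, s, cfg)
  b <- correction_apply(model, pc, m, s, cfg)
  expect_identical(a$O_all, b$O_all)
  expect_identical(a$O_main, b$O_main)
})

test_that("training is reproducible and records a full loss trace", {
  pairs <- make_correction_pairs(scfg_small, n = 3)
  cfg <- correction_config(lstm_hidden = 4, epochs = 3, batch_size = 3,
                           bidirectional = FALSE, seed = 7)
  f1 <- train_correction(pairs, cfg)
  f2 <- train_correction(pairs, cfg)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$model, f2$model)
  expect_equal(nrow(f1$trace), 3)
  expect_true(all(c("l_main", "l_side", "l_all") %in% names(f1$trace)))
  expect_s3_class(tidy(f1), "tbl_df")
  expect_equal(glance(f1)$epochs, 3)
})

test_that("MSE training on identical pairs has zero loss at identity init", {
  precise <- lapply(1:2, function(i) make_precise_complex(scfg_small, i))
  pairs <- tibble::tibble(pair_id = c("a", "b"),
                          precise = precise, predicted = precise)
  cfg <- correction_config(lstm_hidden = 4, epochs = 2, batch_size = 2,
                           bidirectional = FALSE, loss_mode = "MSE",
                           learning_rate = 0, seed = 3)
  fit <- train_correction(pairs, cfg)
  expect_equal(fit$trace$mse, c(0, 0))
})

test_that("the LSTM_ALL variant has no chain-branch parameters or gradients", {
  cfg <- correction_config(lstm_hidden = 4, variant = "LSTM_ALL", seed = 2)
  model <- init_correction_model(cfg)
  expect_null(model$main)
  expect_null(model$side)
  pairs <- make_correction_pairs(scfg_small, n = 2)
  fit <- train_correction(pairs, correction_config(
    lstm_hidden = 4, variant = "LSTM_ALL", epochs = 2, batch_size = 2,
    bidirectional = FALSE, seed = 2))
  expect_null(fit$model$main)
  expect_identical(names(fit$trace), c("epoch", "loss", "l_all"))
})

test_that("chain-bypass variants pass the untouched chain through", {
  cfg <- correction_config(lstm_hidden = 4, variant = "LSTM_MAIN", seed = 2)
  set.seed(8)
  jitter <- function(p) if (is.list(p)) lapply(p, jitter) else
    p + rnorm(length(p)) * 0.05
  model <- jitter(init_correction_model(cfg))
  s <- make_correction_pairs(scfg_small, n = 1)$predicted[[1]]
  pc <- pad_truncate(s)
  out <- correction_apply(model, pc, build_chain_masks(s), s, cfg)
  side_idx <- which(!tcrcost:::canonicalize_structure(s)$is_main_chain)
  n_side <- length(side_idx)
  # side corrector bypassed: O_side equals the input side-chain coordinates
  expect_equal(out$O_side[seq_len(n_side), ], pc$coords[side_idx, ])
  # main corrector active: O_main differs from the input main coordinates
  main_idx <- which(tcrcost:::canonicalize_structure(s)$is_main_chain)
  expect_gt(max(abs(out$O_main[seq_along(main_idx), ] - pc$coords[main_idx, ])),
            1e-8)
})

test_that("correct_structure preserves atom content and round-trips as PDB", {
  pairs <- make_correction_pairs(scfg_small, n = 1)
  cfg <- correction_config(lstm_hidden = 4, epochs = 2, batch_size = 1,
                           bidirectional = FALSE, seed = 5)
  fit <- train_correction(pairs, cfg)
  s <- pairs$predicted[[1]]
  co <- correct_structure(fit, s)
  expect_identical(co$atom_name, tcrcost:::canonicalize_structure(s)$atom_name)
  expect_identical(co$residue_name,
                   tcrcost:::canonicalize_structure(s)$residue_name)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(co, f)
  back <- parse_pdb(f)
  expect_lt(max(abs(structure_coords(back) - structure_coords(co))), 5e-4)
})

test_that("oversized structures are truncated with a warning", {
  big_cfg <- synth_config(cdr3a_len = 18, cdr3b_len = 18, peptide_len = 11,
                          seed = 33)
  big <- make_precise_complex(big_cfg, 2)
  cfg <- correction_config(lstm_hidden = 4, seed = 1)
  model <- init_correction_model(cfg)
  expect_warning(co <- correct_structure(model, big, cfg), "truncated")
  expect_lte(n_atoms(co), 400)
  expect_lte(sum(co$is_main_chain), 150)
  expect_lt(n_atoms(co), n_atoms(big))
})

test_that("checkpoints round-trip through save_model/load_model", {
  pairs <- make_correction_pairs(scfg_small, n = 1)
  cfg <- correction_config(lstm_hidden = 4, epochs = 1, batch_size = 1,
                           bidirectional = FALSE, seed = 5)
  fit <- train_correction(pairs, cfg)
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(fit, f)
  fit2 <- load_model(f)
  expect_identical(fit2$model, fit$model)
  s <- pairs$predicted[[1]]
  expect_identical(structure_coords(correct_structure(fit, s)),
                   structure_coords(correct_structure(fit2, s)))
})
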