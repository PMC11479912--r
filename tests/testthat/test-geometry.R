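test_that("backbone frames have the stated canonical form", {
  # axis-aligned construction: rotation is the identity, origin is CA
  res <- manual_structure(c("N", "CA", "C"),
                          matrix(c(0, 1.4, 0, 0, 0, 0, 1.5, 0, 0),
                                 3, 3, byrow = TRUE))
  fr <- build_frames(res)
  expect_equal(fr$rotation[, , 1], diag(3), tolerance = 1e-12)
  expect_equal(fr$origin[1, ], c(0, 0, 0))

  # the inverse transform always sends the residue's own CA to the origin
  s <- random_small_structure(4)
  fr <- build_frames(s)
  for (i in seq_len(nrow(fr$origin))) {
    local <- t(fr$rotation[, , i]) %*% (fr$origin[i, ] - fr$origin[i, ])
    expect_equal(as.vector(local), c(0, 0, 0))
  }
  # orthonormality with det +1
  for (i in seq_len(dim(fr$rotation)[3])) {
    R <- fr$rotation[, , i]
    expect_equal(crossprod(R), diag(3), tolerance = 1e-6)
    expect_equal(det(R), 1, tolerance = 1e-6)
  }
})

test_that("frames of a rigidly rotated structure compose with the rotation", {
  s <- random_small_structure(5)
  fr <- build_frames(s)
  R <- random_rotation_matrix()
  fr2 <- build_frames(transform_structure(s, R, c(1, -2, 3)))
  for (i in seq_len(dim(fr$rotation)[3])) {
    expect_equal(fr2$rotation[, , i], R %*% fr$rotation[, , i],
                 tolerance = 1e-9)
  }
})

test_that("degenerate collinear backbones are rejected with the residue named", {
  bad <- manual_structure(c("N", "CA", "C"),
                          matrix(c(-1, 0, 0, 0, 0, 0, 1, 0, 0),
                                 3, 3, byrow = TRUE))
  expect_error(build_frames(bad), class = "tcrcost_degenerate_frame")
})

test_that("l_main is zero on identical and rigidly transformed structures", {
  s <- random_small_structure(6)
  expect_equal(l_main(s, s), 0)
  for (r in 1:5) {
    R <- random_rotation_matrix()
    t1 <- rnorm(3, 0, 5)
    expect_lt(abs(l_main(transform_structure(s, R, t1), s)), 1e-5)
  }
})

test_that("l_main matches a literal double-loop implementation", {
  cfgp <- synth_config(seed = 31)
  for (seed in c(2, 9, 17)) {
    s <- random_small_structure(seed, n_res = 5)
    p <- perturb_structure(s, cfgp, seed = seed + 100)
    expect_equal(l_main(p, s), brute_l_main(p, s), tolerance = 1e-6)
  }
})

test_that("a rigid translation of one residue gives the brute-force FAPE value", {
  s <- random_small_structure(12, n_res = 2)
  p <- s
  shift <- p$residue_index == 1
  p$x[shift] <- p$x[shift] + 2
  p <- tcr_structure(p)
  expect_gt(l_main(p, s), 0)
  expect_equal(l_main(p, s), brute_l_main(p, s), tolerance = 1e-6)
})

test_that("l_side reproduces hand-computed values and conventions", {
  Dr <- matrix(1, 3, 3); diag(Dr) <- 0
  Dc <- matrix(6, 3, 3); diag(Dc) <- 0
  # all |Dr - Dc| = 5: per-threshold ratios 4.5/5, 4/5, 3/5, 1/5
  expect_equal(l_side(Dc, Dr), 0.625)
  expect_equal(l_side(Dr, Dr), 0)  # 0/0 convention
  # uniform deviations below the smallest threshold cost nothing
  Dc2 <- Dr + 0.4; diag(Dc2) <- 0
  expect_equal(l_side(Dc2, Dr), 0)
  expect_error(l_side(matrix(0, 2, 2), Dr), class = "tcrcost_loss_error")
})

test_that("l_side stays in [0, 1], saturates, and matches the literal loop", {
  set.seed(42)
  for (r in 1:50) {
    n <- sample(3:8, 1)
    Dc <- as.matrix(dist(matrix(rnorm(3 * n, 0, 4), n, 3)))
    Dr <- as.matrix(dist(matrix(rnorm(3 * n, 0, 4), n, 3)))
    v <- l_side(Dc, Dr)
    expect_gte(v, 0)
    expect_lte(v, 1)
    expect_equal(v, brute_l_side(Dc, Dr), tolerance = 1e-12)
  }
  # a huge uniform discrepancy drives the loss towards its upper bound
  Dr <- matrix(1, 4, 4); diag(Dr) <- 0
  Dc <- Dr + 1000; diag(Dc) <- 0
  expect_gt(l_side(Dc, Dr), 0.998)
})

test_that("l_side is invariant under rigid transforms of either structure", {
  s <- random_small_structure(3)
  p <- perturb_structure(s, synth_config(seed = 3), seed = 5)
  v0 <- l_side(side_distance_matrix(p), side_distance_matrix(s))
  for (r in 1:5) {
    R <- random_rotation_matrix()
    sR <- transform_structure(s, R, rnorm(3))
    pR <- transform_structure(p, random_rotation_matrix(), rnorm(3))
    expect_equal(l_side(side_distance_matrix(pR), side_distance_matrix(sR)),
                 v0, tolerance = 1e-9)
  }
})

test_that("bond geometry measures canonical peptide-bond quantities", {
  two <- tcr_structure(tibble::tibble(
    element = rep(c("N", "C", "C", "O"), 2),
    atom_name = rep(c("N", "CA", "C", "O"), 2),
    residue_index = rep(0:1, each = 4),
    residue_name = "GLY", segment = "CDR3A",
    x = c(-2.3, -1.5, 0, 0.2, 1.33, 2.5, 3.4, 3.5),
    y = c(0.8, 1.2, 0, -1.1, 0, 0.8, -0.2, -1.3),
    z = rep(0, 8)))
  g <- bond_geometry(two)
  expect_equal(nrow(g), 1)
  expect_equal(g$length, sqrt(1.33^2 + 0^2))

  # near-collinear CA-C-N angle approaches (but does not reach) 180 degrees
  three <- manual_structure(c("N", "CA", "C"),
                            matrix(c(-1.2, 1, 0, -1, 0.01, 0, 0, 0, 0),
                                   3, 3, byrow = TRUE))
  nxt <- manual_structure(c("N", "CA", "C"),
                          matrix(c(1, 0, 0, 2.2, 0.7, 0, 3.5, 0, 0),
                                 3, 3, byrow = TRUE), residue_index = 1L)
  s <- tcr_structure(dplyr::bind_rows(three, nxt))
  ang <- bond_geometry(s)$angle[1]
  expect_equal(ang, 179.4271, tolerance = 1e-3)
  expect_lt(ang, 180)
})

test_that("bond geometry is invariant under rigid motion", {
  s <- random_small_structure(9)
  g0 <- bond_geometry(s)
  sR <- transform_structure(s, random_rotation_matrix(), rnorm(3, 0, 10))
  g1 <- bond_geometry(sR)
  expect_equal(g1$length, g0$length, tolerance = 1e-9)
  expect_equal(g1$angle, g0$angle, tolerance = 1e-9)
})

test_that("l_all adds exact bond penalties and dominates l_main", {
  s <- random_small_structure(14, n_res = 4)
  expect_equal(l_all(s, s), 0)

  # stretch every inter-residue bond by +0.1 A along its own axis while
  # keeping each residue internally rigid: translate residue blocks
  p <- s
  bb <- backbone_triples(s)
  offset <- matrix(0, nrow(s), 3)
  shift <- c(0, 0, 0)
  for (i in 2:4) {
    dirv <- bb$N[i, ] - bb$C[i - 1, ]
    dirv <- dirv / sqrt(sum(dirv^2))
    shift <- shift + 0.1 * dirv
    offset[s$residue_index == i - 1, ] <-
      matrix(shift, sum(s$residue_index == i - 1), 3, byrow = TRUE)
  }
  xyz <- structure_coords(s) + offset
  p <- tcr_structure(dplyr::mutate(s, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
  geom_term <- l_all(p, s) - l_main(p, s)
  expect_equal(geom_term, 0.1 * 3, tolerance = 1e-6)

  cfgp <- synth_config(seed = 2)
  q <- perturb_structure(s, cfgp, seed = 77)
  expect_gte(l_all(q, s), l_main(q, s))
  expect_equal(l_all(q, s), brute_l_all(q, s), tolerance = 1e-6)
})

test_that("rmsd matches hand arithmetic and closed forms", {
  a <- manual_structure(c("N", "CA", "C"),
                        matrix(c(0, 0, 0, 1.5, 0, 0, 2, 1, 0), 3, 3,
                               byrow = TRUE))
  expect_equal(rmsd(a, a), 0)
  # two displaced atoms: sqrt((3^2 + 4^2 + 0^2) / 3)
  b <- a
  b$x[1] <- b$x[1] + 3
  b$y[2] <- b$y[2] + 4
  expect_equal(rmsd(tcr_structure(b), a), sqrt(25 / 3))
  # pure translation: rmsd equals the translation norm
  for (r in 1:5) {
    t1 <- rnorm(3, 0, 4)
    expect_equal(rmsd(transform_structure(a, diag(3), t1), a),
                 sqrt(sum(t1^2)), tolerance = 1e-9)
  }
  expect_error(rmsd(structure_coords(a)[1:2, ], structure_coords(a)),
               class = "tcrcost_loss_error")
})

test_that("rmsd behaves as a metric on aligned coordinate sets", {
  set.seed(7)
  for (r in 1:20) {
    X <- matrix(rnorm(30), 10, 3)
    Y <- matrix(rnorm(30), 10, 3)
    Z <- matrix(rnorm(30), 10, 3)
    expect_equal(rmsd(X, Y), rmsd(Y, X))
    expect_lte(rmsd(X, Z), rmsd(X, Y) + rmsd(Y, Z) + 1e-12)
  }
  X <- matrix(rnorm(30), 10, 3)
  expect_identical(rmsd(X, X), 0)
})

test_that("loss gradients agree with central differences", {
  cfgp <- synth_config(seed = 2)
  s <- random_small_structure(21, n_res = 4)
  p <- perturb_structure(s, cfgp, seed = 3)
  pb <- backbone_triples(p)
  rb <- backbone_triples(s)
  cache <- tcrcost:::fape_ref_cache(rb$N, rb$CA, rb$C)
  g <- tcrcost:::fape_backbone(pb$N, pb$CA, pb$C, cache, grad = TRUE)
  eps <- 1e-6
  for (nm in c("N", "CA", "C")) {
    for (pick in list(c(1, 1), c(3, 2))) {
      pb2 <- pb
      pb2[[nm]][pick[1], pick[2]] <- pb2[[nm]][pick[1], pick[2]] + eps
      v1 <- tcrcost:::fape_backbone(pb2$N, pb2$CA, pb2$C, cache)
      pb2[[nm]][pick[1], pick[2]] <- pb2[[nm]][pick[1], pick[2]] - 2 * eps
      v0 <- tcrcost:::fape_backbone(pb2$N, pb2$CA, pb2$C, cache)
      expect_equal(g[[paste0("d", nm)]][pick[1], pick[2]],
                   (v1 - v0) / (2 * eps), tolerance = 1e-5)
    }
  }
  X <- structure_coords(p)[!p$is_main_chain, ]
  Dr <- side_distance_matrix(s)
  gs <- tcrcost:::lside_with_grad(X, Dr)
  for (pick in list(c(1, 1), c(4, 3))) {
    X2 <- X
    X2[pick[1], pick[2]] <- X2[pick[1], pick[2]] + eps
    v1 <- tcrcost:::lside_with_grad(X2, Dr)$value
    X2[pick[1], pick[2]] <- X2[pick[1], pick[2]] - 2 * eps
    v0 <- tcrcost:::lside_with_grad(X2, Dr)$value
    expect_equal(gs$dX[pick[1], pick[2]], (v1 - v0) / (2 * eps),
                 tolerance = 1e-5)
  }
})
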