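#' Per-residue backbone frames
#'
#' Builds one rigid transform per residue from its N, CA and C atoms by
#' Gram-Schmidt: `e1` is the unit vector from CA to C, `e2` the unit
#' component of CA-to-N orthogonal to `e1`, `e3 = e1 x e2`, and the origin
#' is CA. The rotation columns `(e1, e2, e3)` map local coordinates to
#' global ones; the inverse transform expresses any atom in the residue's
#' local frame.
#'
#' @param s A [tcr_structure()].
#' @return An object of class `frame_set`: list with `rotation`
#'   (3 x 3 x n_residues array) and `origin` (n_residues x 3 matrix).
#' @export
build_frames <- function(s) {
  bb <- backbone_points(s)
  fr <- frames_from_backbone(bb$N, bb$CA, bb$C, error_on_degenerate = TRUE)
  structure(list(rotation = fr$rotation, origin = bb$CA), class = "frame_set")
}

# N, CA, C coordinate matrices in residue order
backbone_points <- function(s) {
  s <- canonicalize_structure(s)
  pick <- function(nm) {
    structure_coords(s)[s$atom_name == nm, , drop = FALSE]
  }
  out <- list(N = pick("N"), CA = pick("CA"), C = pick("C"))
  nr <- n_residues(s)
  if (any(vapply(out, nrow, 0L) != nr)) {
    abort("every residue needs exactly one N, CA and C atom",
          class = "tcrcost_missing_backbone")
  }
  out
}

cross_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# vectorized Gram-Schmidt over residues; returns rotations plus the
# intermediates needed for the backward pass
frames_from_backbone <- function(N, CA, C, error_on_degenerate = FALSE) {
  u1 <- C - CA
  n1 <- sqrt(rowSums(u1^2))
  e1 <- u1 / n1
  w <- N - CA
  dt <- rowSums(e1 * w)
  u2 <- w - dt * e1
  n2 <- sqrt(rowSums(u2^2))
  if (any(n1 < 1e-8) || any(n2 < 1e-8)) {
    bad <- which(n1 < 1e-8 | n2 < 1e-8)[1]
    if (error_on_degenerate) {
      abort(sprintf("degenerate backbone frame at residue %d (collinear N, CA, C)",
                    bad - 1L), class = "tcrcost_degenerate_frame")
    }
  }
  e2 <- u2 / n2
  e3 <- cross_rows(e1, e2)
  nr <- nrow(N)
  rotation <- array(0, c(3, 3, nr))
  rotation[, 1, ] <- t(e1)
  rotation[, 2, ] <- t(e2)
  rotation[, 3, ] <- t(e3)
  list(rotation = rotation, e1 = e1, e2 = e2, e3 = e3,
       n1 = n1, n2 = n2, w = w)
}

# backward through frames_from_backbone: gE1, gE2, gE3 are N x 3 gradients
# w.r.t. the basis vectors; returns gradients w.r.t. the N, CA, C inputs
frames_backward <- function(cache, gE1, gE2, gE3) {
  e1 <- cache$e1; e2 <- cache$e2; w <- cache$w
  n1 <- cache$n1; n2 <- cache$n2
  ge1 <- gE1 + cross_rows(e2, gE3)
  ge2 <- gE2 + cross_rows(gE3, e1)
  gu2 <- (ge2 - e2 * rowSums(e2 * ge2)) / n2
  gw <- gu2 - e1 * rowSums(e1 * gu2)
  ge1 <- ge1 - w * rowSums(e1 * gu2) - gu2 * rowSums(e1 * w)
  gu1 <- (ge1 - e1 * rowSums(e1 * ge1)) / n1
  list(dN = gw, dCA = -gu1 - gw, dC = gu1)
}

# rows of the stacked inverse-rotation matrix: for frame i, rows
# 3(i-1)+1..3 are e1_i, e2_i, e3_i as row vectors
stack_frames <- function(fr) {
  nr <- nrow(fr$e1)
  M <- rbind(fr$e1, fr$e2, fr$e3)
  M[as.vector(rbind(seq_len(nr), nr + seq_len(nr), 2 * nr + seq_len(nr))), ,
    drop = FALSE]
}

# local coordinates of every point in every frame: (3N x M) matrix where
# row 3(i-1)+k holds the k-th local coordinate in frame i
local_coords <- function(Rt, CA, P) {
  tr <- rowSums(Rt * CA[rep(seq_len(nrow(CA)), each = 3), , drop = FALSE])
  Rt %*% t(P) - tr
}

# frame-aligned point error over backbone N/CA/C points, with optional
# analytic gradient w.r.t. the predicted backbone atoms
fape_backbone <- function(predN, predCA, predC, ref_cache, grad = FALSE,
                          clamp = Inf, smooth_eps = 0) {
  nr <- nrow(predN)
  M <- 3L * nr
  P <- matrix(0, M, 3)
  iN <- seq(1, M, 3); iCA <- seq(2, M, 3); iC <- seq(3, M, 3)
  P[iN, ] <- predN; P[iCA, ] <- predCA; P[iC, ] <- predC
  fr <- frames_from_backbone(predN, predCA, predC)
  Rt <- stack_frames(fr)
  Lp <- local_coords(Rt, predCA, P)
  Diff <- Lp - ref_cache$Lr
  i1 <- seq(1, 3 * nr, 3)
  D1 <- Diff[i1, , drop = FALSE]
  D2 <- Diff[i1 + 1, , drop = FALSE]
  D3 <- Diff[i1 + 2, , drop = FALSE]
  d2 <- D1^2 + D2^2 + D3^2
  # smooth_eps > 0 replaces the norm by sqrt(d^2 + eps^2): value change is
  # bounded by eps, but the gradient vanishes as the deviation does, which
  # removes the step-size oscillation floor of the exact norm
  d <- sqrt(d2 + smooth_eps^2)
  clamped <- is.finite(clamp) & (d > clamp)
  dv <- pmin(d, clamp)
  value <- sum(dv) / (nr^2 * 3)
  if (!grad) return(value)

  wgt <- 1 / (nr^2 * 3)
  dn <- ifelse(d > 1e-12 & !clamped, wgt / d, 0)
  G1 <- D1 * dn; G2 <- D2 * dn; G3 <- D3 * dn
  Gf <- matrix(0, 3 * nr, M)
  Gf[i1, ] <- G1; Gf[i1 + 1, ] <- G2; Gf[i1 + 2, ] <- G3
  # gradient through the points
  dP <- t(crossprod(Rt, Gf))
  # gradient through the frame translation (the CA origin)
  S <- rowSums(Gf)
  S1 <- S[i1]; S2 <- S[i1 + 1]; S3 <- S[i1 + 2]
  dCA_tr <- -(fr$e1 * S1 + fr$e2 * S2 + fr$e3 * S3)
  dP[iCA, ] <- dP[iCA, ] + dCA_tr
  # gradient through the rotations
  sumG <- cbind(S1, S2, S3)
  gE <- lapply(1:3, function(k) {
    Gk <- Gf[i1 + (k - 1), , drop = FALSE]
    (Gk %*% P) - sumG[, k] * predCA
  })
  fb <- frames_backward(fr, gE[[1]], gE[[2]], gE[[3]])
  dP[iN, ] <- dP[iN, ] + fb$dN
  dP[iCA, ] <- dP[iCA, ] + fb$dCA
  dP[iC, ] <- dP[iC, ] + fb$dC
  list(value = value, dN = dP[iN, , drop = FALSE],
       dCA = dP[iCA, , drop = FALSE], dC = dP[iC, , drop = FALSE])
}

# reference-side cache for fape_backbone
fape_ref_cache <- function(refN, refCA, refC) {
  nr <- nrow(refN)
  M <- 3L * nr
  P <- matrix(0, M, 3)
  P[seq(1, M, 3), ] <- refN
  P[seq(2, M, 3), ] <- refCA
  P[seq(3, M, 3), ] <- refC
  fr <- frames_from_backbone(refN, refCA, refC)
  list(Lr = local_coords(stack_frames(fr), refCA, P))
}

#' Frame-aligned point error between two aligned structures
#'
#' Implements the main-chain loss: every residue i defines a local backbone
#' frame in each structure; every residue j is represented by its N, CA and
#' C atoms, whose positions are expressed in frame i of the predicted and
#' the reference structure respectively; the loss is the average (over all
#' frame/residue pairs and the three atoms) of the distance between the two
#' local positions. The construction is invariant to rigid transforms of
#' either structure because frames co-move with coordinates.
#'
#' @param pred,ref Atom-aligned [tcr_structure()] objects with the same
#'   number of residues.
#' @param clamp Optional distance clamp (Angstrom) applied to each local
#'   deviation; `Inf` (default) disables clamping.
#' @return Non-negative scalar (Angstrom).
#' @export
l_main <- function(pred, ref, clamp = Inf) {
  pb <- backbone_points(pred)
  rb <- backbone_points(ref)
  if (nrow(pb$N) != nrow(rb$N)) {
    abort("structures have different residue counts", class = "tcrcost_loss_error")
  }
  fape_backbone(pb$N, pb$CA, pb$C, fape_ref_cache(rb$N, rb$CA, rb$C),
                clamp = clamp)
}

#' Threshold/weight configuration for the side-chain distance loss
#'
#' @param thresholds Strictly increasing distance-error thresholds, Angstrom.
#' @param weights Per-threshold weights summing to 1.
#' @return A list of class `lside_config`.
#' @export
lside_config <- function(thresholds = c(0.5, 1, 2, 4),
                         weights = rep(0.25, 4)) {
  if (length(thresholds) != length(weights)) {
    abort("thresholds and weights must have the same length",
          class = "tcrcost_bad_config")
  }
  if (is.unsorted(thresholds, strictly = TRUE)) {
    abort("thresholds must be strictly increasing", class = "tcrcost_bad_config")
  }
  if (abs(sum(weights) - 1) > 1e-8) {
    abort("weights must sum to 1", class = "tcrcost_bad_config")
  }
  structure(list(thresholds = thresholds, weights = weights),
            class = "lside_config")
}

#' Pairwise distance matrix of side-chain atoms
#'
#' @param s A [tcr_structure()].
#' @return A symmetric matrix of Euclidean distances (Angstrom) among the
#'   side-chain atoms, zero on the diagonal.
#' @export
side_distance_matrix <- function(s) {
  xyz <- structure_coords(canonicalize_structure(s))[!s$is_main_chain, ,
                                                     drop = FALSE]
  unname(as.matrix(stats::dist(xyz)))
}

#' Distance-difference loss over side-chain atom pairs
#'
#' For each threshold `t_k` the loss accumulates
#' `sum ReLU(|Dr - Dc| - t_k) / sum |Dr - Dc|` over unordered atom pairs,
#' weighted by `p_k`. Pair deviations below a threshold contribute nothing
#' to its numerator, so the more pairs fall within the tolerances the lower
#' the loss; the value always lies in `[0, 1]`. Identical matrices give the
#' 0/0 limit, defined as 0.
#'
#' @param Dc,Dr Same-shape distance matrices of the corrected and reference
#'   side chains (see [side_distance_matrix()]).
#' @param cfg An [lside_config()].
#' @return Scalar in `[0, 1]`.
#' @export
l_side <- function(Dc, Dr, cfg = lside_config()) {
  if (!all(dim(Dc) == dim(Dr))) {
    abort("Dc and Dr must have the same shape", class = "tcrcost_loss_error")
  }
  up <- upper.tri(Dc)
  delta <- abs(Dr[up] - Dc[up])
  den <- sum(delta)
  if (den == 0) return(0)
  num <- vapply(cfg$thresholds, function(t) sum(pmax(delta - t, 0)), 0)
  sum(cfg$weights * num) / den
}

the_pair_env <- new.env(parent = emptyenv())

# (i, j) pair indices in the order used by stats::dist, cached per size
pair_indices <- function(n) {
  key <- as.character(n)
  if (is.null(the_pair_env[[key]])) {
    j <- rep(seq_len(n - 1L), times = (n - 1L):1L)
    i <- sequence((n - 1L):1L) + j
    the_pair_env[[key]] <- list(i = i, j = j)
  }
  the_pair_env[[key]]
}

# l_side with gradient w.r.t. the side-chain coordinates X (n x 3) that
# generated Dc; Dr is the fixed reference matrix
lside_with_grad <- function(X, Dr, cfg = lside_config(), smooth_eps = 0) {
  n <- nrow(X)
  if (n < 2) return(list(value = 0, dX = matrix(0, n, 3)))
  px <- pair_indices(n)
  dvec <- as.vector(stats::dist(X))
  drvec <- Dr[cbind(px$i, px$j)]
  delta <- drvec - dvec
  adel <- sqrt(delta^2 + smooth_eps^2)
  den <- sum(adel)
  if (den == 0) return(list(value = 0, dX = matrix(0, n, 3)))
  sgn <- if (smooth_eps > 0) delta / adel else sign(delta)
  num <- vapply(cfg$thresholds, function(t) sum(pmax(adel - t, 0)), 0)
  value <- sum(cfg$weights * num) / den
  # d value / d adel, then chain to the corrected distances via -sgn
  dnum <- numeric(length(adel))
  for (k in seq_along(cfg$thresholds)) {
    dnum <- dnum + cfg$weights[k] * (adel > cfg$thresholds[k])
  }
  dadel <- dnum / den - sum(cfg$weights * num) / den^2
  ddc <- -dadel * sgn
  # chain through D_p = ||x_i - x_j||
  wp <- ddc / pmax(dvec, 1e-12)
  diffm <- (X[px$i, , drop = FALSE] - X[px$j, , drop = FALSE]) * wp
  dX <- matrix(0, n, 3)
  s1 <- rowsum(diffm, px$i)
  dX[as.integer(rownames(s1)), ] <- dX[as.integer(rownames(s1)), ] + s1
  s2 <- rowsum(diffm, px$j)
  dX[as.integer(rownames(s2)), ] <- dX[as.integer(rownames(s2)), ] - s2
  list(value = value, dX = dX)
}

#' Peptide-bond lengths and angles
#'
#' For every consecutive residue pair (i, i+1) of the concatenated complex:
#' the bond length is the C(i)-N(i+1) distance and the bond angle is
#' CA(i)-C(i)-N(i+1), in degrees.
#'
#' @param s A [tcr_structure()] with at least two residues.
#' @return A tibble with columns `residue_index`, `length` (Angstrom) and
#'   `angle` (degrees).
#' @export
bond_geometry <- function(s) {
  bb <- backbone_points(s)
  nr <- nrow(bb$N)
  if (nr < 2) abort("need at least two residues", class = "tcrcost_loss_error")
  i <- seq_len(nr - 1)
  Cn <- bb$C[i, , drop = FALSE]
  Nn <- bb$N[i + 1, , drop = FALSE]
  CAn <- bb$CA[i, , drop = FALSE]
  dv <- Nn - Cn
  lengths <- sqrt(rowSums(dv^2))
  a <- CAn - Cn
  b <- dv
  cosang <- rowSums(a * b) / (sqrt(rowSums(a^2)) * lengths)
  cosang <- pmin(1, pmax(-1, cosang))
  tibble(residue_index = i - 1L, length = lengths,
         angle = acos(cosang) * 180 / pi)
}

# bond-geometry L1 penalty with gradient w.r.t. the predicted backbone;
# angle_scale converts from radians (1 = radians, 180/pi = degrees)
bond_penalty <- function(predN, predCA, predC, ref_geom, grad = FALSE,
                         angle_scale = 180 / pi, smooth_eps = 0) {
  nr <- nrow(predN)
  i <- seq_len(nr - 1)
  Cn <- predC[i, , drop = FALSE]
  Nn <- predN[i + 1, , drop = FALSE]
  CAn <- predCA[i, , drop = FALSE]
  b <- Nn - Cn
  lb <- sqrt(rowSums(b^2))
  a <- CAn - Cn
  la <- sqrt(rowSums(a^2))
  cosang <- pmin(1, pmax(-1, rowSums(a * b) / (la * lb)))
  ang <- acos(cosang) * angle_scale
  dlen <- lb - ref_geom$length
  dang <- ang - ref_geom$angle * angle_scale / (180 / pi)
  sabs <- function(x) sqrt(x^2 + smooth_eps^2)  # smoothed |x| (see above)
  ssign <- function(x) if (smooth_eps > 0) x / sabs(x) else sign(x)
  value <- sum(sabs(dlen)) + sum(sabs(dang))
  if (!grad) return(value)
  dN <- matrix(0, nr, 3); dCA <- matrix(0, nr, 3); dC <- matrix(0, nr, 3)
  # length terms
  ub <- b / lb
  gl <- ssign(dlen)
  dN[i + 1, ] <- dN[i + 1, ] + gl * ub
  dC[i, ] <- dC[i, ] - gl * ub
  # angle terms
  sinang <- sqrt(pmax(1 - cosang^2, 1e-12))
  ga <- ssign(dang) * angle_scale * (-1 / sinang)
  da <- ga * (b / (la * lb) - cosang * a / la^2)
  db <- ga * (a / (la * lb) - cosang * b / lb^2)
  dCA[i, ] <- dCA[i, ] + da
  dN[i + 1, ] <- dN[i + 1, ] + db
  dC[i, ] <- dC[i, ] - da - db
  list(value = value, dN = dN, dCA = dCA, dC = dC)
}

#' Whole-structure correction loss
#'
#' The frame-aligned point error of the full structure's backbone plus L1
#' penalties on peptide-bond length differences (Angstrom) and bond-angle
#' differences (degrees) between the two structures.
#'
#' @inheritParams l_main
#' @param angle_unit Unit of the bond-angle penalty. Both appear in the
#'   literature; degrees make the angle term numerically dominant, radians
#'   keep it commensurate with the other terms (the package trains in
#'   radians for that reason).
#' @return Non-negative scalar.
#' @export
l_all <- function(pred, ref, clamp = Inf,
                  angle_unit = c("degrees", "radians")) {
  angle_unit <- match.arg(angle_unit)
  pb <- backbone_points(pred)
  rb <- backbone_points(ref)
  if (nrow(pb$N) != nrow(rb$N)) {
    abort("structures have different residue counts", class = "tcrcost_loss_error")
  }
  fape <- fape_backbone(pb$N, pb$CA, pb$C, fape_ref_cache(rb$N, rb$CA, rb$C),
                        clamp = clamp)
  geom <- bond_penalty(pb$N, pb$CA, pb$C, bond_geometry(ref),
                       angle_scale = if (angle_unit == "degrees") 180 / pi else 1)
  fape + geom
}

# least-squares rigid alignment of P onto Q (Kabsch); used to fix the
# rigid-body gauge that the invariant training losses leave undetermined
kabsch_onto <- function(P, Q) {
  cp <- colMeans(P)
  cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp)
  Qc <- sweep(Q, 2, cq)
  sv <- svd(crossprod(Pc, Qc))
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sweep(Pc %*% t(R), 2, cq, "+")
}

#' Root mean square distance between paired atoms
#'
#' Computed over positionally paired atoms of two aligned structures; no
#' superposition is applied.
#'
#' @param pred,ref Atom-aligned [tcr_structure()] objects (or coordinate
#'   matrices) with equal atom counts.
#' @return Non-negative scalar (Angstrom).
#' @export
rmsd <- function(pred, ref) {
  Xp <- if (is.data.frame(pred)) structure_coords(pred) else as.matrix(pred)
  Xr <- if (is.data.frame(ref)) structure_coords(ref) else as.matrix(ref)
  if (nrow(Xp) != nrow(Xr)) {
    abort("atom counts differ", class = "tcrcost_loss_error")
  }
  sqrt(mean(rowSums((Xp - Xr)^2)))
}
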