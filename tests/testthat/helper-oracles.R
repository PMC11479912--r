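# Independent, literal-loop reference implementations used as oracles, plus
# small fixture builders. These deliberately avoid the package's vectorized
# code paths.

single_frame <- function(N, CA, C) {
  u1 <- C - CA
  e1 <- u1 / sqrt(sum(u1^2))
  w <- N - CA
  u2 <- w - sum(e1 * w) * e1
  e2 <- u2 / sqrt(sum(u2^2))
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  cbind(e1, e2, e3)
}

# literal double loop over frames i and residues j (three backbone atoms)
brute_l_main <- function(pred, ref) {
  pb <- backbone_triples(pred)
  rb <- backbone_triples(ref)
  nr <- nrow(pb$N)
  total <- 0
  for (i in seq_len(nr)) {
    Rp <- single_frame(pb$N[i, ], pb$CA[i, ], pb$C[i, ])
    Rr <- single_frame(rb$N[i, ], rb$CA[i, ], rb$C[i, ])
    for (j in seq_len(nr)) {
      dsum <- 0
      for (a in c("N", "CA", "C")) {
        lp <- t(Rp) %*% (pb[[a]][j, ] - pb$CA[i, ])
        lr <- t(Rr) %*% (rb[[a]][j, ] - rb$CA[i, ])
        dsum <- dsum + sqrt(sum((lp - lr)^2))
      }
      total <- total + dsum / 3
    }
  }
  total / nr^2
}

backbone_triples <- function(s) {
  xyz <- structure_coords(s)
  list(N = xyz[s$atom_name == "N", , drop = FALSE],
       CA = xyz[s$atom_name == "CA", , drop = FALSE],
       C = xyz[s$atom_name == "C", , drop = FALSE])
}

# literal-loop distance-difference loss
brute_l_side <- function(Dc, Dr, thresholds = c(0.5, 1, 2, 4),
                         weights = rep(0.25, 4)) {
  n <- nrow(Dc)
  den <- 0
  num <- numeric(length(thresholds))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- abs(Dr[i, j] - Dc[i, j])
    den <- den + d
    for (k in seq_along(thresholds)) {
      num[k] <- num[k] + max(d - thresholds[k], 0)
    }
  }
  if (den == 0) return(0)
  sum(weights * num) / den
}

# literal-loop whole-structure loss (degrees, matching l_all's default)
brute_l_all <- function(pred, ref) {
  pb <- backbone_triples(pred)
  rb <- backbone_triples(ref)
  nr <- nrow(pb$N)
  geom <- 0
  ang <- function(A, B, C) {
    a <- A - B; b <- C - B
    acos(max(-1, min(1, sum(a * b) / sqrt(sum(a^2) * sum(b^2))))) * 180 / pi
  }
  for (i in seq_len(nr - 1)) {
    lc <- sqrt(sum((pb$N[i + 1, ] - pb$C[i, ])^2))
    lr <- sqrt(sum((rb$N[i + 1, ] - rb$C[i, ])^2))
    ac <- ang(pb$CA[i, ], pb$C[i, ], pb$N[i + 1, ])
    ar <- ang(rb$CA[i, ], rb$C[i, ], rb$N[i + 1, ])
    geom <- geom + abs(lc - lr) + abs(ac - ar)
  }
  brute_l_main(pred, ref) + geom
}

# exhaustive pairwise AUC
brute_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

random_rotation_matrix <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# small random structure with valid frames: a short synthetic complex
random_small_structure <- function(seed, n_res = 4) {
  cfg <- synth_config(n_complexes = 1, cdr3a_len = 11, cdr3b_len = 11,
                      peptide_len = 8, seed = seed)
  s <- make_precise_complex(cfg, 1)
  keep <- s$residue_index < n_res
  sub <- s[keep, ]
  sub$segment <- "CDR3A"
  tcr_structure(sub)
}

# hand-built single-residue structure from explicit atom records
manual_structure <- function(atom_name, xyz, residue_index = 0L,
                             residue_name = "ALA", segment = "CDR3A",
                             validate = TRUE) {
  n <- length(atom_name)
  tcr_structure(tibble::tibble(
    element = substr(atom_name, 1, 1),
    atom_name = atom_name,
    residue_index = rep_len(residue_index, n),
    residue_name = rep_len(residue_name, n),
    segment = rep_len(segment, n),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]), validate = validate)
}

expect_structures_equal <- function(a, b, tol = 1e-9) {
  expect_identical(a$atom_name, b$atom_name)
  expect_identical(a$residue_index, b$residue_index)
  expect_lt(max(abs(structure_coords(a) - structure_coords(b))), tol)
}
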