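#' Configuration for the synthetic complex generator
#'
#' The generator emulates pairs of (precise, predicted) CDR3A:CDR3B:peptide
#' structures and binding-labelled complexes with a planted geometric rule.
#' Backbones are laid out with canonical bond lengths (N-CA 1.46, CA-C 1.52,
#' C-N 1.33 Angstrom) along seeded helical curves; side chains are grown from
#' idealized residue templates. Predicted structures are emulated by adding
#' zero-mean Gaussian displacement with a larger standard deviation on
#' side-chain atoms than on main-chain atoms (mirroring the observation that
#' structure predictors do worse on side chains), plus a small global rigid
#' jitter.
#'
#' @param n_complexes Number of complexes in a dataset.
#' @param cdr3a_len,cdr3b_len CDR3 segment lengths in residues (11-18).
#' @param peptide_len Peptide length in residues (8-11).
#' @param main_noise_sd,side_noise_sd Gaussian displacement SD (Angstrom) for
#'   main-chain and side-chain atoms; `side_noise_sd >= main_noise_sd`.
#' @param binding_rule_radius Planted rule radius (Angstrom): a complex is a
#'   binder iff the peptide centroid lies within this distance of the
#'   midpoint of the two CDR3 centroids. Default 6.
#' @param jitter_rot_sd,jitter_trans_sd Global rigid jitter of the perturbed
#'   copy: rotation-angle SD (degrees) and per-axis translation SD (Angstrom).
#' @param n_peptides Number of distinct peptide identities in the pool.
#' @param seed Integer seed; the full dataset is a pure function of the
#'   configuration.
#'
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_complexes = 100L,
                         cdr3a_len = 13L, cdr3b_len = 14L, peptide_len = 9L,
                         main_noise_sd = 1.0, side_noise_sd = 2.0,
                         binding_rule_radius = 6.0,
                         jitter_rot_sd = 2.0, jitter_trans_sd = 0.5,
                         n_peptides = 8L, seed = 1L) {
  stopifnot(cdr3a_len >= 11, cdr3a_len <= 18,
            cdr3b_len >= 11, cdr3b_len <= 18,
            peptide_len >= 8, peptide_len <= 11)
  if (side_noise_sd < main_noise_sd) {
    abort("side_noise_sd must be >= main_noise_sd", class = "tcrcost_bad_config")
  }
  structure(list(n_complexes = as.integer(n_complexes),
                 cdr3a_len = as.integer(cdr3a_len),
                 cdr3b_len = as.integer(cdr3b_len),
                 peptide_len = as.integer(peptide_len),
                 main_noise_sd = main_noise_sd,
                 side_noise_sd = side_noise_sd,
                 binding_rule_radius = binding_rule_radius,
                 jitter_rot_sd = jitter_rot_sd,
                 jitter_trans_sd = jitter_trans_sd,
                 n_peptides = as.integer(n_peptides),
                 seed = as.integer(seed)),
            class = "synth_config")
}

AA20 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")

SIDE_CHAIN_PARENTS <- list(
  ALA = c(CB = "CA"),
  ARG = c(CB = "CA", CG = "CB", CD = "CG", NE = "CD", CZ = "NE",
          NH1 = "CZ", NH2 = "CZ"),
  ASN = c(CB = "CA", CG = "CB", OD1 = "CG", ND2 = "CG"),
  ASP = c(CB = "CA", CG = "CB", OD1 = "CG", OD2 = "CG"),
  CYS = c(CB = "CA", SG = "CB"),
  GLN = c(CB = "CA", CG = "CB", CD = "CG", OE1 = "CD", NE2 = "CD"),
  GLU = c(CB = "CA", CG = "CB", CD = "CG", OE1 = "CD", OE2 = "CD"),
  GLY = c(),
  HIS = c(CB = "CA", CG = "CB", ND1 = "CG", CD2 = "CG", CE1 = "ND1",
          NE2 = "CD2"),
  ILE = c(CB = "CA", CG1 = "CB", CG2 = "CB", CD1 = "CG1"),
  LEU = c(CB = "CA", CG = "CB", CD1 = "CG", CD2 = "CG"),
  LYS = c(CB = "CA", CG = "CB", CD = "CG", CE = "CD", NZ = "CE"),
  MET = c(CB = "CA", CG = "CB", SD = "CG", CE = "SD"),
  PHE = c(CB = "CA", CG = "CB", CD1 = "CG", CD2 = "CG", CE1 = "CD1",
          CE2 = "CD2", CZ = "CE1"),
  PRO = c(CB = "CA", CG = "CB", CD = "CG"),
  SER = c(CB = "CA", OG = "CB"),
  THR = c(CB = "CA", OG1 = "CB", CG2 = "CB"),
  TRP = c(CB = "CA", CG = "CB", CD1 = "CG", CD2 = "CG", NE1 = "CD1",
          CE2 = "CD2", CE3 = "CD2", CZ2 = "CE2", CZ3 = "CE3", CH2 = "CZ2"),
  TYR = c(CB = "CA", CG = "CB", CD1 = "CG", CD2 = "CG", CE1 = "CD1",
          CE2 = "CD2", CZ = "CE1", OH = "CZ"),
  VAL = c(CB = "CA", CG1 = "CB", CG2 = "CB")
)

BOND_LENGTH_BY_ELEMENT <- c(C = 1.52, N = 1.47, O = 1.40, S = 1.81)

# place atom D bonded to C with |CD| = len, angle(B, C, D) = ang (degrees)
# and dihedral(A, B, C, D) = dih (degrees)
place_atom <- function(A, B, C, len, ang, dih) {
  th <- ang * pi / 180
  chi <- dih * pi / 180
  bc <- C - B
  bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  C + len * (-bc * cos(th) + m * sin(th) * cos(chi) + n * sin(th) * sin(chi))
}

# idealized helical segment with side chains; returns a bare atom tibble
build_segment <- function(residues, segment, residue_offset) {
  L <- length(residues)
  phi <- -57 + runif(L, -8, 8)
  psi <- -47 + runif(L, -8, 8)
  N <- CA <- CC <- O <- matrix(0, L, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(1.46, 0, 0)
  CC[1, ] <- CA[1, ] + 1.52 * c(cos(69 * pi / 180), sin(69 * pi / 180), 0)
  for (i in seq_len(L)) {
    if (i > 1) {
      N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], CC[i - 1, ],
                           1.33, 116, psi[i - 1])
      CA[i, ] <- place_atom(CA[i - 1, ], CC[i - 1, ], N[i, ], 1.46, 121.7, 180)
      CC[i, ] <- place_atom(CC[i - 1, ], N[i, ], CA[i, ], 1.52, 111, phi[i])
    }
    O[i, ] <- place_atom(N[i, ], CA[i, ], CC[i, ], 1.23, 121, psi[i] + 180)
  }
  rows <- vector("list", L)
  for (i in seq_len(L)) {
    res <- residues[i]
    pos <- list(N = N[i, ], CA = CA[i, ], C = CC[i, ], O = O[i, ])
    parents <- SIDE_CHAIN_PARENTS[[res]]
    names_sc <- names(parents)
    n_child <- integer(0)
    for (a in names_sc) {
      p1 <- parents[[a]]
      elem <- substr(a, 1, 1)
      len <- BOND_LENGTH_BY_ELEMENT[[elem]]
      k <- if (is.null(n_child[p1]) || is.na(n_child[p1])) 0L else n_child[p1]
      n_child[p1] <- k + 1L
      dih <- 180 - k * 120 + runif(1, -15, 15)
      if (p1 == "CA") {
        pos[[a]] <- place_atom(pos$C, pos$N, pos$CA, len, 110, -122 + runif(1, -8, 8))
      } else {
        p2 <- if (p1 == "CB") "CA" else parents[[p1]]
        p3 <- if (p2 == "CA") "N" else if (p2 == "CB") "CA" else parents[[p2]]
        pos[[a]] <- place_atom(pos[[p3]], pos[[p2]], pos[[p1]], len, 111, dih)
      }
    }
    atom_names <- c(MAIN_CHAIN_ATOMS, names_sc)
    xyz <- do.call(rbind, pos[atom_names])
    rows[[i]] <- tibble(
      element = substr(atom_names, 1, 1),
      atom_name = atom_names,
      residue_index = residue_offset + i - 1L,
      residue_name = res,
      segment = segment,
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  }
  dplyr::bind_rows(rows)
}

random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

rotation_about_axis <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

recenter_rotate <- function(df, center) {
  xyz <- as.matrix(df[, c("x", "y", "z")])
  xyz <- sweep(xyz, 2, colMeans(xyz))
  xyz <- xyz %*% t(random_rotation())
  xyz <- sweep(xyz, 2, center, "+")
  df$x <- xyz[, 1]; df$y <- xyz[, 2]; df$z <- xyz[, 3]
  df
}

peptide_pool <- function(cfg) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed %% .Machine$integer.max)
  lapply(seq_len(cfg$n_peptides), function(i) {
    sample(AA20, cfg$peptide_len, replace = TRUE)
  })
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

complex_seed <- function(cfg, index, salt = 0L) {
  as.integer((as.double(cfg$seed) * 7919 + index * 104729 + salt * 15485863) %%
               2147483647)
}

#' Generate one idealized ("precise") synthetic complex
#'
#' Builds the three segments from idealized residue templates along seeded
#' helical curves and places the peptide either inside or outside the
#' inter-CDR3 groove according to the planted binding rule: label 1 iff the
#' peptide centroid is within `binding_rule_radius` of the midpoint of the
#' two CDR3 centroids. Complexes with odd `index` are binders, so a dataset
#' over consecutive indices is label-balanced by construction.
#'
#' @param cfg A [synth_config()].
#' @param index Complex index (1-based); the structure is a pure function of
#'   `(cfg, index)`.
#' @return A [tcr_structure()] with attributes `tcr_id`, `peptide_id` and
#'   `label` (0/1).
#' @export
make_precise_complex <- function(cfg, index) {
  pool <- peptide_pool(cfg)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(complex_seed(cfg, index))
  label <- as.integer(index %% 2L == 1L)
  pep_i <- sample.int(cfg$n_peptides, 1)
  seq_a <- sample(AA20, cfg$cdr3a_len, replace = TRUE)
  seq_b <- sample(AA20, cfg$cdr3b_len, replace = TRUE)
  seg_a <- build_segment(seq_a, "CDR3A", 0L)
  seg_b <- build_segment(seq_b, "CDR3B", cfg$cdr3a_len)
  seg_p <- build_segment(pool[[pep_i]], "peptide",
                         cfg$cdr3a_len + cfg$cdr3b_len)
  seg_a <- recenter_rotate(seg_a, c(-5.5, 0, 0))
  seg_b <- recenter_rotate(seg_b, c(5.5, 0, 0))
  dir <- rnorm(3)
  dir <- dir / sqrt(sum(dir^2))
  r <- if (label == 1L) runif(1, 0, 0.5 * cfg$binding_rule_radius) else
    runif(1, cfg$binding_rule_radius + 5, cfg$binding_rule_radius + 8)
  seg_p <- recenter_rotate(seg_p, r * dir)
  s <- tcr_structure(dplyr::bind_rows(seg_a, seg_b, seg_p))
  attr(s, "tcr_id") <- sprintf("tcr%04d", index)
  attr(s, "peptide_id") <- sprintf("pep%02d", pep_i)
  attr(s, "label") <- label
  s
}

#' Emulate a low-quality predicted copy of a structure
#'
#' Adds seeded zero-mean isotropic Gaussian displacement with standard
#' deviation `main_noise_sd` to main-chain atoms and `side_noise_sd` to
#' side-chain atoms, then applies one global random rigid jitter (rotation
#' about the centroid plus translation). Atom content is unchanged.
#'
#' @param s A [tcr_structure()].
#' @param cfg A [synth_config()] providing the noise amplitudes.
#' @param seed Integer seed for the perturbation draw.
#' @return The perturbed [tcr_structure()].
#' @export
perturb_structure <- function(s, cfg, seed = cfg$seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  xyz <- structure_coords(s)
  n <- nrow(xyz)
  noise <- matrix(rnorm(3 * n), n, 3)
  sds <- ifelse(s$is_main_chain, cfg$main_noise_sd, cfg$side_noise_sd)
  xyz <- xyz + noise * sds
  if (cfg$jitter_rot_sd > 0 || cfg$jitter_trans_sd > 0) {
    axis <- rnorm(3)
    angle <- rnorm(1, 0, cfg$jitter_rot_sd)
    shift <- rnorm(3, 0, cfg$jitter_trans_sd)
    ctr <- colMeans(xyz)
    R <- rotation_about_axis(axis, angle)
    xyz <- sweep(sweep(xyz, 2, ctr) %*% t(R), 2, ctr + shift, "+")
  }
  out <- set_structure_coords(s, xyz)
  attributes(out)[c("tcr_id", "peptide_id", "label")] <-
    attributes(s)[c("tcr_id", "peptide_id", "label")]
  out
}

#' Generate a binding-labelled synthetic dataset
#'
#' @param cfg A [synth_config()] with `n_complexes >= 4`.
#' @param dir Optional directory; when given, per-complex PDB files and a
#'   `manifest.tsv` (file, tcr_id, peptide_id, label) are written there.
#' @return A tibble with columns `tcr_id`, `peptide_id`, `label` and the
#'   list-column `structure`.
#' @export
make_binding_dataset <- function(cfg, dir = NULL) {
  stopifnot(cfg$n_complexes >= 4)
  rows <- lapply(seq_len(cfg$n_complexes), function(i) {
    s <- make_precise_complex(cfg, i)
    tibble(tcr_id = attr(s, "tcr_id"),
           peptide_id = attr(s, "peptide_id"),
           label = attr(s, "label"),
           structure = list(s))
  })
  ds <- dplyr::bind_rows(rows)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- sprintf("%s.pdb", ds$tcr_id)
    for (i in seq_len(nrow(ds))) {
      write_pdb(ds$structure[[i]], file.path(dir, files[i]))
    }
    manifest <- dplyr::select(dplyr::mutate(ds, file = files), -"structure")
    utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  ds
}

#' Generate (predicted, precise) training pairs for the correction module
#'
#' @param cfg A [synth_config()].
#' @param n Number of pairs (default `cfg$n_complexes`).
#' @param index_offset Offset added to the complex indices, so that disjoint
#'   train/held-out sets can be drawn from one configuration.
#' @return A tibble with columns `pair_id` and list-columns `precise` and
#'   `predicted` (atom-aligned by construction).
#' @export
make_correction_pairs <- function(cfg, n = cfg$n_complexes, index_offset = 0L) {
  rows <- lapply(seq_len(n), function(i) {
    idx <- i + index_offset
    s <- make_precise_complex(cfg, idx)
    p <- perturb_structure(s, cfg, seed = complex_seed(cfg, idx, salt = 1L))
    tibble(pair_id = attr(s, "tcr_id"), precise = list(s), predicted = list(p))
  })
  dplyr::bind_rows(rows)
}

#' Write a full synthetic dataset to disk
#'
#' Produces `precise/*.pdb`, `predicted/*.pdb` and a `manifest.tsv` with
#' tcr/peptide identities and binding labels.
#'
#' @param cfg A [synth_config()].
#' @param dir Output directory.
#' @return The manifest tibble, invisibly.
#' @export
write_synth_dataset <- function(cfg, dir) {
  dir.create(file.path(dir, "precise"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "predicted"), recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_len(cfg$n_complexes), function(i) {
    s <- make_precise_complex(cfg, i)
    p <- perturb_structure(s, cfg, seed = complex_seed(cfg, i, salt = 1L))
    f <- sprintf("%s.pdb", attr(s, "tcr_id"))
    write_pdb(s, file.path(dir, "precise", f))
    write_pdb(p, file.path(dir, "predicted", f))
    tibble(file = f, tcr_id = attr(s, "tcr_id"),
           peptide_id = attr(s, "peptide_id"), label = attr(s, "label"))
  })
  manifest <- dplyr::bind_rows(rows)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
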