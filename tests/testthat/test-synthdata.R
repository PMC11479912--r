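test_that("generated complexes satisfy structural invariants", {
  cfg <- synth_config(seed = 3)
  for (i in 1:3) {
    s <- make_precise_complex(cfg, i)
    expect_s3_class(s, "tcr_structure")
    expect_equal(n_residues(s), cfg$cdr3a_len + cfg$cdr3b_len + cfg$peptide_len)
    expect_identical(sort(unique(s$segment)),
                     sort(c("CDR3A", "CDR3B", "peptide")))
    # backbone completeness is enforced by the constructor; frames exist
    expect_no_error(build_frames(s))
  }
})

test_that("pre-noise peptide bonds are canonical within each segment", {
  cfg <- synth_config(seed = 9)
  s <- make_precise_complex(cfg, 2)
  g <- bond_geometry(s)
  seg_of_res <- tapply(as.character(s$segment), s$residue_index,
                       function(z) z[1])
  within <- seg_of_res[-length(seg_of_res)] == seg_of_res[-1]
  expect_true(all(abs(g$length[within] - 1.33) <= 0.01))
})

test_that("generation is a pure function of (config, index)", {
  cfg <- synth_config(seed = 17)
  a <- make_precise_complex(cfg, 5)
  b <- make_precise_complex(cfg, 5)
  expect_identical(structure_coords(a), structure_coords(b))
  expect_identical(attr(a, "peptide_id"), attr(b, "peptide_id"))
  c2 <- make_precise_complex(cfg, 6)
  expect_false(isTRUE(all.equal(dim(structure_coords(a)),
                                dim(structure_coords(c2)))) &&
                 isTRUE(all.equal(structure_coords(a), structure_coords(c2))))
})

test_that("zero noise and zero jitter reproduce the input exactly", {
  cfg0 <- synth_config(main_noise_sd = 0, side_noise_sd = 0,
                       jitter_rot_sd = 0, jitter_trans_sd = 0, seed = 4)
  s <- make_precise_complex(cfg0, 1)
  p <- perturb_structure(s, cfg0, seed = 99)
  expect_identical(structure_coords(p), structure_coords(s))
})

test_that("pure isotropic noise gives rmsd near sqrt(3) * sd", {
  # single noise scale, no rigid jitter, enough atoms for concentration
  cfg <- synth_config(cdr3a_len = 18, cdr3b_len = 18, peptide_len = 10,
                      main_noise_sd = 1.5, side_noise_sd = 1.5,
                      jitter_rot_sd = 0, jitter_trans_sd = 0, seed = 6)
  s <- make_precise_complex(cfg, 1)
  expect_gte(n_atoms(s), 300)
  p <- perturb_structure(s, cfg, seed = 10)
  expect_equal(rmsd(p, s), sqrt(3) * 1.5, tolerance = 0.1)
})

test_that("side chains are perturbed more than main chains on average", {
  cfg <- synth_config(seed = 2)
  s <- make_precise_complex(cfg, 1)
  wins <- 0
  for (k in 1:20) {
    p <- perturb_structure(s, cfg, seed = k)
    main <- s$is_main_chain
    r_main <- rmsd(structure_coords(p)[main, ], structure_coords(s)[main, ])
    r_side <- rmsd(structure_coords(p)[!main, ], structure_coords(s)[!main, ])
    wins <- wins + (r_side >= r_main)
  }
  expect_gte(wins, 16)
})

test_that("the correction task is non-trivial but solvable", {
  cfg <- synth_config(seed = 44)
  s <- make_precise_complex(cfg, 1)
  p <- perturb_structure(s, cfg, seed = 3)
  expect_gt(rmsd(p, s), 0)
  # an oracle that returns the precise coordinates achieves zero error
  oracle <- p
  xyz <- structure_coords(s)
  oracle$x <- xyz[, 1]; oracle$y <- xyz[, 2]; oracle$z <- xyz[, 3]
  expect_identical(rmsd(oracle, s), 0)
})

test_that("doubling the noise amplitude does not reduce the distortion", {
  cfg1 <- synth_config(seed = 5)
  cfg2 <- synth_config(main_noise_sd = 2, side_noise_sd = 4, seed = 5)
  s <- make_precise_complex(cfg1, 1)
  r1 <- mean(sapply(1:5, function(k) rmsd(perturb_structure(s, cfg1, k), s)))
  r2 <- mean(sapply(1:5, function(k) rmsd(perturb_structure(s, cfg2, k), s)))
  expect_gte(r2, r1)
})

test_that("binding datasets are balanced and the planted rule is recoverable", {
  cfg <- synth_config(n_complexes = 40, seed = 13)
  ds <- make_binding_dataset(cfg)
  expect_equal(nrow(ds), 40)
  expect_equal(mean(ds$label), 0.5)
  expect_gte(length(unique(ds$peptide_id)), 2)

  # the label is exactly the centroid-distance rule on noiseless structures
  rule <- vapply(ds$structure, function(s) {
    xyz <- structure_coords(s)
    ctr <- function(seg) colMeans(xyz[s$segment == seg, , drop = FALSE])
    mid <- (ctr("CDR3A") + ctr("CDR3B")) / 2
    as.integer(sqrt(sum((ctr("peptide") - mid)^2)) <= cfg$binding_rule_radius)
  }, integer(1))
  expect_identical(rule, ds$label)
})

test_that("all fixtures fit the 48 Angstrom voxel cube with no drops", {
  cfg <- synth_config(n_complexes = 10, seed = 23)
  ds <- make_binding_dataset(cfg)
  for (s in ds$structure) {
    vg <- voxelize(s)
    expect_identical(vg$dropped, 0L)
  }
  p <- perturb_structure(ds$structure[[2]], cfg, seed = 1)
  expect_identical(voxelize(p)$dropped, 0L)
})

test_that("datasets round-trip through PDB files and the manifest", {
  cfg <- synth_config(n_complexes = 4, seed = 31)
  dir <- withr::local_tempdir()
  manifest <- write_synth_dataset(cfg, dir)
  expect_setequal(c("file", "tcr_id", "peptide_id", "label"), names(manifest))
  ds <- make_binding_dataset(cfg)
  for (i in seq_len(nrow(manifest))) {
    s <- parse_pdb(file.path(dir, "precise", manifest$file[i]))
    expect_structures_equal(s, ds$structure[[i]], tol = 5e-4)
    p <- parse_pdb(file.path(dir, "predicted", manifest$file[i]))
    expect_identical(p$atom_name, s$atom_name)
  }
})
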