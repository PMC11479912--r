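#' Atom-table representation of a CDR3A:CDR3B:peptide complex
#'
#' A `tcr_structure` is a tibble with one row per heavy atom and columns
#' `element`, `atom_name`, `residue_index` (0-based position in the
#' concatenated CDR3A + CDR3B + peptide sequence), `residue_name` (3-letter
#' code), `segment` (one of `"CDR3A"`, `"CDR3B"`, `"peptide"`), `x`, `y`,
#' `z` (Angstrom) and `is_main_chain` (`TRUE` for backbone N, CA, C, O).
#' Atoms are stored residue by residue; within a residue the backbone atoms
#' come first (N, CA, C, O) followed by the side-chain atoms.
#'
#' @param atoms A data frame with the columns listed above (`is_main_chain`
#'   is derived from `atom_name` if absent).
#' @param validate Check structural invariants (backbone completeness,
#'   finite coordinates, non-decreasing residue index)?
#'
#' @return A `tcr_structure` tibble.
#' @export
tcr_structure <- function(atoms, validate = TRUE) {
  atoms <- as_tibble(atoms)
  required <- c("element", "atom_name", "residue_index", "residue_name",
                "segment", "x", "y", "z")
  missing <- setdiff(required, names(atoms))
  if (length(missing) > 0) {
    abort(paste0("missing column(s): ", paste(missing, collapse = ", ")),
          class = "tcrcost_bad_structure")
  }
  atoms$residue_index <- as.integer(atoms$residue_index)
  atoms$is_main_chain <- atoms$atom_name %in% MAIN_CHAIN_ATOMS
  out <- structure(atoms, class = c("tcr_structure", class(tibble())))
  if (validate) validate_structure(out)
  out
}

validate_structure <- function(s) {
  xyz <- as.matrix(s[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) {
    abort("non-finite coordinates in structure", class = "tcrcost_bad_structure")
  }
  if (is.unsorted(s$residue_index)) {
    abort("residue_index must be non-decreasing along the atom list",
          class = "tcrcost_bad_structure")
  }
  if (!all(s$segment %in% SEGMENT_LEVELS)) {
    abort("segment must be one of CDR3A, CDR3B, peptide",
          class = "tcrcost_bad_structure")
  }
  by_res <- split(s$atom_name, s$residue_index)
  for (ri in names(by_res)) {
    miss <- setdiff(c("N", "CA", "C"), by_res[[ri]])
    if (length(miss) > 0) {
      abort(sprintf("residue %s is missing backbone atom(s): %s",
                    ri, paste(miss, collapse = ", ")),
            class = "tcrcost_missing_backbone")
    }
  }
  invisible(s)
}

#' @export
print.tcr_structure <- function(x, ...) {
  cat(sprintf("<tcr_structure: %d atoms, %d residues (%s)>\n",
              n_atoms(x), n_residues(x),
              paste(unique(x$segment), collapse = "+")))
  NextMethod()
}

#' Atom and residue counts
#'
#' @param s A [tcr_structure()].
#' @return An integer count.
#' @export
n_atoms <- function(s) nrow(s)

#' @rdname n_atoms
#' @export
n_residues <- function(s) length(unique(s$residue_index))

#' Coordinate matrix of a structure
#'
#' @param s A [tcr_structure()].
#' @return An `n_atoms x 3` numeric matrix (Angstrom).
#' @export
structure_coords <- function(s) {
  unname(as.matrix(s[, c("x", "y", "z")]))
}

set_structure_coords <- function(s, xyz) {
  stopifnot(nrow(xyz) == nrow(s))
  s$x <- xyz[, 1]
  s$y <- xyz[, 2]
  s$z <- xyz[, 3]
  s
}

# order atoms canonically: segments in CDR3A/CDR3B/peptide order, residues by
# index, backbone (N, CA, C, O) first within each residue, side-chain atoms
# keeping their current relative order
canonicalize_structure <- function(s) {
  seg <- match(s$segment, SEGMENT_LEVELS)
  bb <- match(s$atom_name, MAIN_CHAIN_ATOMS)
  bb[is.na(bb)] <- length(MAIN_CHAIN_ATOMS) + 1L
  ord <- order(seg, s$residue_index, bb, seq_len(nrow(s)))
  s[ord, ]
}

#' Parse a PDB file into a structure table
#'
#' Reads ATOM records (hydrogens are dropped), maps PDB chain identifiers to
#' the three segments of the complex, renumbers residues 0-based along the
#' concatenated CDR3A + CDR3B + peptide sequence and orders atoms
#' canonically (backbone N, CA, C, O first within each residue).
#'
#' @param pdb Either a path to a PDB file or a character scalar/vector of
#'   PDB-format text.
#' @param chain_id_map Named character vector mapping PDB chain IDs to
#'   segments; default `c(A = "CDR3A", B = "CDR3B", C = "peptide")`.
#'
#' @return A [tcr_structure()].
#' @export
parse_pdb <- function(pdb, chain_id_map = default_chain_id_map()) {
  path <- pdb_as_path(pdb)
  lines <- readLines(path, warn = FALSE)
  if (!any(startsWith(lines, "ATOM"))) {
    abort("no ATOM records found in PDB input", class = "tcrcost_bad_pdb")
  }
  parsed <- bio3d::read.pdb(path, verbose = FALSE)
  at <- parsed$atom[parsed$atom$type == "ATOM", , drop = FALSE]
  elem <- trimws(at$elesy)
  guess <- substr(trimws(at$elety), 1, 1)
  elem[is.na(elem) | elem == ""] <- guess[is.na(elem) | elem == ""]
  keep <- toupper(elem) != "H"
  at <- at[keep, , drop = FALSE]
  elem <- elem[keep]
  chains <- trimws(at$chain)
  unknown <- setdiff(unique(chains), names(chain_id_map))
  if (length(unknown) > 0) {
    abort(sprintf("PDB chain(s) not in chain_id_map: %s",
                  paste(unknown, collapse = ", ")),
          class = "tcrcost_bad_pdb")
  }
  seg <- unname(chain_id_map[chains])
  # residue key within segment, then 0-based index over the concatenation
  key <- paste(seg, at$resno, at$insert, sep = "|")
  first <- !duplicated(key)
  u_key <- key[first]
  u_ord <- order(match(seg[first], SEGMENT_LEVELS), at$resno[first])
  ridx <- match(key, u_key[u_ord]) - 1L
  s <- tcr_structure(tibble(
    element = elem,
    atom_name = trimws(at$elety),
    residue_index = ridx,
    residue_name = trimws(at$resid),
    segment = seg,
    x = at$x, y = at$y, z = at$z
  ), validate = FALSE)
  s <- canonicalize_structure(s)
  validate_structure(s)
  s
}

pdb_as_path <- function(pdb) {
  if (length(pdb) == 1 && !grepl("\n", pdb) && file.exists(pdb)) return(pdb)
  txt <- if (length(pdb) == 1) strsplit(pdb, "\n", fixed = TRUE)[[1]] else pdb
  path <- tempfile(fileext = ".pdb")
  writeLines(txt, path)
  path
}

#' Write a structure as a PDB file
#'
#' Emits fixed-width ATOM records (one per heavy atom, occupancy 1.00,
#' B-factor 0.00), a TER record per segment and END. Coordinates are written
#' with three decimals, the precision of the PDB format.
#'
#' @param s A [tcr_structure()].
#' @param path Output file path.
#' @param chain_id_map Named character vector mapping PDB chain IDs to
#'   segments (inverted for writing).
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path, chain_id_map = default_chain_id_map()) {
  seg_to_chain <- setNames(names(chain_id_map), unname(chain_id_map))
  lines <- character(0)
  serial <- 0L
  for (segment in intersect(SEGMENT_LEVELS, unique(s$segment))) {
    ss <- s[s$segment == segment, , drop = FALSE]
    chain <- seg_to_chain[[segment]]
    # per-segment 1-based residue numbering
    resno <- match(ss$residue_index, unique(ss$residue_index))
    for (i in seq_len(nrow(ss))) {
      serial <- serial + 1L
      name <- ss$atom_name[i]
      name_fmt <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
      lines <- c(lines, sprintf(
        "ATOM  %5d %4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, name_fmt, ss$residue_name[i], chain, resno[i],
        ss$x[i], ss$y[i], ss$z[i], 1, 0, ss$element[i]))
    }
    lines <- c(lines, sprintf("TER   %5d      %3s %s%4d",
                              serial + 1L, ss$residue_name[nrow(ss)],
                              chain, resno[length(resno)]))
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Align the atom order of a precise/predicted structure pair
#'
#' Both structures are put into the canonical atom order and the predicted
#' structure's side-chain atoms are reordered within each residue to match
#' the precise structure, so that atom pairing is positional thereafter.
#' Coordinates are never modified.
#'
#' @param precise,predicted [tcr_structure()] objects with identical residue
#'   content and identical atom content per residue.
#' @return A list with elements `precise` and `predicted`.
#' @export
align_atom_order <- function(precise, predicted) {
  precise <- canonicalize_structure(precise)
  predicted <- canonicalize_structure(predicted)
  key_p <- residue_key(precise)
  key_q <- residue_key(predicted)
  if (!identical(key_p, key_q)) {
    abort("residue sequences differ between the two structures",
          class = "tcrcost_align_error")
  }
  pieces <- vector("list", length(key_p))
  split_p <- split(seq_len(nrow(precise)), precise$residue_index)
  split_q <- split(seq_len(nrow(predicted)), predicted$residue_index)
  for (k in seq_along(split_p)) {
    ip <- split_p[[k]]
    iq <- split_q[[k]]
    names_p <- precise$atom_name[ip]
    names_q <- predicted$atom_name[iq]
    if (!setequal(names_p, names_q) || length(ip) != length(iq)) {
      abort(sprintf(
        "atom content differs in residue %d (%s): precise has {%s}, predicted has {%s}",
        precise$residue_index[ip[1]], precise$residue_name[ip[1]],
        paste(names_p, collapse = ","), paste(names_q, collapse = ",")),
        class = "tcrcost_align_error")
    }
    pieces[[k]] <- iq[match(names_p, names_q)]
  }
  predicted <- predicted[unlist(pieces), ]
  list(precise = precise, predicted = predicted)
}

residue_key <- function(s) {
  first <- !duplicated(s$residue_index)
  paste(s$segment[first], s$residue_index[first], s$residue_name[first])
}

#' Pad or truncate a structure's coordinates to fixed length
#'
#' Coordinates are laid out in canonical atom order; structures longer than
#' `max_atoms` are truncated (with a message) and shorter ones are
#' zero-padded, with a logical mask marking real atoms.
#'
#' @param s A [tcr_structure()].
#' @param max_atoms Fixed coordinate length (default 400).
#' @return An object of class `padded_coords`: a list with `coords`
#'   (`max_atoms x 3` matrix) and `mask` (length-`max_atoms` logical).
#' @export
pad_truncate <- function(s, max_atoms = 400L) {
  s <- canonicalize_structure(s)
  xyz <- structure_coords(s)
  n <- nrow(xyz)
  if (n > max_atoms) {
    inform(sprintf("structure truncated from %d to %d atoms", n, max_atoms))
    xyz <- xyz[seq_len(max_atoms), , drop = FALSE]
    n <- max_atoms
  }
  coords <- matrix(0, max_atoms, 3)
  coords[seq_len(n), ] <- xyz
  mask <- c(rep(TRUE, n), rep(FALSE, max_atoms - n))
  structure(list(coords = coords, mask = mask), class = "padded_coords")
}

#' Main-chain and side-chain membership matrices
#'
#' Builds the binary matrices `Mm` (`max_atoms x main_capacity`) and `Ms`
#' (`max_atoms x max_atoms`): `Mm[i, j] = 1` when the i-th atom of the
#' padded input is the j-th main-chain atom, and likewise `Ms` for
#' side-chain atoms. `t(Mm) %*% X` therefore extracts main-chain
#' coordinates in order and `Mm %*% Xm + Ms %*% Xs` re-interleaves the two
#' chains into the original atom order.
#'
#' @param s A [tcr_structure()] with at most `max_atoms` atoms.
#' @param max_atoms Padded input length (default 400).
#' @param main_capacity Number of main-chain slots (default 150).
#' @return An object of class `chain_masks`: list with matrices `Mm`, `Ms`
#'   and integer attribute vectors `main_idx`, `side_idx` giving the padded
#'   row index of each main-/side-chain atom.
#' @export
build_chain_masks <- function(s, max_atoms = 400L, main_capacity = 150L) {
  s <- canonicalize_structure(s)
  if (nrow(s) > max_atoms) {
    abort(sprintf("structure has %d atoms; at most %d supported (truncate first)",
                  nrow(s), max_atoms), class = "tcrcost_capacity")
  }
  main_idx <- which(s$is_main_chain)
  side_idx <- which(!s$is_main_chain)
  if (length(main_idx) > main_capacity) {
    abort(sprintf("%d main-chain atoms exceed the capacity of %d",
                  length(main_idx), main_capacity),
          class = "tcrcost_capacity")
  }
  Mm <- matrix(0, max_atoms, main_capacity)
  Ms <- matrix(0, max_atoms, max_atoms)
  if (length(main_idx) > 0) Mm[cbind(main_idx, seq_along(main_idx))] <- 1
  if (length(side_idx) > 0) Ms[cbind(side_idx, seq_along(side_idx))] <- 1
  structure(list(Mm = Mm, Ms = Ms),
            main_idx = main_idx, side_idx = side_idx,
            class = "chain_masks")
}

# light-weight index form used by the correction network
mask_indices <- function(s) {
  s <- canonicalize_structure(s)
  list(main = which(s$is_main_chain), side = which(!s$is_main_chain))
}

#' Apply a rigid transform to a structure
#'
#' @param s A [tcr_structure()].
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 numeric vector (Angstrom).
#' @return The transformed structure.
#' @export
transform_structure <- function(s, rotation = diag(3), translation = c(0, 0, 0)) {
  xyz <- structure_coords(s) %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, "+")
  set_structure_coords(s, xyz)
}
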