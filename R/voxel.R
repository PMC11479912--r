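#' Rasterize a structure onto the feature voxel grid
#'
#' The grid is a cube of `grid_size` voxels per axis with `voxel_size`
#' Angstrom spacing, centred on the heavy-atom centroid of the complex
#' (origin = centroid - grid extent / 2). Each atom is assigned to the
#' voxel containing it and contributes its eight feature values to the
#' corresponding channels; collisions accumulate by summation, so channel
#' sums are conserved whenever no atom falls outside the cube. Atoms
#' outside the cube are dropped and counted.
#'
#' @param s A [tcr_structure()].
#' @param features Optional feature tibble from [atom_features()]; computed
#'   from `s` if missing.
#' @param grid_size Voxels per axis (default 48).
#' @param voxel_size Voxel edge length in Angstrom (default 1).
#' @return An object of class `voxel_grid`: list with `grid`
#'   (`grid_size^3 x 8` array, dims `c(g, g, g, 8)`), `origin` (3-vector)
#'   and `dropped` (count of out-of-bounds atoms).
#' @export
voxelize <- function(s, features = NULL, grid_size = 48L, voxel_size = 1) {
  g <- as.integer(grid_size)
  grid <- array(0, c(g, g, g, length(FEATURE_NAMES)))
  if (nrow(s) == 0) {
    return(structure(list(grid = grid, origin = c(0, 0, 0), dropped = 0L),
                     class = "voxel_grid"))
  }
  if (is.null(features)) features <- atom_features(s)
  Fm <- as.matrix(features[, FEATURE_NAMES])
  xyz <- structure_coords(s)
  ctr <- colMeans(xyz)
  origin <- ctr - g * voxel_size / 2
  ijk <- floor(sweep(xyz, 2, origin) / voxel_size)
  inb <- rowSums(ijk >= 0 & ijk <= g - 1) == 3
  dropped <- sum(!inb)
  if (dropped > 0) {
    inform(sprintf("%d atom(s) outside the %d Angstrom cube were dropped",
                   dropped, g))
  }
  if (any(inb)) {
    lin <- 1 + ijk[inb, 1] + g * (ijk[inb, 2] + g * ijk[inb, 3])
    acc <- rowsum(Fm[inb, , drop = FALSE], lin)
    flat <- matrix(grid, g^3, length(FEATURE_NAMES))
    flat[as.integer(rownames(acc)), ] <- acc
    grid <- array(flat, c(g, g, g, length(FEATURE_NAMES)))
  }
  structure(list(grid = grid, origin = origin, dropped = dropped),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<voxel_grid: %dx%dx%dx%d, %d occupied voxels, %d dropped atoms>\n",
              d[1], d[2], d[3], d[4],
              sum(rowSums(matrix(x$grid, prod(d[1:3]), d[4]) != 0) > 0),
              x$dropped))
  invisible(x)
}

# average-pool a voxel grid by an integer factor; returns (nvox, C) matrix
pool_voxel_grid <- function(vg, factor = 1L) {
  g <- dim(vg$grid)[1]
  C <- dim(vg$grid)[4]
  if (factor <= 1L) return(matrix(vg$grid, g^3, C))
  gp <- g %/% factor
  out <- array(0, c(gp, gp, gp, C))
  for (dx in seq_len(factor)) for (dy in seq_len(factor)) for (dz in seq_len(factor)) {
    out <- out + vg$grid[seq(dx, g, factor), seq(dy, g, factor),
                         seq(dz, g, factor), , drop = FALSE]
  }
  matrix(out / factor^3, gp^3, C)
}

#' Write or read a portable container of binding samples
#'
#' Each sample stores the atom coordinates (`coords`, n x 3), the eight
#' per-atom features (`features`, n x 8), the binary `label` and the
#' `peptide_id` / `tcr_id` strings, mirroring the on-disk layout used for
#' training data.
#'
#' @param data A tibble with columns `structure`, `label`, `tcr_id`,
#'   `peptide_id` (see [make_binding_dataset()]).
#' @param path Container file path.
#' @return `path` (write) or the reconstructed tibble (read).
#' @export
write_binding_samples <- function(data, path) {
  samples <- lapply(seq_len(nrow(data)), function(i) {
    s <- data$structure[[i]]
    list(coords = structure_coords(s),
         atom_name = s$atom_name, residue_index = s$residue_index,
         residue_name = s$residue_name, segment = s$segment,
         features = as.matrix(atom_features(s)),
         label = data$label[i], tcr_id = data$tcr_id[i],
         peptide_id = data$peptide_id[i])
  })
  saveRDS(samples, path)
  invisible(path)
}

#' @rdname write_binding_samples
#' @export
read_binding_samples <- function(path) {
  samples <- readRDS(path)
  dplyr::bind_rows(lapply(samples, function(sm) {
    s <- tcr_structure(tibble(
      element = substr(sm$atom_name, 1, 1),
      atom_name = sm$atom_name, residue_index = sm$residue_index,
      residue_name = sm$residue_name, segment = sm$segment,
      x = sm$coords[, 1], y = sm$coords[, 2], z = sm$coords[, 3]))
    tibble(tcr_id = sm$tcr_id, peptide_id = sm$peptide_id,
           label = sm$label, structure = list(s))
  }))
}
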