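the_feature_env <- new.env(parent = emptyenv())

#' Per-atom chemical feature table for the 20 standard residues
#'
#' A fixed lookup table keyed by (residue name, atom name) with the eight
#' per-atom features used by the binding classifier: atomic number, formal
#' charge, aromaticity flag, ring membership flag, hybridization code
#' (SP = 1, SP2 = 2, SP3 = 3, other = 0), explicit valence, implicit
#' valence and total valence. Values were derived once from mid-chain
#' residues of G-X-G tripeptides with a cheminformatics toolkit and are
#' shipped as a plain-text table, so featurization is deterministic and
#' needs no chemistry dependency at run time.
#'
#' @return A tibble with one row per (residue, heavy atom).
#' @export
residue_feature_table <- function() {
  if (is.null(the_feature_env$table)) {
    path <- system.file("extdata", "aa_atom_features.tsv", package = "tcrcost")
    if (path == "") {
      path <- file.path("inst", "extdata", "aa_atom_features.tsv")
    }
    the_feature_env$table <- as_tibble(read.delim(path, sep = "\t"))
  }
  the_feature_env$table
}

FEATURE_NAMES <- c("element_code", "charge", "is_aromatic", "in_ring",
                   "hybridization_code", "explicit_valence",
                   "implicit_valence", "total_valence")

#' Eight chemical features per atom of a structure
#'
#' @param s A [tcr_structure()] containing standard amino-acid residues.
#' @return A tibble with one row per atom (in the structure's atom order)
#'   and the eight feature columns; see [residue_feature_table()].
#' @export
atom_features <- function(s) {
  tab <- residue_feature_table()
  key <- paste(tab$residue_name, tab$atom_name)
  hit <- match(paste(s$residue_name, s$atom_name), key)
  if (anyNA(hit)) {
    bad <- which(is.na(hit))[1]
    abort(sprintf("no feature entry for atom %s of residue %s",
                  s$atom_name[bad], s$residue_name[bad]),
          class = "tcrcost_unknown_atom")
  }
  tab[hit, FEATURE_NAMES]
}
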