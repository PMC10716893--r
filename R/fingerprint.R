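# Extended-connectivity (circular, Morgan-style) fingerprints on the
# internal graph. Identifiers are built by iteratively hashing each atom's
# invariants with its neighbors' previous-round identifiers; "diameter 4"
# means radius-2 neighborhoods. Hashing is a deterministic 31-bit integer
# mix, so fingerprints are stable across sessions and platforms.

.HASH_MOD <- 2147483647   # 2^31 - 1; doubles hold intermediate products exactly

hash_mix <- function(ids) {
  h <- 17
  for (v in ids) {
    h <- (h * 31 + (v %% .HASH_MOD)) %% .HASH_MOD
  }
  h
}

# Round-0 atom invariants: element, degree, implicit H count, charge,
# aromaticity, ring membership.
ecfp_initial_ids <- function(mol) {
  deg <- mol_degree(mol)
  imph <- mol_implicit_h(mol)
  ring_atoms <- unique(unlist(mol_rings(mol)))
  in_ring <- seq_len(mol$n) %in% ring_atoms
  elem_idx <- match(mol$elem, names(.ATOMIC_MASS))
  elem_idx[is.na(elem_idx)] <- 0L
  vapply(seq_len(mol$n), function(a) {
    hash_mix(c(1000003, elem_idx[a], deg[a], imph[a],
               mol$charge[a] + 10, as.integer(mol$arom[a]),
               as.integer(in_ring[a])))
  }, numeric(1))
}

# All substructure identifiers up to `radius` (with duplicates removed per
# round, as in the canonical ECFP construction).
ecfp_identifiers <- function(mol, radius = 2L) {
  ids <- ecfp_initial_ids(mol)
  all_ids <- ids
  if (mol$n == 0L) return(numeric(0))
  adj <- mol_adjacency(mol)
  for (r in seq_len(radius)) {
    new_ids <- vapply(seq_len(mol$n), function(a) {
      nb <- adj[[a]]
      if (nrow(nb) == 0L) return(hash_mix(c(r, ids[a])))
      pairs <- cbind(nb$order * 10, ids[nb$j])
      ord <- order(pairs[, 1L], pairs[, 2L])
      hash_mix(c(r, ids[a], t(pairs[ord, , drop = FALSE])))
    }, numeric(1))
    ids <- new_ids
    all_ids <- c(all_ids, ids)
  }
  unique(all_ids)
}

#' Circular fingerprint of a molecule
#'
#' 2048-bit extended-connectivity fingerprint of diameter 4 (radius 2) by
#' default, matching the descriptor used for chemical-space projection.
#'
#' @param smiles a single SMILES string.
#' @param radius neighborhood radius (diameter / 2).
#' @param nbits fingerprint length.
#' @return an integer 0/1 vector of length `nbits`.
#' @export
morgan_fingerprint <- function(smiles, radius = 2L, nbits = 2048L) {
  mol <- parse_molecule(smiles)
  if (is.null(mol)) {
    abort_invalid_structure(paste0("cannot parse SMILES: ", smiles))
  }
  ids <- ecfp_identifiers(mol, radius)
  fp <- integer(nbits)
  fp[(ids %% nbits) + 1L] <- 1L
  fp
}

#' Fingerprint matrix for a set of molecules
#'
#' @param smiles character vector of SMILES.
#' @inheritParams morgan_fingerprint
#' @return an `n x nbits` 0/1 matrix, rows named by input.
#' @export
fingerprint_matrix <- function(smiles, radius = 2L, nbits = 2048L) {
  m <- t(vapply(smiles, morgan_fingerprint, integer(nbits),
                radius = radius, nbits = nbits))
  rownames(m) <- smiles
  m
}

#' Tanimoto (Jaccard) similarity between two bit vectors
#'
#' @param a,b 0/1 vectors of equal length.
#' @return similarity in `[0, 1]` (1 for two empty vectors).
#' @export
tanimoto <- function(a, b) {
  both <- sum(a & b)
  either <- sum(a | b)
  if (either == 0L) return(1)
  both / either
}
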