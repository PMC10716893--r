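# Synthetic-accessibility score in [1, 10] (lower = easier to make),
# following the fragment-contribution-plus-complexity recipe of the
# Ertl-Schuffenhauer method: a per-atom fragment familiarity score from a
# frequency-derived contribution table, corrected by size, ring-complexity,
# spiro, macrocycle and symmetry terms, then mapped onto [1, 10].
#
# The shipped contribution table (inst/extdata/sa_fragment_scores_synthetic.tsv)
# is synthetic: it is derived from the package's own enumerable fixture
# space rather than from a large public compound database (see the methods
# vignette). Fragments absent from the table contribute the unfamiliarity
# floor.

.sa_env <- new.env(parent = emptyenv())

sa_fragment_table <- function() {
  if (is.null(.sa_env$table)) {
    path <- system.file("extdata", "sa_fragment_scores_synthetic.tsv",
                        package = "molgrow")
    if (!nzchar(path) || !file.exists(path)) {
      # table not built yet (e.g. during bootstrap); empty table means every
      # fragment scores at the unfamiliarity floor
      .sa_env$table <- stats::setNames(numeric(0), character(0))
    } else {
      df <- utils::read.table(path, header = TRUE, sep = "\t",
                              colClasses = c("character", "numeric"))
      .sa_env$table <- stats::setNames(df$score, df$id)
    }
  }
  .sa_env$table
}

.SA_UNKNOWN_FRAGMENT <- -4   # contribution floor for unseen fragments

#' Synthetic-accessibility score
#'
#' @param smiles a single SMILES string.
#' @return score in `[1, 10]`; lower means easier to synthesize.
#' @export
sa_score <- function(smiles) {
  mol <- parse_molecule(smiles)
  if (is.null(mol)) {
    abort_invalid_structure(paste0("cannot parse SMILES: ", smiles))
  }
  tab <- sa_fragment_table()

  # fragment familiarity: per-occurrence contributions of radius-2
  # substructure identifiers, averaged over occurrences
  ids <- ecfp_fragment_counts(mol, radius = 2L)
  contrib <- tab[names(ids)]
  contrib[is.na(contrib)] <- .SA_UNKNOWN_FRAGMENT
  score1 <- sum(contrib * ids) / sum(ids)

  # complexity penalties
  n <- mol$n
  rings <- mol_rings(mol)
  ring_sizes <- vapply(rings, length, integer(1))
  n_macro <- sum(ring_sizes > 8L)
  ring_atoms <- unlist(rings)
  n_bridge <- sum(table(ring_atoms) >= 2L)       # atoms shared by >= 2 rings
  n_spiro <- count_spiro(rings)
  size_penalty <- n^1.005 - n
  ring_penalty <- log10(n_bridge + 1) + log10(n_spiro + 1)
  macro_penalty <- if (n_macro > 0L) log10(2) else 0
  score2 <- -(size_penalty + ring_penalty + macro_penalty)

  # symmetry correction: molecules made of few distinct fragments relative
  # to their size read as simpler than the raw average suggests
  n_unique_frag <- length(ids)
  score3 <- 0
  if (n > n_unique_frag) score3 <- log(n / n_unique_frag) * 0.5

  raw <- score1 + score2 + score3
  # map the practical raw range onto [1, 10] (familiar, simple -> 1)
  smin <- -4; smax <- 2.5
  sa <- 11 - (raw - smin + 1) / (smax - smin) * 9
  if (sa > 8) sa <- 8 + log(sa + 1 - 9)
  min(max(sa, 1), 10)
}

# atom shared by exactly two rings whose intersection is just that atom
count_spiro <- function(rings) {
  if (length(rings) < 2L) return(0L)
  n_spiro <- 0L
  for (a in seq_len(length(rings) - 1L)) {
    for (b in (a + 1L):length(rings)) {
      inter <- intersect(rings[[a]], rings[[b]])
      if (length(inter) == 1L) n_spiro <- n_spiro + 1L
    }
  }
  n_spiro
}

# counts of circular fragment identifiers (radius 0..radius), names are
# identifier strings
ecfp_fragment_counts <- function(mol, radius = 2L) {
  ids <- ecfp_initial_ids(mol)
  all_ids <- ids
  adj <- mol_adjacency(mol)
  for (r in seq_len(radius)) {
    ids <- vapply(seq_len(mol$n), function(a) {
      nb <- adj[[a]]
      if (nrow(nb) == 0L) return(hash_mix(c(r, ids[a])))
      pairs <- cbind(nb$order * 10, ids[nb$j])
      ord <- order(pairs[, 1L], pairs[, 2L])
      hash_mix(c(r, ids[a], t(pairs[ord, , drop = FALSE])))
    }, numeric(1))
    all_ids <- c(all_ids, ids)
  }
  tab <- table(format(all_ids, scientific = FALSE, trim = TRUE))
  stats::setNames(as.numeric(tab), names(tab))
}
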