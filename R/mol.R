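# Internal molecular graph ("mg_mol"): heavy atoms only, kekulized bond
# orders, aromatic flags carried over from the canonical SMILES. Built by
# round-tripping a SMILES through OpenBabel's ctab writer, which preserves
# atom order, so the aromatic flags from the SMILES scan line up with the
# ctab atom block.

# Default valences at formal charge 0 (used for implicit hydrogen filling);
# for charged N/O/S/P atoms the allowed valence shifts by the charge.
.DEFAULT_VALENCE <- c(B = 3, C = 4, N = 3, O = 2, F = 1, P = 3, S = 2,
                      Cl = 1, Br = 1, I = 1)

# Maximum valence used when the builder asks whether one more bond fits
# (hypervalent P/S allowed up to their common oxidation states).
.MAX_VALENCE <- c(B = 3, C = 4, N = 3, O = 2, F = 1, P = 5, S = 6,
                  Cl = 1, Br = 1, I = 1)

.ATOMIC_MASS <- c(H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999,
                  F = 18.998, P = 30.974, S = 32.06, Cl = 35.45,
                  Br = 79.904, I = 126.904)

max_valence_of <- function(element) {
  v <- .MAX_VALENCE[element]
  if (any(is.na(v))) {
    abort_config(paste0("no valence entry for element(s): ",
                        paste(unique(element[is.na(v)]), collapse = ", ")))
  }
  unname(v)
}

#' Parse a SMILES string into the internal molecular graph
#'
#' Canonicalizes through OpenBabel (stereochemistry and isotopes stripped),
#' then reads the kekulized connection table. Returns `NULL` for strings
#' that fail the strict syntax scan or do not parse.
#'
#' @param smiles a single SMILES string.
#' @return a list with elements `elem` (character), `arom` (logical),
#'   `charge` (integer), `bonds` (data.frame `i`,`j`,`order`), `n` (atom
#'   count) and `smiles` (the canonical form), or `NULL`.
#' @keywords internal
parse_molecule <- function(smiles) {
  hit <- .mol_cache[[smiles]]
  if (!is.null(hit)) {
    if (identical(hit, "invalid")) return(NULL)
    return(hit)
  }
  mol <- parse_molecule_uncached(smiles)
  # memoized under both the input string and the canonical form; tree-search
  # rewards revisit molecules heavily
  if (is.null(mol)) {
    assign(smiles, "invalid", envir = .mol_cache)
  } else {
    assign(smiles, mol, envir = .mol_cache)
    if (!identical(mol$smiles, smiles)) {
      assign(mol$smiles, mol, envir = .mol_cache)
    }
  }
  mol
}

.mol_cache <- new.env(parent = emptyenv())

parse_molecule_uncached <- function(smiles) {
  if (!smiles_syntax_ok(smiles)) return(NULL)
  canon <- if (isTRUE(.mol_cache[[paste0("canon::", smiles)]])) {
    smiles               # string is a known canonicalization output
  } else {
    ob_canonical_raw(smiles_strip_stereo(smiles))
  }
  if (is.null(canon)) return(NULL)
  scan <- smiles_scan(canon)
  if (is.null(scan)) return(NULL)
  block <- ob_molblock(canon)
  if (is.null(block)) return(NULL)
  ctab <- parse_molblock(block)
  if (is.null(ctab) || ctab$n != nrow(scan)) return(NULL)
  if (!all(ctab$elem == scan$symbol)) return(NULL)  # order mismatch guard
  list(elem = ctab$elem, arom = scan$aromatic, charge = ctab$charge,
       bonds = ctab$bonds, n = ctab$n, smiles = canon)
}

# Minimal MDL V2000 reader (atoms, bonds, M CHG); coordinates optional.
parse_molblock <- function(block) {
  lines <- strsplit(block, "\n", fixed = TRUE)[[1L]]
  cnt <- which(grepl("V2000", lines, fixed = TRUE))
  if (length(cnt) != 1L) return(NULL)
  counts <- lines[cnt]
  natoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nbonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(natoms) || is.na(nbonds) || natoms < 1L) return(NULL)
  atom_lines <- lines[(cnt + 1L):(cnt + natoms)]
  elem <- trimws(substr(atom_lines, 32, 34))
  xyz <- cbind(as.numeric(substr(atom_lines, 1, 10)),
               as.numeric(substr(atom_lines, 11, 20)),
               as.numeric(substr(atom_lines, 21, 30)))
  bonds <- data.frame(i = integer(0), j = integer(0), order = numeric(0))
  if (nbonds > 0L) {
    bond_lines <- lines[(cnt + natoms + 1L):(cnt + natoms + nbonds)]
    bi <- as.integer(substr(bond_lines, 1, 3))
    bj <- as.integer(substr(bond_lines, 4, 6))
    bo <- as.integer(substr(bond_lines, 7, 9))
    if (anyNA(bi) || anyNA(bj) || anyNA(bo)) return(NULL)
    bonds <- data.frame(i = pmin(bi, bj), j = pmax(bi, bj),
                        order = as.numeric(bo))
  }
  charge <- integer(natoms)
  for (cl in grep("^M  CHG", lines, value = TRUE)) {
    flds <- as.integer(strsplit(trimws(substring(cl, 7)), "[ ]+")[[1L]])
    k <- flds[1L]
    for (q in seq_len(k)) {
      charge[flds[2L * q]] <- flds[2L * q + 1L]
    }
  }
  list(n = natoms, elem = elem, bonds = bonds, charge = charge, xyz = xyz)
}

# Sum of bond orders incident to each atom (kekulized orders).
mol_bond_order_sum <- function(mol) {
  s <- numeric(mol$n)
  if (nrow(mol$bonds) > 0L) {
    for (k in seq_len(nrow(mol$bonds))) {
      s[mol$bonds$i[k]] <- s[mol$bonds$i[k]] + mol$bonds$order[k]
      s[mol$bonds$j[k]] <- s[mol$bonds$j[k]] + mol$bonds$order[k]
    }
  }
  s
}

mol_degree <- function(mol) {
  d <- integer(mol$n)
  if (nrow(mol$bonds) > 0L) {
    tab <- table(factor(c(mol$bonds$i, mol$bonds$j), levels = seq_len(mol$n)))
    d <- as.integer(tab)
  }
  d
}

# Implicit hydrogens: default valence (shifted by formal charge for the
# common heteroatoms) minus the kekulized bond-order sum, floored at zero.
mol_implicit_h <- function(mol) {
  dv <- .DEFAULT_VALENCE[mol$elem]
  dv[is.na(dv)] <- 0
  adj <- ifelse(mol$elem %in% c("N", "O", "S", "P"), mol$charge, 0L)
  pmax(0, round(unname(dv) + adj - mol_bond_order_sum(mol)))
}

mol_mw <- function(mol) {
  m <- .ATOMIC_MASS[mol$elem]
  if (anyNA(m)) return(NA_real_)
  sum(m) + sum(mol_implicit_h(mol)) * .ATOMIC_MASS[["H"]]
}

# Adjacency list (neighbor index + bond order) for traversals.
mol_adjacency <- function(mol) {
  adj <- rep(list(data.frame(j = integer(0), order = numeric(0))), mol$n)
  if (nrow(mol$bonds) > 0L) {
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$i[k]; j <- mol$bonds$j[k]; o <- mol$bonds$order[k]
      adj[[i]] <- rbind(adj[[i]], data.frame(j = j, order = o))
      adj[[j]] <- rbind(adj[[j]], data.frame(j = i, order = o))
    }
  }
  adj
}

n_fragments <- function(mol) {
  if (mol$n == 0L) return(0L)
  seen <- logical(mol$n)
  adj <- mol_neighbors(mol)
  comp <- 0L
  for (start in seq_len(mol$n)) {
    if (seen[start]) next
    comp <- comp + 1L
    queue <- start
    seen[start] <- TRUE
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
  }
  comp
}

# Plain neighbor lists (no orders) -- cheaper than mol_adjacency.
mol_neighbors <- function(mol) {
  adj <- rep(list(integer(0)), mol$n)
  if (nrow(mol$bonds) > 0L) {
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  adj
}

# Smallest-ring perception: for every edge outside a spanning tree, take the
# shortest cycle through that edge (BFS with the edge removed). Duplicate
# rings are merged. This is the practical SSSR-style set used for ring
# penalties, ring-size multisets and aromatic ring counting.
mol_rings <- function(mol) {
  nb <- mol$bonds
  if (is.null(nb) || nrow(nb) == 0L || mol$n < 3L) return(list())
  adj <- mol_neighbors(mol)
  # spanning forest via BFS
  in_tree <- logical(nrow(nb))
  seen <- logical(mol$n)
  edge_key <- paste(nb$i, nb$j)
  edge_index <- function(a, b) match(paste(min(a, b), max(a, b)), edge_key)
  for (start in seq_len(mol$n)) {
    if (seen[start]) next
    seen[start] <- TRUE
    queue <- start
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (w in adj[[v]]) {
        if (!seen[w]) {
          seen[w] <- TRUE
          in_tree[edge_index(v, w)] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
  }
  rings <- list()
  keys <- character(0)
  for (k in which(!in_tree)) {
    a <- nb$i[k]; b <- nb$j[k]
    path <- bfs_shortest_path(adj, a, b, skip_edge = c(a, b))
    if (is.null(path)) next
    ring <- path                               # a .. b, closed by edge (a,b)
    key <- paste(sort(ring), collapse = "-")
    if (!key %in% keys) {
      keys <- c(keys, key)
      rings[[length(rings) + 1L]] <- ring
    }
  }
  rings
}

bfs_shortest_path <- function(adj, from, to, skip_edge = NULL) {
  n <- length(adj)
  prev <- integer(n)
  seen <- logical(n)
  seen[from] <- TRUE
  queue <- from
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    for (w in adj[[v]]) {
      if (!is.null(skip_edge) &&
          ((v == skip_edge[1L] && w == skip_edge[2L]) ||
           (v == skip_edge[2L] && w == skip_edge[1L]))) next
      if (!seen[w]) {
        seen[w] <- TRUE
        prev[w] <- v
        if (w == to) {
          path <- w
          while (path[1L] != from) path <- c(prev[path[1L]], path)
          return(path)
        }
        queue <- c(queue, w)
      }
    }
  }
  NULL
}

mol_ring_sizes <- function(mol) vapply(mol_rings(mol), length, integer(1))

mol_largest_ring <- function(mol) {
  rs <- mol_ring_sizes(mol)
  if (length(rs) == 0L) 0L else max(rs)
}

# A ring counts as aromatic when every member atom carries the aromatic flag.
mol_aromatic_ring_count <- function(mol) {
  rings <- mol_rings(mol)
  if (length(rings) == 0L) return(0L)
  sum(vapply(rings, function(r) all(mol$arom[r]), logical(1)))
}

mol_aliphatic_ring_count <- function(mol) {
  rings <- mol_rings(mol)
  if (length(rings) == 0L) return(0L)
  sum(vapply(rings, function(r) !all(mol$arom[r]), logical(1)))
}

# Rotatable bonds, simple definition: acyclic single bonds whose endpoints
# both have heavy-atom degree >= 2.
mol_rotatable_bonds <- function(mol) {
  if (nrow(mol$bonds) == 0L) return(0L)
  deg <- mol_degree(mol)
  rings <- mol_rings(mol)
  in_ring_bond <- function(i, j) {
    any(vapply(rings, function(r) (i %in% r) && (j %in% r), logical(1)))
  }
  n_rot <- 0L
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    if (mol$bonds$order[k] == 1 && deg[i] >= 2L && deg[j] >= 2L &&
        !in_ring_bond(i, j)) {
      n_rot <- n_rot + 1L
    }
  }
  n_rot
}

# Lipinski-style hydrogen-bond counts from the graph: donors are N/O atoms
# carrying at least one hydrogen; acceptors are all N/O atoms.
mol_hbd <- function(mol) {
  imph <- mol_implicit_h(mol)
  sum(mol$elem %in% c("N", "O") & imph >= 1L)
}

mol_hba <- function(mol) sum(mol$elem %in% c("N", "O"))

# Hybridization heuristic from kekulized orders: triple bond or two doubles
# -> sp; any double bond or aromatic flag -> sp2; otherwise sp3.
mol_hybridization <- function(mol) {
  res <- rep("sp3", mol$n)
  if (nrow(mol$bonds) > 0L) {
    dbl <- numeric(mol$n); trp <- numeric(mol$n)
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$i[k]; j <- mol$bonds$j[k]; o <- mol$bonds$order[k]
      if (o == 2) { dbl[i] <- dbl[i] + 1; dbl[j] <- dbl[j] + 1 }
      if (o == 3) { trp[i] <- trp[i] + 1; trp[j] <- trp[j] + 1 }
    }
    res[dbl >= 1 | mol$arom] <- "sp2"
    res[trp >= 1 | dbl >= 2] <- "sp"
  }
  res
}
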