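# chem_graph: conversion between molecule representations and fixed-size
# feature maps, plus the valence-guarded build state the tree search grows.

#' Convert a SMILES string to a fixed-size molecular graph
#'
#' The molecule is canonicalized (stereochemistry stripped, hydrogens
#' implicit), atoms are laid out in canonical order in the first
#' `n_atoms` node slots, and node/edge feature blocks are filled per the
#' [feature_config()]. Padding slots beyond `n_atoms` are zero.
#'
#' @param smiles a single SMILES string.
#' @param config a [feature_config()].
#' @return an object of class `molecular_graph` with fields
#'   `node_features` (`max_atoms x d_node`), `edge_features`
#'   (`max_atoms x max_atoms x d_edge`, symmetric in the first two indices,
#'   zero diagonal), `n_atoms` and `source` (canonical SMILES).
#' @export
smiles_to_graph <- function(smiles, config) {
  stopifnot(inherits(config, "feature_config"))
  mol <- parse_molecule(smiles)
  if (is.null(mol)) {
    abort_invalid_structure(paste0("cannot parse SMILES: ", smiles),
                            smiles = smiles)
  }
  if (n_fragments(mol) > 1L) {
    abort_invalid_structure(paste0("multi-fragment structure: ", smiles),
                            smiles = smiles)
  }
  if (mol$n > config$max_atoms) {
    abort_capacity(sprintf("%d heavy atoms exceed max_atoms = %d (%s)",
                           mol$n, config$max_atoms, smiles), smiles = smiles)
  }
  out_of_vocab <- setdiff(unique(mol$elem), config$allowed_elements)
  if (length(out_of_vocab) > 0L) {
    abort_capacity(paste0("element(s) outside vocabulary: ",
                          paste(out_of_vocab, collapse = ", "),
                          " (", smiles, ")"), smiles = smiles)
  }

  M <- config$max_atoms
  node <- matrix(0, nrow = M, ncol = config$d_node)
  deg <- mol_degree(mol)
  hyb <- mol_hybridization(mol)
  n_el <- length(config$allowed_elements)
  for (a in seq_len(mol$n)) {
    col <- 0L
    node[a, match(mol$elem[a], config$allowed_elements)] <- 1
    col <- n_el
    node[a, col + min(deg[a], 5L) + 1L] <- 1
    col <- col + 6L
    node[a, col + 1L] <- mol$charge[a]
    col <- col + 1L
    node[a, col + 1L] <- as.numeric(mol$arom[a])
    col <- col + 1L
    hidx <- match(hyb[a], c("sp", "sp2", "sp3"))
    if (is.na(hidx)) hidx <- 4L
    node[a, col + hidx] <- 1
  }

  edge <- array(0, dim = c(M, M, config$d_edge))
  if (nrow(mol$bonds) > 0L) {
    rings <- mol_rings(mol)
    in_same_ring <- function(i, j) {
      any(vapply(rings, function(r) (i %in% r) && (j %in% r), logical(1)))
    }
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$i[k]; j <- mol$bonds$j[k]; o <- mol$bonds$order[k]
      type <- if (mol$arom[i] && mol$arom[j] && in_same_ring(i, j)) {
        "aromatic"
      } else {
        c("single", "double", "triple")[o]
      }
      t_idx <- match(type, config$bond_types)
      if (is.na(t_idx)) t_idx <- match("single", config$bond_types)
      edge[i, j, t_idx] <- 1
      edge[j, i, t_idx] <- 1
    }
  }

  structure(list(node_features = node, edge_features = edge,
                 n_atoms = mol$n, source = mol$smiles),
            class = "molecular_graph")
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat("molecular_graph:", x$source, "\n")
  cat("  n_atoms:", x$n_atoms, " slots:", nrow(x$node_features), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# BuildState: the partial molecule grown by the tree search. Atoms live in
# feature-map slots; bonds carry explicit kekulized orders (1/2/3). Every
# mutation goes through valence_ok(), which is what makes generated
# molecules valid by construction.

#' Create an empty build state
#'
#' Bookkeeping is incremental: the per-atom bond-order sums (`osum`) and
#' the multiset of ring sizes are maintained on every mutation so the
#' search loop never re-derives them.
#'
#' @param config a [feature_config()].
#' @return an object of class `build_state`.
#' @export
build_state <- function(config) {
  structure(list(slots = integer(0),        # feature-map slot per atom
                 elem = character(0),
                 bonds = matrix(numeric(0), ncol = 3,
                                dimnames = list(NULL, c("i", "j", "order"))),
                 osum = numeric(0),
                 headroom = numeric(0),   # max valence minus osum, per atom
                 ring_sizes = integer(0),
                 config = config),
            class = "build_state")
}

n_atoms <- function(state) length(state$elem)

# Bond-order sum per atom (indexed like state$elem).
state_order_sum <- function(state) state$osum

state_bonds_df <- function(state) {
  data.frame(i = as.integer(state$bonds[, 1L]),
             j = as.integer(state$bonds[, 2L]),
             order = state$bonds[, 3L])
}

state_as_mol <- function(state) {
  list(elem = state$elem, arom = rep(FALSE, n_atoms(state)),
       charge = rep(0L, n_atoms(state)), bonds = state_bonds_df(state),
       n = n_atoms(state), smiles = NA_character_)
}

state_ring_sizes <- function(state) state$ring_sizes

# shortest path length (in atoms) between two atoms of the state graph,
# or NA when disconnected; used to size a ring about to be closed
state_path_length <- function(state, from, to) {
  n <- n_atoms(state)
  bi <- state$bonds[, 1L]; bj <- state$bonds[, 2L]
  dist <- rep(NA_integer_, n)
  dist[from] <- 0L
  queue <- from
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    nbr <- c(bj[bi == v], bi[bj == v])
    for (w in nbr) {
      if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L
        if (w == to) return(dist[w])
        queue <- c(queue, w)
      }
    }
  }
  dist[to]
}

#' Can one more bond be added to an atom without breaking valence?
#'
#' True iff adding a bond of order `order` keeps the atom's bond-order sum
#' within the element's maximum valence (neutral-atom table; C4, N3, O2,
#' F/Cl/Br/I 1, P5, S6, B3).
#'
#' @param state a [build_state()].
#' @param atom index of the atom within the state (1-based).
#' @param order bond order to add (1, 2 or 3).
#' @return logical.
#' @export
valence_ok <- function(state, atom, order) {
  stopifnot(inherits(state, "build_state"))
  if (atom < 1L || atom > n_atoms(state)) {
    abort_config(sprintf("atom index %d outside state (n = %d)",
                         atom, n_atoms(state)))
  }
  maxv <- max_valence_of(state$elem[atom])
  state$osum[atom] + order <= maxv
}

# Valence headroom for a hypothetical new atom of a given element.
element_allows_order <- function(element, order) {
  max_valence_of(element) >= order
}

# Add a new atom bonded to an existing one. `anchor = 0` places the first
# atom of an empty state. Returns the new state or NULL when valence or
# slot constraints forbid the move (callers treat NULL as inadmissible).
state_add_atom <- function(state, slot, element, anchor = 0L, order = 1) {
  if (slot %in% state$slots) return(NULL)
  if (slot < 1L || slot > state$config$max_atoms) return(NULL)
  if (!element %in% state$config$allowed_elements) return(NULL)
  if (anchor == 0L) {
    if (n_atoms(state) > 0L) return(NULL)   # connectivity: one seed atom only
    state$slots <- slot
    state$elem <- element
    state$osum <- 0
    state$headroom <- max_valence_of(element)
    return(state)
  }
  if (!element_allows_order(element, order)) return(NULL)
  if (!valence_ok(state, anchor, order)) return(NULL)
  state$slots <- c(state$slots, slot)
  state$elem <- c(state$elem, element)
  new_idx <- n_atoms(state)
  state$bonds <- rbind(state$bonds, c(anchor, new_idx, order))
  state$osum <- c(state$osum, order)
  state$osum[anchor] <- state$osum[anchor] + order
  state$headroom <- c(state$headroom, max_valence_of(element) - order)
  state$headroom[anchor] <- state$headroom[anchor] - order
  state
}

# Close a ring between two placed atoms. NULL when inadmissible.
state_add_bond <- function(state, a, b, order = 1) {
  if (a == b) return(NULL)
  lo <- min(a, b); hi <- max(a, b)
  if (nrow(state$bonds) > 0L &&
      any(state$bonds[, 1L] == lo & state$bonds[, 2L] == hi)) return(NULL)
  if (!valence_ok(state, a, order) || !valence_ok(state, b, order)) {
    return(NULL)
  }
  plen <- state_path_length(state, a, b)    # ring size about to be closed
  state$bonds <- rbind(state$bonds, c(lo, hi, order))
  state$osum[a] <- state$osum[a] + order
  state$osum[b] <- state$osum[b] + order
  state$headroom[a] <- state$headroom[a] - order
  state$headroom[b] <- state$headroom[b] - order
  if (!is.na(plen)) {
    state$ring_sizes <- c(state$ring_sizes, plen + 1L)
  }
  state
}

#' Realize a build state as a canonical SMILES string
#'
#' Writes the kekulized graph as SMILES (depth-first, ring-closure digits),
#' then canonicalizes through the toolkit; implicit hydrogens fill the
#' remaining valence. Because every construction step is valence-gated,
#' sanitization failure here indicates a construction bug and raises an
#' error.
#'
#' @param state a [build_state()] with at least one atom.
#' @return a canonical SMILES string.
#' @export
assemble_molecule <- function(state) {
  stopifnot(inherits(state, "build_state"))
  if (n_atoms(state) == 0L) {
    abort_invalid_structure("empty build state has no molecule")
  }
  maxv <- max_valence_of(state$elem)
  if (any(state$osum > maxv)) {
    abort_invalid_structure("build state violates valence; construction bug")
  }
  raw <- state_to_smiles(state)
  canon <- ob_canonical_raw(raw)
  if (is.null(canon) || !smiles_syntax_ok(canon)) {
    abort_invalid_structure(
      paste0("assembled state failed sanitization: ", raw))
  }
  assign(paste0("canon::", canon), TRUE, envir = .mol_cache)
  canon
}

# Kekulized SMILES writer: DFS from atom 1, branches in parentheses,
# back-edges as ring closures.
state_to_smiles <- function(state) {
  n <- n_atoms(state)
  if (n == 1L) return(smiles_atom_token(state$elem[1L]))
  nbr <- rep(list(integer(0)), n)     # neighbor atom per incident edge
  ord <- rep(list(numeric(0)), n)     # matching bond order
  for (k in seq_len(nrow(state$bonds))) {
    i <- state$bonds[k, 1L]; j <- state$bonds[k, 2L]
    o <- state$bonds[k, 3L]
    nbr[[i]] <- c(nbr[[i]], j); ord[[i]] <- c(ord[[i]], o)
    nbr[[j]] <- c(nbr[[j]], i); ord[[j]] <- c(ord[[j]], o)
  }
  visited <- logical(n)
  ring_marks <- rep(list(character(0)), n)   # closure tokens per atom
  order_sym <- function(o) c("", "=", "#")[o]

  # pre-pass: identify back edges via DFS, assign closure digits
  parent <- rep(NA_integer_, n)
  disc <- integer(n); timer <- 0L
  back_edges <- list()
  visited_pre <- logical(n)
  dfs_pre <- function(v) {
    visited_pre[v] <<- TRUE
    timer <<- timer + 1L; disc[v] <<- timer
    for (r in seq_along(nbr[[v]])) {
      w <- nbr[[v]][r]
      if (!visited_pre[w]) {
        parent[w] <<- v
        dfs_pre(w)
      } else if ((is.na(parent[v]) || w != parent[v]) && disc[w] < disc[v]) {
        back_edges[[length(back_edges) + 1L]] <<- c(v, w, ord[[v]][r])
      }
    }
  }
  dfs_pre(1L)
  ring_label <- 0L
  for (be in back_edges) {
    ring_label <- ring_label + 1L
    lab <- if (ring_label <= 9L) as.character(ring_label) else
      sprintf("%%%02d", ring_label)
    v <- be[1L]; w <- be[2L]; o <- be[3L]
    ring_marks[[v]] <- c(ring_marks[[v]], paste0(order_sym(o), lab))
    ring_marks[[w]] <- c(ring_marks[[w]], paste0(order_sym(o), lab))
  }
  is_back <- function(v, w) {
    any(vapply(back_edges,
               function(be) (be[1L] == v && be[2L] == w) ||
                 (be[1L] == w && be[2L] == v), logical(1)))
  }

  emit <- function(v, from) {
    visited[v] <<- TRUE
    out <- paste0(smiles_atom_token(state$elem[v]),
                  paste0(ring_marks[[v]], collapse = ""))
    ws <- nbr[[v]]; os <- ord[[v]]
    keep <- which(ws != from & !visited[ws])
    keep <- keep[!vapply(keep, function(r) is_back(v, ws[r]), logical(1))]
    for (q in seq_along(keep)) {
      r <- keep[q]
      if (visited[ws[r]]) next          # visited via an earlier branch
      piece <- paste0(order_sym(os[r]), emit(ws[r], v))
      out <- if (q < length(keep)) {
        paste0(out, "(", piece, ")")
      } else {
        paste0(out, piece)
      }
    }
    out
  }
  emit(1L, 0L)
}

smiles_atom_token <- function(element) {
  if (element %in% .ORGANIC_SUBSET) element else paste0("[", element, "]")
}

# ---------------------------------------------------------------------------

#' Read molecules from a SMILES or SDF file
#'
#' SMILES files hold one structure per line (an optional whitespace-separated
#' name is ignored); SDF per the MDL V2000 standard. Unparseable records are
#' counted and reported, never fatal.
#'
#' @param path file path.
#' @param format `"smiles"` or `"sdf"`.
#' @return a list with `smiles` (canonical structures of parseable records)
#'   and `n_skipped`.
#' @export
read_molecule_file <- function(path, format = c("smiles", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort_io(paste0("file not found: ", path))
  }
  records <- if (format == "smiles") {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    vapply(strsplit(lines, "[ \t]+"), `[[`, character(1), 1L)
  } else {
    txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
    recs <- strsplit(txt, "\\$\\$\\$\\$\n?")[[1L]]
    recs <- recs[grepl("V2000", recs)]
    vapply(recs, function(r) {
      out <- ob_convert("SDF", "CAN", paste0(r, "\n$$$$\n"))
      out <- strsplit(trimws(out), "[ \t\n]+")[[1L]]
      if (length(out) >= 1L && nzchar(out[1L])) out[1L] else NA_character_
    }, character(1), USE.NAMES = FALSE)
  }
  if (length(records) == 0L) {
    return(list(smiles = character(0), n_skipped = 0L))
  }
  canon <- vapply(records, function(s) {
    if (is.na(s)) return(NA_character_)
    m <- parse_molecule(s)
    if (is.null(m)) NA_character_ else m$smiles
  }, character(1), USE.NAMES = FALSE)
  keep <- !is.na(canon)
  n_skipped <- sum(!keep)
  if (n_skipped > 0L) {
    message(sprintf("read_molecule_file: skipped %d unparseable record(s)",
                    n_skipped))
  }
  list(smiles = canon[keep], n_skipped = n_skipped)
}

#' Write SMILES strings to a file, one per line
#'
#' @param smiles character vector.
#' @param path output path.
#' @export
write_molecule_file <- function(smiles, path) {
  writeLines(smiles, path)
  invisible(path)
}

#' Canonicalize a SMILES string
#'
#' Stereochemistry and isotopes are stripped; returns `NA` for strings that
#' do not parse.
#'
#' @param smiles character vector of SMILES.
#' @return character vector of canonical SMILES (`NA` where invalid).
#' @export
canonical_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    m <- parse_molecule(s)
    if (is.null(m)) NA_character_ else m$smiles
  }, character(1), USE.NAMES = FALSE)
}

#' Does a structure string parse and sanitize?
#'
#' @param smiles character vector.
#' @return logical vector.
#' @export
is_valid_smiles <- function(smiles) {
  vapply(smiles, function(s) !is.null(parse_molecule(s)), logical(1),
         USE.NAMES = FALSE)
}
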