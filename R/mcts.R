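# Monte Carlo tree search over partial molecules. Each iteration runs
# Selection (UCB1, minimized: rewards are "lower is better"), Expansion
# (valence-gated bond/atom additions drawn from the decoded feature maps),
# Simulation (uniform random rollout to a complete molecule) and Update
# (backing the rollout reward up the path, with realism-filter penalties
# and the aromatic-mode bonus applied).

#' Search configuration
#'
#' @param c exploration coefficient of the UCB rule (default 1.5).
#' @param edge_threshold candidate-edge probability cutoff, inclusive
#'   (default 0.10).
#' @param iterations searches per feature map (default 8000).
#' @param minimum_depth smallest molecule size (heavy atoms) emitted;
#'   `NULL` lets [mcts_generate()] pick the objective-specific default
#'   (21 for distribution benchmarks, 17 for QED, 6 for penalized logP).
#' @param aromatic_force seed searches with a 5- or 6-membered aromatic
#'   ring when the edge map supports one, and favor aromatic-containing
#'   molecules during backup.
#' @param aromatic_bonus reward adjustment for aromatic-containing
#'   molecules (default 0.5).
#' @param aromatic_bonus_mode `"subtract"` lowers the backed-up reward by
#'   `aromatic_bonus` (floored at 0) so aromatic branches are preferred
#'   under minimization; `"add"` applies the raw additive variant.
#' @param filter_penalty_factor multiplier on the backed-up reward when a
#'   realism filter fired (default 10).
#' @param max_ring_size rings larger than this flag the node (default 7).
#' @param rollout_cap maximum atoms a rollout may place; `NULL` means the
#'   feature map's `max_atoms`.
#' @param use_strain_filter also run the 3D steric-strain filter on rollout
#'   molecules (geometry embedding per molecule; off by default, the
#'   oversized-ring filter alone is cheap).
#' @param strain_cutoff strain-score cutoff (default 0.82).
#' @return an object of class `mcts_config`.
#' @export
mcts_config <- function(c = 1.5, edge_threshold = 0.10, iterations = 8000L,
                        minimum_depth = NULL, aromatic_force = TRUE,
                        aromatic_bonus = 0.5,
                        aromatic_bonus_mode = c("subtract", "add"),
                        filter_penalty_factor = 10,
                        max_ring_size = 7L, rollout_cap = NULL,
                        use_strain_filter = FALSE, strain_cutoff = 0.82) {
  aromatic_bonus_mode <- match.arg(aromatic_bonus_mode)
  if (c <= 0) abort_config("exploration coefficient c must be > 0")
  if (edge_threshold < 0 || edge_threshold > 1) {
    abort_config("edge_threshold must lie in [0, 1]")
  }
  iterations <- as.integer(iterations)
  if (iterations < 1L) abort_config("iterations must be >= 1")
  if (!is.null(minimum_depth) && minimum_depth < 1L) {
    abort_config("minimum_depth must be >= 1")
  }
  structure(list(c = c, edge_threshold = edge_threshold,
                 iterations = iterations, minimum_depth = minimum_depth,
                 aromatic_force = aromatic_force,
                 aromatic_bonus = aromatic_bonus,
                 aromatic_bonus_mode = aromatic_bonus_mode,
                 filter_penalty_factor = filter_penalty_factor,
                 max_ring_size = as.integer(max_ring_size),
                 rollout_cap = rollout_cap,
                 use_strain_filter = use_strain_filter,
                 strain_cutoff = strain_cutoff),
            class = "mcts_config")
}

#' UCB selection value (minimization form)
#'
#' `s/n - c * sqrt(ln N / n)`; unvisited nodes return `-Inf` so each child
#' is tried once before any is revisited. The node with the smallest value
#' is selected.
#'
#' @param s cumulative backed-up score of the node.
#' @param n visit count of the node.
#' @param N visit count of the parent (>= 1).
#' @param c exploration coefficient.
#' @return numeric.
#' @export
ucb_value <- function(s, n, N, c = 1.5) {
  stopifnot(N >= 1)
  if (n == 0) return(-Inf)
  s / n - c * sqrt(log(N) / n)
}

# --- search-tree nodes (mutable environments) --------------------------------

new_node <- function(state, parent = NULL, flagged = FALSE) {
  node <- new.env(parent = emptyenv())
  node$state <- state
  node$parent <- parent
  node$children <- list()
  node$s <- 0
  node$n <- 0L
  node$depth <- if (is.null(parent)) n_atoms(state) else parent$depth + 1L
  node$flagged <- flagged
  node$expanded <- FALSE
  node$terminal <- FALSE
  node
}

#' Descend from the root to the next node to work on
#'
#' Repeatedly takes the child with the minimal [ucb_value()] (ties broken
#' by lowest child index) until reaching a node that is unexpanded or
#' terminal.
#'
#' @param root the tree root (a node created by the search).
#' @param config an [mcts_config()].
#' @return the selected node.
#' @export
mcts_select <- function(root, config) {
  node <- root
  while (node$expanded && !node$terminal && length(node$children) > 0L) {
    vals <- vapply(node$children, function(ch) {
      ucb_value(ch$s, ch$n, max(node$n, 1L), config$c)
    }, numeric(1))
    node <- node$children[[which.min(vals)]]
  }
  node
}

#' Candidate edges above the probability threshold
#'
#' Returns every feature-map edge with probability `>= threshold`
#' (inclusive) that either extends the partial molecule (placed atom to
#' unplaced slot) or closes a ring (two placed, unbonded atoms), excluding
#' self-loops and duplicates; each edge carries the bond orders that are
#' valence-feasible at both endpoints.
#'
#' @param fm a [vgae_decode()] output (or any list with `edge_prob`).
#' @param state a [build_state()].
#' @param threshold probability cutoff in `[0, 1]`.
#' @return a data.frame with columns `i` (placed-atom index within the
#'   state, or 0 for the empty state), `slot` (feature-map slot of the
#'   other end), `j` (state index of the other end for ring closures, 0
#'   for extensions), `kind` (`"extend"`/`"close"`), and a list-column
#'   `orders`.
#' @export
candidate_edges <- function(fm, state, threshold = 0.10) {
  if (threshold < 0 || threshold > 1) {
    abort_config("threshold must lie in [0, 1]")
  }
  P <- fm$edge_prob
  M <- nrow(P)
  placed <- state$slots
  empty <- data.frame(i = integer(0), slot = integer(0), j = integer(0),
                      kind = character(0))
  empty$orders <- list()
  if (length(placed) == 0L) return(empty)
  headroom <- state$headroom
  max_order <- 3L
  ii <- integer(0); ss <- integer(0); jj <- integer(0)
  kk <- character(0); oo <- list()
  slot_state <- match(seq_len(M), placed)     # state index per slot (or NA)
  b <- state$bonds
  for (ai in which(headroom >= 1)) {
    si <- placed[ai]
    free_i <- headroom[ai]
    hits <- which(P[si, ] >= threshold)
    hits <- hits[hits != si]
    for (sj in hits) {
      aj <- slot_state[sj]
      if (is.na(aj)) {
        ii <- c(ii, ai); ss <- c(ss, sj); jj <- c(jj, 0L)
        kk <- c(kk, "extend")
        oo[[length(oo) + 1L]] <- seq_len(min(free_i, max_order))
      } else if (aj > ai) {               # each placed pair once
        if (nrow(b) > 0L &&
            any(b[, 1L] == min(ai, aj) & b[, 2L] == max(ai, aj))) next
        o_max <- min(free_i, headroom[aj], max_order)
        if (o_max >= 1) {
          ii <- c(ii, ai); ss <- c(ss, sj); jj <- c(jj, aj)
          kk <- c(kk, "close")
          oo[[length(oo) + 1L]] <- seq_len(o_max)
        }
      }
    }
  }
  if (length(ii) == 0L) return(empty)
  out <- data.frame(i = ii, slot = ss, j = jj, kind = kk)
  out$orders <- oo
  out
}

# Element sampling weights for a slot: the node map's element block,
# restricted to elements whose maximum valence admits the bond order.
slot_element_weights <- function(fm, slot, config, order) {
  w <- fm$node_map[slot, seq_along(config$allowed_elements)]
  ok <- config$element_maxv >= order
  w <- w * ok
  if (sum(w) <= 0) w <- as.numeric(ok)
  w / sum(w)
}

#' Expand a node into valence-feasible children
#'
#' One child per admissible (candidate edge, bond order) action; for
#' extension edges the new atom's element is drawn stochastically from the
#' node feature map. Children whose states contain a ring larger than
#' `max_ring_size` are created but flagged. A node with no admissible
#' action is marked terminal.
#'
#' For an empty state the expansion places a single first atom (one child
#' per vocabulary element) at the best-connected slot of the edge map.
#'
#' @param node the selected node.
#' @param fm the decoded feature map guiding the search.
#' @param config an [mcts_config()].
#' @param feat the [feature_config()] of the feature map.
#' @return the list of created children (also stored on the node).
#' @export
mcts_expand <- function(node, fm, config, feat) {
  state <- node$state
  children <- list()
  if (n_atoms(state) == 0L) {
    slot <- which.max(rowSums(fm$edge_prob))
    for (el in feat$allowed_elements) {
      st <- state_add_atom(state, slot, el, anchor = 0L)
      if (!is.null(st)) {
        children[[length(children) + 1L]] <- new_node(st, parent = node)
      }
    }
  } else if (n_atoms(state) < feat$max_atoms) {
    cands <- candidate_edges(fm, state, config$edge_threshold)
    if (nrow(cands) > 0L) {
      for (k in seq_len(nrow(cands))) {
        for (o in cands$orders[[k]]) {
          if (cands$kind[k] == "extend") {
            w <- slot_element_weights(fm, cands$slot[k], feat, o)
            el <- sample(feat$allowed_elements, 1L, prob = w)
            st <- state_add_atom(state, cands$slot[k], el,
                                 anchor = cands$i[k], order = o)
          } else {
            st <- state_add_bond(state, cands$i[k], cands$j[k], order = o)
          }
          if (is.null(st)) next
          flagged <- any(state_ring_sizes(st) > config$max_ring_size)
          children[[length(children) + 1L]] <-
            new_node(st, parent = node, flagged = flagged)
        }
      }
    }
  }
  node$children <- children
  node$expanded <- TRUE
  if (length(children) == 0L) node$terminal <- TRUE
  children
}

#' Random rollout from a partial molecule
#'
#' Applies uniformly random admissible actions until no action remains or
#' the rollout cap is reached, then assembles and scores the molecule.
#'
#' @param state a [build_state()] (at least one atom).
#' @param fm the decoded feature map.
#' @param config an [mcts_config()].
#' @param reward a function `smiles -> reward in [0, 1]`.
#' @return a list: `smiles`, `reward`, `n_atoms`, `flags` (named logical),
#'   `aromatic`.
#' @export
mcts_rollout <- function(state, fm, config, reward) {
  feat <- state$config
  cap <- config$rollout_cap %||% feat$max_atoms
  repeat {
    if (n_atoms(state) >= cap) break
    cands <- candidate_edges(fm, state, config$edge_threshold)
    if (nrow(cands) == 0L) break
    k <- sample.int(nrow(cands), 1L)
    o <- resample(cands$orders[[k]], 1L)
    st <- if (cands$kind[k] == "extend") {
      w <- slot_element_weights(fm, cands$slot[k], feat, o)
      el <- sample(feat$allowed_elements, 1L, prob = w)
      state_add_atom(state, cands$slot[k], el, anchor = cands$i[k],
                     order = o)
    } else {
      state_add_bond(state, cands$i[k], cands$j[k], order = o)
    }
    if (is.null(st)) break   # cannot happen: candidate orders are gated
    state <- st
  }
  smiles <- state_to_smiles(state)
  r <- reward(smiles)
  flags <- c(oversized_ring = any(state_ring_sizes(state) >
                                    config$max_ring_size),
             steric_strain = FALSE)
  if (config$use_strain_filter) {
    flags[["steric_strain"]] <-
      isTRUE(detect_filters(smiles, strain_cutoff = config$strain_cutoff,
                            check_strain = TRUE)[["steric_strain"]])
  }
  aromatic <- molecule_is_aromatic(smiles)
  list(smiles = smiles, reward = r, n_atoms = n_atoms(state),
       flags = flags, aromatic = aromatic)
}

# sample() misbehaves on length-1 numeric vectors; classic R footgun
resample <- function(x, size) x[sample.int(length(x), size)]

`%||%` <- function(a, b) if (is.null(a)) b else a

# Aromaticity after toolkit perception (works for kekulized input too);
# memoized, the rollout loop asks repeatedly.
.arom_cache <- new.env(parent = emptyenv())

molecule_is_aromatic <- function(smiles) {
  hit <- .arom_cache[[smiles]]
  if (!is.null(hit)) return(hit)
  obm <- ob_parse(smiles)
  val <- !is.null(obm) && count_aromatic_rings(obm) > 0L
  assign(smiles, val, envir = .arom_cache)
  val
}

#' Back a rollout result up the selection path
#'
#' Every node from the leaf to the root gets `n + 1` and `s + effective`,
#' where the effective reward first receives the aromatic adjustment (when
#' the aromatic mode is on and the molecule contains an aromatic ring) and
#' is then multiplied by `filter_penalty_factor` when a realism filter
#' fired on the rollout molecule or on the leaf node itself.
#'
#' @param node the leaf node the rollout started from.
#' @param rollout an [mcts_rollout()] result.
#' @param config an [mcts_config()].
#' @return the effective reward that was backed up (invisibly).
#' @export
mcts_update <- function(node, rollout, config) {
  eff <- rollout$reward
  if (config$aromatic_force && isTRUE(rollout$aromatic)) {
    eff <- if (config$aromatic_bonus_mode == "subtract") {
      max(0, eff - config$aromatic_bonus)
    } else {
      eff + config$aromatic_bonus
    }
  }
  if (any(rollout$flags) || isTRUE(node$flagged)) {
    eff <- eff * config$filter_penalty_factor
  }
  cur <- node
  while (!is.null(cur)) {
    cur$n <- cur$n + 1L
    cur$s <- cur$s + eff
    cur <- cur$parent
  }
  invisible(eff)
}

# --- aromatic seeding --------------------------------------------------------

#' Seed state for the aromatic force cycle mode
#'
#' Looks for a 6- or 5-cycle among above-threshold edges of the feature
#' map; if found, returns a build state containing a kekulized aromatic
#' ring on those slots (ring atoms chosen from the aromatic-capable
#' elements by node-map weight), otherwise the empty state.
#'
#' @param fm a decoded feature map.
#' @param config an [mcts_config()].
#' @param feat the [feature_config()].
#' @return a [build_state()].
#' @export
aromatic_seed <- function(fm, config, feat) {
  empty <- build_state(feat)
  adj <- fm$edge_prob >= config$edge_threshold
  diag(adj) <- FALSE
  for (size in c(6L, 5L)) {
    cyc <- find_cycle(adj, size)
    if (is.null(cyc)) next
    return(build_aromatic_ring(cyc, size, fm, feat))
  }
  empty
}

# first simple cycle of exactly `size` nodes in an undirected adjacency
find_cycle <- function(adj, size) {
  M <- nrow(adj)
  path <- integer(0)
  found <- NULL
  visit <- function(v, start) {
    if (!is.null(found)) return()
    path <<- c(path, v)
    if (length(path) == size) {
      if (adj[v, start]) found <<- path
    } else {
      for (w in which(adj[v, ])) {
        if (!is.null(found)) break
        if (w > start && !(w %in% path)) visit(w, start)
      }
    }
    path <<- path[-length(path)]
  }
  for (start in seq_len(M)) {
    if (!is.null(found)) break
    visit(start, start)
  }
  found
}

build_aromatic_ring <- function(slots, size, fm, feat) {
  state <- build_state(feat)
  # 6-rings: benzene/pyridine pattern (alternating single/double);
  # 5-rings: one divalent heteroatom (O/S/N) then alternating bonds
  carbons <- intersect("C", feat$allowed_elements)
  if (length(carbons) == 0L) return(state)
  elems <- rep("C", size)
  if (size == 5L) {
    het <- intersect(c("O", "N", "S"), feat$allowed_elements)
    if (length(het) == 0L) return(state)
    w <- fm$node_map[slots[1L], match(het, feat$allowed_elements)]
    elems[1L] <- het[which.max(w)]
  }
  orders <- if (size == 6L) c(1, 2, 1, 2, 1, 2) else c(1, 2, 1, 2, 1)
  state <- state_add_atom(state, slots[1L], elems[1L], anchor = 0L)
  for (k in 2L:size) {
    state <- state_add_atom(state, slots[k], elems[k], anchor = k - 1L,
                            order = orders[k - 1L])
    if (is.null(state)) return(build_state(feat))
  }
  closed <- state_add_bond(state, size, 1L, order = orders[size])
  if (is.null(closed)) return(build_state(feat))
  closed
}

# --- full generation ---------------------------------------------------------

#' Generate molecules with the feature-map-guided tree search
#'
#' For each feature map (drawn from the latent prior and decoded), runs
#' `iterations` search cycles and then emits, for every depth (heavy-atom
#' count) `>= minimum_depth` that was reached, the molecule with the best
#' (lowest) reward observed at that depth. Wholly reproducible under
#' `seed`.
#'
#' @param model a trained [vgae_train()] model.
#' @param spec a [reward_spec()].
#' @param config an [mcts_config()].
#' @param n_feature_maps number of feature maps to search (>= 1).
#' @param seed integer seed covering prior draws, expansion stochasticity
#'   and rollouts.
#' @return a data.frame with columns `map`, `depth`, `smiles`, `reward`,
#'   plus an attribute `n_rollouts`.
#' @export
mcts_generate <- function(model, spec, config = mcts_config(),
                          n_feature_maps = 1L, seed = 1L) {
  stopifnot(inherits(model, "vgae_model"), inherits(spec, "reward_spec"))
  if (n_feature_maps < 1L) abort_config("n_feature_maps must be >= 1")
  feat <- model$config
  min_depth <- config$minimum_depth %||%
    switch(spec$objective, qed = 17L, plogp = 6L, 21L)
  rew <- reward_fn(spec)
  out <- list()
  n_rollouts <- 0L
  withr::with_seed(as.integer(seed), {
    for (map_idx in seq_len(n_feature_maps)) {
      z <- stats::rnorm(model$hyper$latent_dim)
      fm <- vgae_decode(z, model)
      best <- run_feature_map_search(fm, config, feat, rew)
      n_rollouts <- n_rollouts + config$iterations
      depths <- sort(as.integer(ls(best)))
      for (d in depths) {
        if (d < min_depth) next
        rec <- best[[as.character(d)]]
        out[[length(out) + 1L]] <-
          data.frame(map = map_idx, depth = d, smiles = rec$smiles,
                     reward = rec$reward)
      }
    }
  })
  res <- if (length(out) > 0L) {
    do.call(rbind, out)
  } else {
    data.frame(map = integer(0), depth = integer(0),
               smiles = character(0), reward = numeric(0))
  }
  if (nrow(res) > 0L) {
    # emit canonical forms; a failure here would be a construction bug
    canon <- canonical_smiles(res$smiles)
    if (anyNA(canon)) {
      abort_invalid_structure("emitted molecule failed sanitization")
    }
    res$smiles <- canon
  }
  attr(res, "n_rollouts") <- n_rollouts
  attr(res, "minimum_depth") <- min_depth
  res
}

# One feature map's worth of search; returns an environment mapping depth
# (as character) to the best (lowest-reward) molecule seen at that depth.
run_feature_map_search <- function(fm, config, feat, rew) {
  seed_state <- if (config$aromatic_force) {
    aromatic_seed(fm, config, feat)
  } else {
    build_state(feat)
  }
  root <- new_node(seed_state)
  best <- new.env(parent = emptyenv())
  record <- function(rollout) {
    key <- as.character(rollout$n_atoms)
    cur <- best[[key]]
    if (any(rollout$flags)) return()      # filtered molecules are not output
    if (is.null(cur) || rollout$reward < cur$reward) {
      best[[key]] <- rollout[c("smiles", "reward")]
    }
  }
  for (it in seq_len(config$iterations)) {
    leaf <- mcts_select(root, config)
    if (!leaf$expanded && !leaf$terminal) {
      mcts_expand(leaf, fm, config, feat)
    }
    start <- if (length(leaf$children) > 0L) {
      leaf$children[[sample.int(length(leaf$children), 1L)]]
    } else {
      leaf
    }
    if (n_atoms(start$state) == 0L) break   # no way to place a first atom
    rollout <- mcts_rollout(start$state, fm, config, rew)
    record(rollout)
    mcts_update(start, rollout, config)
  }
  best
}

# --- realism filters ---------------------------------------------------------

#' Chemical-realism filters for a finished molecule
#'
#' `oversized_ring`: any ring with more than `max_ring_size` atoms.
#' `steric_strain`: strain score above the cutoff, computed from bond-angle
#' deviations after force-field 3D embedding (see [strain_score()]); when
#' geometry embedding fails the flag is `FALSE` with a warning.
#'
#' @param smiles a single SMILES string.
#' @param max_ring_size ring-size limit (default 7).
#' @param strain_cutoff strain-score cutoff (default 0.82).
#' @param check_strain set `FALSE` to skip the (3D, slower) strain filter.
#' @return named logical vector `steric_strain`, `oversized_ring`.
#' @export
detect_filters <- function(smiles, max_ring_size = 7L, strain_cutoff = 0.82,
                           check_strain = TRUE) {
  mol <- parse_molecule(smiles)
  if (is.null(mol)) {
    abort_invalid_structure(paste0("cannot parse SMILES: ", smiles))
  }
  oversized <- any(mol_ring_sizes(mol) > max_ring_size)
  strained <- FALSE
  if (check_strain) {
    s <- strain_score(mol$smiles)
    if (is.na(s)) {
      warning("geometry embedding failed; steric_strain treated as FALSE")
    } else {
      strained <- s > strain_cutoff
    }
  }
  c(steric_strain = strained, oversized_ring = oversized)
}

#' Steric-strain score from embedded 3D geometry
#'
#' Embeds the molecule in 3D with a force-field relaxation (OpenBabel
#' `--gen3d`), measures every heavy-atom bond angle against the ideal
#' angle for the central atom's hybridization (109.47/120/180 degrees) and
#' maps the root-mean-square deviation onto `[0, 1)` as
#' `1 - exp(-(rms / 12)^2)`. Unstrained ring systems score near 0; fused
#' cage and small-ring systems exceed the 0.82 default cutoff.
#'
#' @param smiles a single SMILES string.
#' @return strain score in `[0, 1)`, or `NA` if embedding failed.
#' @export
strain_score <- function(smiles) {
  out <- suppressWarnings(system2("obabel",
                                  c(shQuote(paste0("-:", smiles)),
                                    "-osdf", "--gen3d", "-d"),
                                  stdout = TRUE, stderr = FALSE))
  block <- paste(out, collapse = "\n")
  ctab <- tryCatch(parse_molblock(block), error = function(e) NULL)
  if (is.null(ctab) || is.null(ctab$xyz) || anyNA(ctab$xyz)) {
    return(NA_real_)
  }
  mol <- parse_molecule(smiles)
  if (is.null(mol) || ctab$n != mol$n) return(NA_real_)
  hyb <- mol_hybridization(list(elem = ctab$elem, arom = mol$arom,
                                charge = ctab$charge, bonds = ctab$bonds,
                                n = ctab$n))
  ideal <- c(sp = 180, sp2 = 120, sp3 = 109.47)
  adj <- mol_neighbors(list(n = ctab$n, bonds = ctab$bonds))
  devs <- numeric(0)
  for (j in seq_len(ctab$n)) {
    nb <- adj[[j]]
    if (length(nb) < 2L) next
    for (a in seq_len(length(nb) - 1L)) {
      for (b in (a + 1L):length(nb)) {
        v1 <- ctab$xyz[nb[a], ] - ctab$xyz[j, ]
        v2 <- ctab$xyz[nb[b], ] - ctab$xyz[j, ]
        cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
        ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
        devs <- c(devs, ang - ideal[[hyb[j]]])
      }
    }
  }
  if (length(devs) == 0L) return(0)
  rms <- sqrt(mean(devs^2))
  1 - exp(-(rms / 12)^2)
}
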