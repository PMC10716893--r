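# Shared fixtures for the suite. Expensive objects (a small trained model)
# are built once per test run and cached.

.helper_cache <- new.env(parent = emptyenv())

helper_feature_config <- function() {
  if (is.null(.helper_cache$cfg)) {
    .helper_cache$cfg <- feature_config(max_atoms = 12)
  }
  .helper_cache$cfg
}

helper_smiles <- function(n = 40) {
  key <- paste0("smiles_", n)
  if (is.null(.helper_cache[[key]])) {
    pool <- make_fixture_set(200, seed = 42)
    small <- Filter(function(s) {
      g <- tryCatch(smiles_to_graph(s, helper_feature_config()),
                    molgrow_error = function(e) NULL)
      !is.null(g)
    }, pool)
    .helper_cache[[key]] <- utils::head(small, n)
  }
  .helper_cache[[key]]
}

# A small trained model shared by the auto-encoder and search tests.
helper_model <- function() {
  if (is.null(.helper_cache$model)) {
    cfg <- helper_feature_config()
    graphs <- lapply(helper_smiles(40), smiles_to_graph, config = cfg)
    .helper_cache$model <- vgae_train(
      graphs, cfg,
      hyper = list(epochs = 12, batch_size = 16, val_frac = 0),
      seed = 7)
  }
  .helper_cache$model
}

helper_graphs <- function() {
  lapply(helper_smiles(40), smiles_to_graph,
         config = helper_feature_config())
}

# Rebuild a build_state from a parsed molecule (atoms in parse order).
state_from_smiles <- function(smiles, cfg) {
  mol <- molgrow:::parse_molecule(smiles)
  st <- build_state(cfg)
  st <- molgrow:::state_add_atom(st, 1L, mol$elem[1], anchor = 0L)
  if (mol$n >= 2L) {
    for (a in 2:mol$n) {
      sel <- (mol$bonds$i == a & mol$bonds$j < a) |
        (mol$bonds$j == a & mol$bonds$i < a)
      b <- mol$bonds[sel, , drop = FALSE][1L, ]
      anchor <- min(b$i, b$j)
      st <- molgrow:::state_add_atom(st, a, mol$elem[a], anchor = anchor,
                                     order = b$order)
    }
  }
  for (k in seq_len(nrow(mol$bonds))) {
    b <- mol$bonds[k, ]
    done <- nrow(st$bonds) > 0L &&
      any(st$bonds[, 1L] == min(b$i, b$j) & st$bonds[, 2L] == max(b$i, b$j))
    if (!done) {
      st <- molgrow:::state_add_bond(st, b$i, b$j, order = b$order)
    }
  }
  st
}

# A decoded-feature-map stand-in with explicit probabilities, for search
# tests that need full control over candidate edges.
toy_feature_map <- function(edge_prob, cfg, node_map = NULL) {
  if (is.null(node_map)) {
    node_map <- matrix(0, nrow(edge_prob), cfg$d_node)
    node_map[, match("C", cfg$allowed_elements)] <- 1
  }
  structure(list(edge_prob = edge_prob, node_map = node_map, config = cfg),
            class = "decoded_feature_map")
}

# Exact two-sided Mann-Whitney p-value by full enumeration of rank
# assignments (no ties), used as the oracle for small samples.
exact_mw_p <- function(a, b) {
  n_a <- length(a)
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  r_obs <- sum(rank(pooled)[seq_len(n_a)])
  u_obs <- r_obs - n_a * (n_a + 1) / 2
  n <- length(pooled)
  mid <- n_a * length(b) / 2
  combos <- utils::combn(n, n_a)
  us <- apply(combos, 2, function(idx) {
    sum(rank(pooled)[idx]) - n_a * (n_a + 1) / 2
  })
  mean(abs(us - mid) >= abs(u_obs - mid))
}
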