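test_that("ucb_value implements minimized UCB1 with forced first visits", {
  expect_identical(ucb_value(0, 0, 5), -Inf)
  # frozen arithmetic oracle: 0.5/1 - 1.5*sqrt(ln 2 / 1)
  expect_equal(ucb_value(0.5, 1, 2, c = 1.5), -0.7488319, tolerance = 1e-6)
  # exploration term vanishes: value increases toward s/n as n grows
  vals <- vapply(c(1, 5, 50, 500, 5e5), function(n) {
    ucb_value(0.4 * n, n, 1e6, c = 1.5)
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals < 0.4))
  expect_lt(abs(vals[5] - 0.4), 0.01)
})

make_manual_tree <- function(spec_list, cfg) {
  st <- build_state(cfg)
  st <- molgrow:::state_add_atom(st, 1L, "C", anchor = 0L)
  build <- function(spec, parent) {
    node <- molgrow:::new_node(st, parent = parent)
    node$s <- spec$s
    node$n <- spec$n
    if (!is.null(spec$children)) {
      node$expanded <- TRUE
      node$children <- lapply(spec$children, build, parent = node)
    }
    node
  }
  build(spec_list, NULL)
}

test_that("selection matches exhaustive argmin on a hand-built tree", {
  cfg <- helper_feature_config()
  config <- mcts_config(iterations = 1)
  # 3-level tree with fully specified statistics
  tree <- make_manual_tree(list(
    s = 10, n = 20, children = list(
      list(s = 2.0, n = 5, children = list(
        list(s = 0.9, n = 2), list(s = 1.2, n = 3))),
      list(s = 4.5, n = 10, children = list(
        list(s = 1.0, n = 4), list(s = 2.0, n = 6))),
      list(s = 3.0, n = 5))), cfg)

  # brute-force oracle: recompute the argmin path by hand at each level
  oracle_path <- function(node) {
    path <- list()
    while (node$expanded && length(node$children) > 0L) {
      vals <- vapply(node$children, function(ch) {
        if (ch$n == 0) -Inf else {
          ch$s / ch$n - 1.5 * sqrt(log(max(node$n, 1)) / ch$n)
        }
      }, numeric(1))
      node <- node$children[[which.min(vals)]]
      path[[length(path) + 1L]] <- node
    }
    node
  }
  expect_identical(mcts_select(tree, config), oracle_path(tree))

  # all children unvisited -> first child by the tie-break
  tied <- make_manual_tree(list(
    s = 0, n = 1, children = list(
      list(s = 0, n = 0), list(s = 0, n = 0), list(s = 0, n = 0))), cfg)
  expect_identical(mcts_select(tied, config), tied$children[[1]])

  # returned node depth equals the path length from the root
  sel <- mcts_select(tree, config)
  d <- 0L; cur <- sel
  while (!is.null(cur$parent)) { d <- d + 1L; cur <- cur$parent }
  expect_equal(sel$depth - tree$depth, d)
})

test_that("candidate_edges matches brute-force enumeration on a toy map", {
  cfg <- feature_config(max_atoms = 5)
  P <- matrix(c(0.00, 0.50, 0.10, 0.09, 0.30,
                0.50, 0.00, 0.80, 0.02, 0.00,
                0.10, 0.80, 0.00, 0.15, 0.60,
                0.09, 0.02, 0.15, 0.00, 0.40,
                0.30, 0.00, 0.60, 0.40, 0.00), 5, 5, byrow = TRUE)
  fm <- toy_feature_map(P, cfg)
  st <- build_state(cfg)
  st <- molgrow:::state_add_atom(st, 1L, "C", anchor = 0L)
  st <- molgrow:::state_add_atom(st, 2L, "C", anchor = 1L)

  cands <- candidate_edges(fm, st, threshold = 0.10)
  # brute force over the matrix: placed slots {1,2}, unplaced {3,4,5}
  expected <- 0L
  for (si in 1:2) {
    for (sj in 1:5) {
      if (sj == si) next
      if (P[si, sj] < 0.10) next
      if (sj <= 2 && sj < si) next                  # dedup placed pairs
      if (sj <= 2) next_is_bonded <- TRUE else next_is_bonded <- FALSE
      if (sj <= 2 && next_is_bonded) next           # 1-2 already bonded
      expected <- expected + 1L
    }
  }
  expect_equal(nrow(cands), expected)
  # threshold is inclusive: probability exactly 0.10 is in (slot 1-3)
  expect_true(any(cands$i == 1 & cands$slot == 3))
  # all probabilities below threshold -> empty
  none <- candidate_edges(toy_feature_map(matrix(0.05, 5, 5), cfg), st,
                          threshold = 0.10)
  expect_equal(nrow(none), 0L)
  # every returned candidate really is above threshold and non-self
  for (k in seq_len(nrow(cands))) {
    si <- st$slots[cands$i[k]]
    expect_gte(P[si, cands$slot[k]], 0.10)
    expect_true(si != cands$slot[k])
  }
})

test_that("expansion creates valence-safe children one level deeper", {
  cfg <- feature_config(max_atoms = 5)
  P <- matrix(0.5, 5, 5); diag(P) <- 0
  fm <- toy_feature_map(P, cfg)
  config <- mcts_config(iterations = 1)
  st <- build_state(cfg)
  st <- molgrow:::state_add_atom(st, 1L, "C", anchor = 0L)
  node <- molgrow:::new_node(st)
  withr::with_seed(2, children <- mcts_expand(node, fm, config, cfg))
  expect_gt(length(children), 0L)
  for (ch in children) {
    expect_equal(ch$depth, node$depth + 1L)
    expect_true(all(ch$state$osum <=
                      molgrow:::max_valence_of(ch$state$elem)))
    expect_equal(nrow(ch$state$bonds), n_atoms(ch$state) - 1L)
  }
  # no admissible action -> terminal node (fluorine is saturated)
  stF <- build_state(cfg)
  stF <- molgrow:::state_add_atom(stF, 1L, "F", anchor = 0L)
  stF <- molgrow:::state_add_atom(stF, 2L, "F", anchor = 1L)
  nodeF <- molgrow:::new_node(stF)
  expect_length(mcts_expand(nodeF, fm, config, cfg), 0L)
  expect_true(nodeF$terminal)
})

test_that("rollouts are seeded, sanitize, and return terminal states as-is", {
  cfg <- feature_config(max_atoms = 6)
  P <- matrix(0.4, 6, 6); diag(P) <- 0
  fm <- toy_feature_map(P, cfg)
  config <- mcts_config(iterations = 1)
  rew <- function(s) 0.5
  st <- build_state(cfg)
  st <- molgrow:::state_add_atom(st, 1L, "C", anchor = 0L)

  r1 <- withr::with_seed(21, mcts_rollout(st, fm, config, rew))
  r2 <- withr::with_seed(21, mcts_rollout(st, fm, config, rew))
  expect_identical(r1$smiles, r2$smiles)
  expect_true(is_valid_smiles(r1$smiles))
  expect_equal(r1$reward, 0.5)

  # terminal input comes back unchanged: two saturated fluorines
  stF <- build_state(cfg)
  stF <- molgrow:::state_add_atom(stF, 1L, "F", anchor = 0L)
  stF <- molgrow:::state_add_atom(stF, 2L, "F", anchor = 1L)
  rF <- withr::with_seed(3, mcts_rollout(stF, fm, config, rew))
  expect_equal(rF$n_atoms, 2L)
  expect_identical(canonical_smiles(rF$smiles), "FF")
})

test_that("update conserves visits and applies the 10x filter penalty", {
  cfg <- helper_feature_config()
  config <- mcts_config(iterations = 1)
  st <- build_state(cfg)
  st <- molgrow:::state_add_atom(st, 1L, "C", anchor = 0L)
  root <- molgrow:::new_node(st)
  child <- molgrow:::new_node(st, parent = root)
  leaf <- molgrow:::new_node(st, parent = child)

  clean <- list(smiles = "CC", reward = 0.3, n_atoms = 2,
                flags = c(oversized_ring = FALSE, steric_strain = FALSE),
                aromatic = FALSE)
  mcts_update(leaf, clean, config)
  for (node in list(root, child, leaf)) {
    expect_equal(node$n, 1L)
    expect_equal(node$s, 0.3)
  }

  flagged <- clean
  flagged$flags[["oversized_ring"]] <- TRUE
  mcts_update(leaf, flagged, config)
  expect_equal(leaf$s, 0.3 + 3.0)   # flagged backup is 10x the clean one
  expect_equal(root$n, 2L)

  # aromatic-mode bonus: reward lowered by 0.5, floored at 0
  cfg_ar <- mcts_config(iterations = 1, aromatic_force = TRUE)
  leaf2 <- molgrow:::new_node(st, parent = root)
  arom <- list(smiles = "c1ccccc1", reward = 0.4, n_atoms = 6,
               flags = c(oversized_ring = FALSE, steric_strain = FALSE),
               aromatic = TRUE)
  mcts_update(leaf2, arom, cfg_ar)
  expect_equal(leaf2$s, 0)          # max(0, 0.4 - 0.5)
})

test_that("after k iterations the root has been visited k times", {
  model <- helper_model()
  fm <- vgae_decode(sample_prior(model, seed = 4), model)
  config <- mcts_config(iterations = 60, minimum_depth = 3)
  rew <- molgrow:::reward_fn(reward_spec("custom", fn = function(s) 0.5))
  seed_state <- build_state(model$config)
  seed_state <- molgrow:::state_add_atom(seed_state, 1L, "C", anchor = 0L)
  root <- molgrow:::new_node(seed_state)
  withr::with_seed(17, {
    for (it in 1:60) {
      leaf <- mcts_select(root, config)
      if (!leaf$expanded && !leaf$terminal) {
        mcts_expand(leaf, fm, config, model$config)
      }
      start <- if (length(leaf$children) > 0L) {
        leaf$children[[sample.int(length(leaf$children), 1L)]]
      } else leaf
      ro <- mcts_rollout(start$state, fm, config, rew)
      mcts_update(start, ro, config)
    }
  })
  expect_equal(root$n, 60L)
  # child visits sum to the root total
  expect_equal(sum(vapply(root$children, function(ch) ch$n, integer(1))),
               60L)
})

test_that("visits concentrate on the lower-reward arm (bandit oracle)", {
  # two-arm synthetic tree: fixed rewards 0.2 vs 0.8
  cfg <- helper_feature_config()
  config <- mcts_config(iterations = 1, c = 1.5)
  st <- build_state(cfg)
  st <- molgrow:::state_add_atom(st, 1L, "C", anchor = 0L)
  root <- molgrow:::new_node(st)
  a <- molgrow:::new_node(st, parent = root)
  b <- molgrow:::new_node(st, parent = root)
  root$children <- list(a, b)
  root$expanded <- TRUE
  a$terminal <- TRUE; a$expanded <- TRUE
  b$terminal <- TRUE; b$expanded <- TRUE
  rewards <- c(0.2, 0.8)
  for (it in 1:100) {
    leaf <- mcts_select(root, config)
    arm <- if (identical(leaf, a)) 1L else 2L
    ro <- list(smiles = "C", reward = rewards[arm], n_atoms = 1,
               flags = c(oversized_ring = FALSE, steric_strain = FALSE),
               aromatic = FALSE)
    mcts_update(leaf, ro, config)
  }
  expect_equal(root$n, 100L)
  expect_gt(a$n / 100, 0.6)   # exact-enumeration bandit: low arm dominates

  # filter effect: the flagged twin of an identical arm is visited less
  root2 <- molgrow:::new_node(st)
  clean_arm <- molgrow:::new_node(st, parent = root2)
  flagged_arm <- molgrow:::new_node(st, parent = root2, flagged = TRUE)
  root2$children <- list(clean_arm, flagged_arm)
  root2$expanded <- TRUE
  clean_arm$terminal <- clean_arm$expanded <- TRUE
  flagged_arm$terminal <- flagged_arm$expanded <- TRUE
  for (it in 1:100) {
    leaf <- mcts_select(root2, config)
    ro <- list(smiles = "C", reward = 0.4, n_atoms = 1,
               flags = c(oversized_ring = FALSE, steric_strain = FALSE),
               aromatic = FALSE)
    mcts_update(leaf, ro, config)
  }
  expect_lt(flagged_arm$n, clean_arm$n)
})

test_that("aromatic seeding builds 5/6-rings only when the map allows", {
  cfg <- feature_config(max_atoms = 8)
  config <- mcts_config(iterations = 1)
  # thresholded 6-cycle over slots 1..6
  P <- matrix(0, 8, 8)
  cyc <- c(1, 2, 3, 4, 5, 6, 1)
  for (k in 1:6) P[cyc[k], cyc[k + 1]] <- P[cyc[k + 1], cyc[k]] <- 0.9
  st <- aromatic_seed(toy_feature_map(P, cfg), config, cfg)
  expect_equal(n_atoms(st), 6L)
  expect_equal(state_ring_sizes(st), 6L)
  expect_identical(canonical_smiles(assemble_molecule(st)), "c1ccccc1")

  # 5-cycle map seeds a 5-ring with one heteroatom
  P5 <- matrix(0, 8, 8)
  cyc5 <- c(1, 2, 3, 4, 5, 1)
  for (k in 1:5) P5[cyc5[k], cyc5[k + 1]] <- P5[cyc5[k + 1], cyc5[k]] <- 0.9
  nm <- matrix(0, 8, cfg$d_node)
  nm[, match("C", cfg$allowed_elements)] <- 0.6
  nm[, match("O", cfg$allowed_elements)] <- 0.4
  st5 <- aromatic_seed(toy_feature_map(P5, cfg, nm), config, cfg)
  expect_equal(n_atoms(st5), 5L)
  expect_true(state_ring_sizes(st5) %in% c(5L, 6L))

  # no above-threshold cycle -> empty state
  st0 <- aromatic_seed(toy_feature_map(matrix(0.01, 8, 8), cfg), config, cfg)
  expect_equal(n_atoms(st0), 0L)
})

test_that("aromatic mode raises the share of aromatic molecules (paired)", {
  model <- helper_model()
  spec <- reward_spec("custom", fn = function(s) 0.5)
  frac_aromatic <- function(aromatic_force) {
    config <- mcts_config(iterations = 40, minimum_depth = 3,
                          aromatic_force = aromatic_force)
    gen <- mcts_generate(model, spec, config, n_feature_maps = 20,
                         seed = 31)
    if (nrow(gen) == 0L) return(0)
    mean(vapply(gen$smiles, molgrow:::molecule_is_aromatic, logical(1)))
  }
  expect_gte(frac_aromatic(TRUE), frac_aromatic(FALSE))
})

test_that("generate emits only molecules at or above minimum_depth", {
  model <- helper_model()
  spec <- reward_spec("qed")
  config <- mcts_config(iterations = 40, minimum_depth = 5)
  gen <- mcts_generate(model, spec, config, n_feature_maps = 3, seed = 19)
  expect_true(all(gen$depth >= 5))
  expect_true(all(is_valid_smiles(gen$smiles)))
  gen2 <- mcts_generate(model, spec, config, n_feature_maps = 3, seed = 19)
  expect_identical(gen, gen2)
})

test_that("realism filters flag oversized rings and strained cages", {
  f <- detect_filters("C1CCCCCCC1", check_strain = FALSE)   # cyclooctane
  expect_true(f[["oversized_ring"]])
  f <- detect_filters("c1ccccc1")
  expect_false(f[["oversized_ring"]])
  expect_false(f[["steric_strain"]])
  # cubane: ~90 degree angles at sp3 carbons exceed the 0.82 cutoff
  f <- detect_filters("C1C2C3C1C1C2C3C1")
  expect_true(f[["steric_strain"]])
  s <- strain_score("C1CCCCC1")
  expect_lt(s, 0.2)
})
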