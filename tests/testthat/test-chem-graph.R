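test_that("smiles_to_graph handles single atoms, aromatics and bad input", {
  cfg <- feature_config(max_atoms = 8)

  g <- smiles_to_graph("C", cfg)
  expect_equal(g$n_atoms, 1L)
  expect_true(all(g$edge_features == 0))

  g <- smiles_to_graph("c1ccccc1", cfg)
  expect_equal(g$n_atoms, 6L)
  arom_idx <- match("aromatic", cfg$bond_types)
  expect_equal(sum(g$edge_features[, , arom_idx]) / 2, 6)  # 6 aromatic bonds
  expect_equal(g$edge_features, aperm(g$edge_features, c(2, 1, 3)))

  expect_error(smiles_to_graph("C(", cfg),
               class = "molgrow_invalid_structure")
  expect_error(smiles_to_graph("not a molecule", cfg),
               class = "molgrow_invalid_structure")
  expect_error(smiles_to_graph("C1CCCCCCCCC1", cfg),
               class = "molgrow_capacity_error")      # 10 atoms > 8 slots
  expect_error(smiles_to_graph("[Si](C)(C)C", cfg),
               class = "molgrow_capacity_error")      # out of vocabulary
})

test_that("padding region is exactly zero beyond n_atoms", {
  cfg <- feature_config(max_atoms = 10)
  g <- smiles_to_graph("CCO", cfg)
  expect_true(all(g$node_features[4:10, ] == 0))
  expect_true(all(g$edge_features[4:10, , ] == 0))
  expect_true(all(g$edge_features[, 4:10, ] == 0))
  expect_true(all(diag(g$edge_features[, , 1]) == 0))
})

test_that("graph -> state -> assembly round-trips canonical structures", {
  cfg <- feature_config(max_atoms = 20)
  for (s in c("CC(=O)Oc1ccccc1C(=O)O", "c1ccncc1", "CC(C)CO",
              "C1CC2CC1CC2", "c1cnc2ccccc2c1", "N#Cc1ccc(Cl)cc1",
              helper_smiles(10))) {
    canon <- canonical_smiles(s)
    st <- state_from_smiles(s, cfg)
    expect_identical(assemble_molecule(st), canon, label = s)
  }
})

test_that("assemble_molecule covers the trivial and erroneous cases", {
  cfg <- feature_config(max_atoms = 6)
  st <- build_state(cfg)
  st <- molgrow:::state_add_atom(st, 1L, "C", anchor = 0L)
  expect_identical(assemble_molecule(st), "C")
  st2 <- molgrow:::state_add_atom(st, 2L, "C", anchor = 1L)
  expect_identical(assemble_molecule(st2), "CC")

  expect_error(assemble_molecule(build_state(cfg)),
               class = "molgrow_invalid_structure")

  # a corrupted state (valence violated behind the API's back) must raise
  bad <- st2
  bad$bonds <- rbind(bad$bonds, c(1, 2, 3), c(1, 2, 1))
  bad$osum <- c(5, 5)
  expect_error(assemble_molecule(bad), class = "molgrow_invalid_structure")
})

test_that("valence_ok matches a brute-force bond-order check", {
  cfg <- feature_config(max_atoms = 10)
  maxv <- c(C = 4, N = 3, O = 2, F = 1, P = 5, S = 6, Cl = 1, Br = 1, I = 1)
  for (el in names(maxv)) {
    # enumerate existing bond multisets up to 6 single bonds
    for (existing in 0:6) {
      st <- build_state(cfg)
      st <- molgrow:::state_add_atom(st, 1L, el, anchor = 0L)
      ok_build <- TRUE
      for (k in seq_len(existing)) {
        nxt <- molgrow:::state_add_atom(st, k + 1L, "C", anchor = 1L)
        if (is.null(nxt)) { ok_build <- FALSE; break }
        st <- nxt
      }
      if (!ok_build) next
      for (order in 1:3) {
        expect_identical(valence_ok(st, 1L, order),
                         existing + order <= maxv[[el]],
                         label = paste(el, existing, order))
      }
    }
  }
  # spec examples
  st <- state_from_smiles("C(C)(C)(C)C", cfg)   # carbon with 4 bonds
  expect_false(valence_ok(st, which(st$osum == 4), 1))
  st <- state_from_smiles("N(C)C", cfg)         # nitrogen with 2 bonds
  expect_true(valence_ok(st, which(st$elem == "N"), 1))
  st <- state_from_smiles("O=C", cfg)           # oxygen with 1 double bond
  ox <- which(st$elem == "O")
  expect_false(valence_ok(st, ox, 1))
  expect_error(valence_ok(st, 99L, 1), class = "molgrow_config_error")
})

test_that("read_molecule_file skips bad records and round-trips", {
  tmp <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO ethanol", "xxx(", "c1ccccc1"), tmp)
  expect_message(res <- read_molecule_file(tmp), "skipped 1")
  expect_equal(length(res$smiles), 2L)
  expect_equal(res$n_skipped, 1L)

  empty <- withr::local_tempfile(fileext = ".smi")
  writeLines(character(0), empty)
  res <- read_molecule_file(empty)
  expect_equal(res$smiles, character(0))
  expect_equal(res$n_skipped, 0L)

  # write-then-read preserves canonical forms
  out <- withr::local_tempfile(fileext = ".smi")
  mols <- canonical_smiles(c("CCO", "c1ccccc1O", "CC(=O)N"))
  write_molecule_file(mols, out)
  expect_identical(read_molecule_file(out)$smiles, mols)

  expect_error(read_molecule_file("no/such/file.smi"),
               class = "molgrow_io_error")
})

test_that("sdf records are read through the same skip-reporting path", {
  sdf <- withr::local_tempfile(fileext = ".sdf")
  blocks <- vapply(c("CCO", "c1ccccc1"), function(s) {
    molgrow:::ob_convert("SMI", "SDF", s)
  }, character(1))
  writeLines(paste0(blocks, collapse = ""), sdf)
  res <- read_molecule_file(sdf, format = "sdf")
  expect_setequal(res$smiles, canonical_smiles(c("CCO", "c1ccccc1")))
  expect_equal(res$n_skipped, 0L)
})

test_that("canonicalization strips stereochemistry and isotopes", {
  expect_identical(canonical_smiles("C[C@H](N)C(=O)O"),
                   canonical_smiles("CC(N)C(=O)O"))
  expect_identical(canonical_smiles("F/C=C/F"), canonical_smiles("FC=CF"))
  expect_identical(canonical_smiles("[13CH4]"), canonical_smiles("C"))
})
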