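test_that("benchmark report handles the boundary cases exactly", {
  ref <- helper_smiles(20)

  # generated == reference -> novelty 0
  rep1 <- distribution_benchmark(ref, ref)
  expect_equal(rep1$validity, 1)
  expect_equal(rep1$uniqueness, 1)
  expect_equal(rep1$novelty, 0)

  # disjoint, all valid, all distinct -> all three are 1
  gen <- c("NCCCCN", "OCCCCCO", "ClCCCCCl")
  rep2 <- distribution_benchmark(gen, ref)
  expect_equal(rep2$validity, 1)
  expect_equal(rep2$uniqueness, 1)
  expect_equal(rep2$novelty, 1)

  # duplicated valid molecule -> uniqueness 0.5
  rep3 <- distribution_benchmark(c("CCO", "OCC"), ref)
  expect_equal(rep3$uniqueness, 0.5)

  expect_error(distribution_benchmark(character(0), ref),
               class = "molgrow_config_error")
  expect_true(is.na(rep3$fcd_score))
  rep4 <- distribution_benchmark(gen, ref, fcd_fn = function(g, r) 0.123)
  expect_equal(rep4$fcd_score, 0.123)
})

test_that("count monotonicity survives adversarial inputs", {
  ref <- helper_smiles(15)
  inputs <- list(
    c("CCO", "CCO", "CCO", "((bad", "c1ccccc1"),
    c("((bad", "also bad", "N#N#N#N"),
    c(ref, ref),
    c("C", "CC", "CCC", "CC", "xx(")
  )
  for (gen in inputs) {
    r <- distribution_benchmark(gen, ref)
    cts <- r$counts
    expect_lte(cts[["n_novel"]], cts[["n_unique"]])
    expect_lte(cts[["n_unique"]], cts[["n_valid"]])
    expect_lte(cts[["n_valid"]], cts[["n_generated"]])
    expect_true(all(c(r$validity, r$uniqueness, r$novelty) >= 0))
    expect_true(all(c(r$validity, r$uniqueness, r$novelty) <= 1))
  }
})

test_that("histogram KL matches the closed-form two-bin oracle", {
  # P = (0.5, 0.5), Q = (0.9, 0.1):
  # KL = 0.5 ln(0.5/0.9) + 0.5 ln(0.5/0.1) = 0.5108256
  ref <- c(rep(0.25, 5), rep(0.75, 5))
  gen <- c(rep(0.25, 9), rep(0.75, 1))
  kl <- molgrow:::kl_divergence_hist(ref, gen, bins = 2L, smooth = 1e-9)
  expect_equal(kl, 0.5108256, tolerance = 1e-5)
  # degenerate single-valued descriptor never divides by zero
  expect_true(is.finite(molgrow:::kl_divergence_hist(rep(1, 10),
                                                     rep(1, 10))))
})

test_that("kl_score is ~1 for identical sets and bounded in (0,1]", {
  mols <- helper_smiles(30)
  s_same <- kl_score(mols, mols)
  expect_gt(s_same, 0.98)
  expect_lte(s_same, 1)
  other <- make_fixture_set(30, seed = 77)
  s_other <- kl_score(other, mols)
  expect_gt(s_other, 0)
  expect_lte(s_other, 1)
  expect_error(kl_score(mols[1:5], mols), class = "molgrow_config_error")
})

test_that("a bootstrap of the reference scores high against it", {
  ref <- make_fixture_set(1000, seed = 5)
  boot <- withr::with_seed(6, sample(ref, 1000, replace = TRUE))
  expect_gt(kl_score(boot, ref), 0.9)
})

test_that("mann-whitney matches the exhaustive permutation oracle", {
  # identical samples: U = n^2/2, adjusted p clamps at 1
  a <- c(1, 2, 3, 4)
  res <- mann_whitney_bonferroni(a, a, n_comparisons = 3)
  expect_equal(res$U, length(a)^2 / 2)
  expect_equal(res$p_adjusted, 1)

  # exact enumeration over all C(8,4) = 70 rank assignments
  withr::with_seed(15, {
    for (k in 1:8) {
      ab <- sample(seq_len(40), 8)       # distinct -> no ties
      a <- ab[1:4]; b <- ab[5:8]
      res <- mann_whitney_bonferroni(a, b)
      expect_equal(res$p_raw, exact_mw_p(a, b), tolerance = 1e-10,
                   label = paste(ab, collapse = ","))
    }
    # also n_a = n_b = 5 and unbalanced 3 vs 5
    for (sizes in list(c(5, 5), c(3, 5))) {
      ab <- sample(seq_len(60), sum(sizes))
      a <- ab[seq_len(sizes[1])]
      b <- ab[sizes[1] + seq_len(sizes[2])]
      expect_equal(mann_whitney_bonferroni(a, b)$p_raw, exact_mw_p(a, b),
                   tolerance = 1e-10)
    }
  })

  # Bonferroni never exceeds 1
  res <- mann_whitney_bonferroni(c(1, 2), c(100, 101), n_comparisons = 50)
  expect_lte(res$p_adjusted, 1)

  # all-tied samples warn and return p = 1
  expect_warning(res <- mann_whitney_bonferroni(rep(2, 5), rep(2, 5)),
                 "tied")
  expect_equal(res$p_raw, 1)

  # the default protocol subsamples to 500 seeded values
  big_a <- stats::runif(2000)
  big_b <- stats::runif(2000) + 0.05
  r1 <- mann_whitney_bonferroni(big_a, big_b, subsample = 500, seed = 2)
  r2 <- mann_whitney_bonferroni(big_a, big_b, subsample = 500, seed = 2)
  expect_equal(r1$n_a, 500)
  expect_identical(r1$p_raw, r2$p_raw)
})

test_that("druglike_filter applies every rule", {
  res <- druglike_filter(c("c1ccccc1", "C1CCCCCCC1"), check_strain = FALSE)
  expect_true(canonical_smiles("c1ccccc1") %in% res$kept)
  expect_false(canonical_smiles("C1CCCCCCC1") %in% res$kept)
  expect_gte(res$failures[["ring_size"]], 1)

  # a deliberately heavy molecule (MW > 500) fails the rule of five
  heavy <- "CCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCC"   # C38: MW 535
  res2 <- druglike_filter(heavy, check_strain = FALSE)
  expect_length(res2$kept, 0)
  expect_equal(unname(res2$failures[["lipinski_mw"]]), 1)

  expect_error(druglike_filter("((bad"),
               class = "molgrow_invalid_structure")
})

test_that("strained molecules are screened when the 3D rule is on", {
  cubane <- "C1C2C3C1C1C2C3C1"
  res <- druglike_filter(c("c1ccccc1O", cubane))
  expect_false(canonical_smiles(cubane) %in% res$kept)
  expect_true(canonical_smiles("c1ccccc1O") %in% res$kept)
})

test_that("chemical_space_map is deterministic with sane geometry", {
  mols <- helper_smiles(12)
  xy1 <- chemical_space_map(mols, seed = 1)
  xy2 <- chemical_space_map(mols, seed = 1)
  expect_equal(dim(xy1), c(12L, 2L))
  expect_identical(xy1, xy2)

  # identical structures receive identical fingerprints and coordinates
  dup <- c(mols[1:5], mols[1])
  fp <- fingerprint_matrix(c(mols[1], canonical_smiles(mols[1])))
  expect_equal(fp[1, ], fp[2, ], ignore_attr = TRUE)
  xy <- chemical_space_map(dup, seed = 1)
  expect_equal(unname(xy[6, ]), unname(xy[1, ]), tolerance = 1e-8)

  expect_error(chemical_space_map(mols[1:3]),
               class = "molgrow_config_error")
})

test_that("fingerprints behave like set representations", {
  fp1 <- morgan_fingerprint("CCO")
  expect_length(fp1, 2048L)
  expect_setequal(unique(fp1), c(0L, 1L))
  expect_equal(tanimoto(fp1, fp1), 1)
  fp2 <- morgan_fingerprint("c1ccccc1")
  expect_lt(tanimoto(fp1, fp2), 0.5)
  expect_equal(tanimoto(integer(8), integer(8)), 1)  # empty convention
})
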