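# evaluation: distribution-learning metrics, statistical comparison,
# drug-likeness filtering and chemical-space projection for generated
# molecule sets.

#' Distribution-learning benchmark report
#'
#' `validity` = fraction of generated strings that parse and sanitize;
#' `uniqueness` = distinct canonical forms among the valid molecules /
#' number valid; `novelty` = fraction of unique valid molecules absent
#' from the reference set; `kl_divergence_score` = [kl_score()] of the
#' valid generated set against the reference. An optional `fcd_fn`
#' (external scorer hook) adds `fcd_score`; otherwise it is `NA`.
#'
#' @param generated character vector of generated structures.
#' @param reference character vector of reference (training) structures.
#' @param fcd_fn optional function `(generated, reference) -> numeric`.
#' @return an object of class `benchmark_report`.
#' @export
distribution_benchmark <- function(generated, reference, fcd_fn = NULL) {
  if (length(generated) == 0L || length(reference) == 0L) {
    abort_config("generated and reference sets must be non-empty")
  }
  canon_gen <- canonical_smiles(generated)
  valid <- !is.na(canon_gen)
  n_generated <- length(generated)
  n_valid <- sum(valid)
  uniq <- unique(canon_gen[valid])
  n_unique <- length(uniq)
  canon_ref <- unique(canonical_smiles(reference))
  canon_ref <- canon_ref[!is.na(canon_ref)]
  novel <- setdiff(uniq, canon_ref)
  n_novel <- length(novel)
  klsc <- if (n_valid >= 10L && length(canon_ref) >= 10L) {
    kl_score(canon_gen[valid], canon_ref)
  } else {
    NA_real_
  }
  fcd <- if (is.function(fcd_fn)) fcd_fn(generated, reference) else NA_real_
  structure(list(validity = if (n_generated > 0) n_valid / n_generated else 0,
                 uniqueness = if (n_valid > 0) n_unique / n_valid else 0,
                 novelty = if (n_unique > 0) n_novel / n_unique else 0,
                 kl_divergence_score = klsc,
                 fcd_score = fcd,
                 counts = c(n_generated = n_generated, n_valid = n_valid,
                            n_unique = n_unique, n_novel = n_novel)),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("benchmark_report\n")
  cat(sprintf("  validity:    %.3f\n", x$validity))
  cat(sprintf("  uniqueness:  %.3f\n", x$uniqueness))
  cat(sprintf("  novelty:     %.3f\n", x$novelty))
  cat(sprintf("  KL score:    %s\n",
              ifelse(is.na(x$kl_divergence_score), "NA",
                     sprintf("%.3f", x$kl_divergence_score))))
  if (!is.na(x$fcd_score)) cat(sprintf("  FCD:         %.3f\n", x$fcd_score))
  cat("  counts:", paste(names(x$counts), x$counts, sep = "=",
                         collapse = " "), "\n")
  invisible(x)
}

# descriptor panel for the KL score; configurable via `panel`
kl_descriptor_panel <- function(smiles) {
  rows <- lapply(smiles, function(s) {
    mol <- parse_molecule(s)
    if (is.null(mol)) return(NULL)
    obm <- ob_parse(mol$smiles)
    data.frame(mw = mol_mw(mol),
               logp = ob_descriptor(obm, "logP"),
               tpsa = ob_descriptor(obm, "TPSA"),
               hba = mol_hba(mol),
               hbd = mol_hbd(mol),
               rotb = mol_rotatable_bonds(mol),
               aliphatic_rings = mol_aliphatic_ring_count(mol),
               aromatic_rings = mol_aromatic_ring_count(mol))
  })
  do.call(rbind, rows)
}

# KL divergence between two samples of one descriptor via shared-bin
# histograms with additive smoothing (never a division by zero, even for
# single-valued descriptors).
kl_divergence_hist <- function(ref, gen, bins = 10L, smooth = 1e-3) {
  rng <- range(c(ref, gen), finite = TRUE)
  if (!all(is.finite(rng))) return(NA_real_)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1L], rng[2L], length.out = bins + 1L)
  p <- graphics::hist(ref, breaks = breaks, plot = FALSE)$counts + smooth
  q <- graphics::hist(gen, breaks = breaks, plot = FALSE)$counts + smooth
  p <- p / sum(p)
  q <- q / sum(q)
  sum(p * log(p / q))
}

#' Distribution-learning KL-divergence score
#'
#' For each descriptor of a fixed physicochemical panel (molecular weight,
#' logP, TPSA, H-bond acceptors/donors, rotatable bonds, aliphatic and
#' aromatic ring counts, plus the internal pairwise-similarity
#' distribution), computes the KL divergence of the generated histogram
#' from the reference histogram (shared bins, additive smoothing) and
#' returns the mean of `exp(-KL)`: 1 means the distributions match.
#'
#' @param generated,reference character vectors with `>= 10` valid
#'   molecules each.
#' @param bins histogram bin count for continuous descriptors.
#' @param similarity_sample how many molecules per set enter the internal
#'   pairwise-similarity distribution.
#' @return score in `(0, 1]`.
#' @export
kl_score <- function(generated, reference, bins = 10L,
                     similarity_sample = 100L) {
  gen <- canonical_smiles(generated); gen <- gen[!is.na(gen)]
  ref <- canonical_smiles(reference); ref <- ref[!is.na(ref)]
  if (length(gen) < 10L || length(ref) < 10L) {
    abort_config("kl_score needs >= 10 valid molecules per set")
  }
  dg <- kl_descriptor_panel(gen)
  dr <- kl_descriptor_panel(ref)
  kls <- vapply(names(dr), function(col) {
    kl_divergence_hist(dr[[col]], dg[[col]], bins = bins)
  }, numeric(1))
  sim_ref <- internal_similarities(ref, similarity_sample)
  sim_gen <- internal_similarities(gen, similarity_sample)
  if (length(sim_ref) > 1L && length(sim_gen) > 1L) {
    kls <- c(kls, similarity = kl_divergence_hist(sim_ref, sim_gen,
                                                  bins = bins))
  }
  mean(exp(-kls), na.rm = TRUE)
}

internal_similarities <- function(smiles, n_sample) {
  s <- unique(smiles)
  if (length(s) > n_sample) s <- s[seq_len(n_sample)]
  if (length(s) < 2L) return(numeric(0))
  fps <- fingerprint_matrix(s)
  sims <- numeric(0)
  for (i in seq_len(nrow(fps) - 1L)) {
    for (j in (i + 1L):nrow(fps)) {
      sims <- c(sims, tanimoto(fps[i, ], fps[j, ]))
    }
  }
  sims
}

#' Mann-Whitney U test with Bonferroni correction
#'
#' Two-sided rank-sum test between two property samples (exact for small
#' untied samples, normal approximation with tie correction otherwise),
#' with the p-value multiplied by the number of comparisons (clamped at
#' 1). The default experiment protocol draws seeded 500-molecule
#' subsamples before testing; pass `subsample = NULL` to test the full
#' vectors.
#'
#' @param sample_a,sample_b numeric property vectors.
#' @param n_comparisons Bonferroni correction factor.
#' @param subsample draw this many values from each sample first
#'   (seeded); `NULL` to use all values.
#' @param seed seed for the subsample draw.
#' @return a list: `U`, `p_raw`, `p_adjusted`, `n_a`, `n_b`.
#' @export
mann_whitney_bonferroni <- function(sample_a, sample_b, n_comparisons = 1L,
                                    subsample = NULL, seed = 1L) {
  if (length(sample_a) == 0L || length(sample_b) == 0L) {
    abort_config("both samples must be non-empty")
  }
  if (!is.null(subsample)) {
    withr::with_seed(as.integer(seed), {
      if (length(sample_a) > subsample) {
        sample_a <- sample(sample_a, subsample)
      }
      if (length(sample_b) > subsample) {
        sample_b <- sample(sample_b, subsample)
      }
    })
  }
  if (length(unique(c(sample_a, sample_b))) == 1L) {
    warning("all values tied across both samples; p = 1")
    return(list(U = length(sample_a) * length(sample_b) / 2, p_raw = 1,
                p_adjusted = 1, n_a = length(sample_a),
                n_b = length(sample_b)))
  }
  wt <- suppressWarnings(stats::wilcox.test(sample_a, sample_b,
                                            alternative = "two.sided"))
  p_raw <- wt$p.value
  list(U = unname(wt$statistic), p_raw = p_raw,
       p_adjusted = min(1, p_raw * n_comparisons),
       n_a = length(sample_a), n_b = length(sample_b))
}

#' Drug-likeness filter
#'
#' Keeps molecules that pass all of: Lipinski's rule of five (MW <= 500,
#' logP <= 5, H-bond donors <= 5, acceptors <= 10), synthetic
#' accessibility <= 5, steric strain below the cutoff, logP <= 5, and
#' largest ring size <= 6.
#'
#' @param smiles character vector of valid structures.
#' @param sa_max synthetic-accessibility limit.
#' @param strain_cutoff steric-strain cutoff (see [strain_score()]).
#' @param check_strain set `FALSE` to skip the 3D strain rule.
#' @return a list: `kept` (surviving canonical SMILES), `failures`
#'   (named counts per rule), `detail` (logical matrix, one row per
#'   molecule).
#' @export
druglike_filter <- function(smiles, sa_max = 5, strain_cutoff = 0.82,
                            check_strain = TRUE) {
  canon <- canonical_smiles(smiles)
  if (anyNA(canon)) {
    abort_invalid_structure("druglike_filter requires sanitizing molecules")
  }
  rules <- c("lipinski_mw", "lipinski_logp", "lipinski_hbd", "lipinski_hba",
             "sa_score", "steric_strain", "logp", "ring_size")
  detail <- matrix(TRUE, nrow = length(canon), ncol = length(rules),
                   dimnames = list(canon, rules))
  for (k in seq_along(canon)) {
    mol <- parse_molecule(canon[k])
    obm <- ob_parse(mol$smiles)
    logp <- ob_descriptor(obm, "logP")
    detail[k, "lipinski_mw"] <- mol_mw(mol) <= 500
    detail[k, "lipinski_logp"] <- logp <= 5
    detail[k, "lipinski_hbd"] <- mol_hbd(mol) <= 5
    detail[k, "lipinski_hba"] <- mol_hba(mol) <= 10
    detail[k, "sa_score"] <- sa_score(mol$smiles) <= sa_max
    if (check_strain) {
      s <- strain_score(mol$smiles)
      detail[k, "steric_strain"] <- is.na(s) || s < strain_cutoff
    }
    detail[k, "logp"] <- logp <= 5
    detail[k, "ring_size"] <- mol_largest_ring(mol) <= 6
  }
  keep <- apply(detail, 1L, all)
  list(kept = canon[keep],
       failures = colSums(!detail),
       detail = detail)
}

#' Project molecules into a 2D chemical-space map
#'
#' 2048-bit circular fingerprints of diameter 4 (radius 2), embedded into
#' two dimensions by classical multidimensional scaling of Jaccard
#' (1 - Tanimoto) distances. Deterministic for fixed input (axis signs are
#' fixed by convention); the `seed` argument is accepted for protocol
#' compatibility with stochastic embedders.
#'
#' @param smiles `>= 5` valid structures.
#' @param seed accepted and recorded; the default embedder is
#'   deterministic.
#' @param radius,nbits fingerprint parameters.
#' @return an `n x 2` coordinate matrix (rows named by input).
#' @export
chemical_space_map <- function(smiles, seed = 1L, radius = 2L,
                               nbits = 2048L) {
  if (length(smiles) < 5L) {
    abort_config("chemical_space_map needs at least 5 molecules")
  }
  fps <- fingerprint_matrix(smiles, radius = radius, nbits = nbits)
  n <- nrow(fps)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- 1 - tanimoto(fps[i, ], fps[j, ])
    }
  }
  coords <- stats::cmdscale(stats::as.dist(d), k = 2L)
  if (ncol(coords) < 2L) {               # degenerate: all points identical
    coords <- cbind(coords, 0)[, 1:2, drop = FALSE]
    if (ncol(coords) < 2L) coords <- matrix(0, n, 2L)
  }
  # deterministic sign convention: largest-magnitude coordinate positive
  for (k in 1:2) {
    col <- coords[, k]
    if (length(col) > 0L && any(col != 0)) {
      if (col[which.max(abs(col))] < 0) coords[, k] <- -col
    }
  }
  rownames(coords) <- smiles
  colnames(coords) <- c("dim1", "dim2")
  coords
}
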