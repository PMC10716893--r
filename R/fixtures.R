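# Seeded fixture-molecule generation: a deterministic combinatorial
# decoration of small drug-like scaffolds. Tests and desk-scale
# experiments train on these sets instead of downloading corpora.

.fixture_env <- new.env(parent = emptyenv())

fixture_scaffolds <- function() {
  list(
    # ring scaffolds: positions marked by {d} take an optional branch
    list(template = "c1c{d}c{d}cc{d}c1", n_dec = 3L),       # benzene
    list(template = "c1c{d}c{d}nc{d}c1", n_dec = 3L),       # pyridine
    list(template = "c1c{d}ncnc1", n_dec = 1L),             # pyrimidine
    list(template = "c1c{d}c{d}oc1", n_dec = 2L),           # furan
    list(template = "c1c{d}c{d}sc1", n_dec = 2L),           # thiophene
    list(template = "c1c{d}c{d}[nH]c1", n_dec = 2L),        # pyrrole
    list(template = "C1CC{d}CC{d}C1", n_dec = 2L),          # cyclohexane
    list(template = "c1c{d}cc2cc{d}ccc2c1", n_dec = 2L),    # naphthalene
    # chain scaffolds: internal carbons take an optional branch
    list(template = "C{d}", n_dec = 1L),
    list(template = "CC{d}", n_dec = 1L),
    list(template = "CC{d}C", n_dec = 1L),
    list(template = "CC{d}C{d}C", n_dec = 2L),
    list(template = "CC{d}C{d}CC", n_dec = 2L),
    list(template = "CC(C)C{d}C", n_dec = 1L),
    list(template = "CC{d}C{d}C{d}CC", n_dec = 3L),
    list(template = "CCC{d}CC{d}CC", n_dec = 2L)
  )
}

fixture_substituents <- function(aromatic) {
  base <- c("F", "Cl", "Br", "O", "N", "C", "CO", "C=O", "C(C)=O")
  if (aromatic) setdiff(base, "C=O") else base
}

# all decorations of one template with at most `max_subs` substituents
decorate_template <- function(template, n_dec, subs, max_subs = 2L) {
  fill <- function(choice) {
    out <- template
    for (k in seq_len(n_dec)) {
      rep_str <- if (choice[k] == 0L) "" else paste0("(", subs[choice[k]], ")")
      out <- sub("{d}", rep_str, out, fixed = TRUE)
    }
    out
  }
  n_s <- length(subs)
  choices <- list(rep(0L, n_dec))
  # single and double substitution patterns, enumerated in fixed order
  for (pos1 in seq_len(n_dec)) {
    for (s1 in seq_len(n_s)) {
      ch <- rep(0L, n_dec); ch[pos1] <- s1
      choices[[length(choices) + 1L]] <- ch
      if (max_subs >= 2L && pos1 < n_dec) {
        for (pos2 in (pos1 + 1L):n_dec) {
          for (s2 in seq_len(n_s)) {
            ch2 <- ch; ch2[pos2] <- s2
            choices[[length(choices) + 1L]] <- ch2
          }
        }
      }
    }
  }
  vapply(choices, fill, character(1))
}

# The full enumerable fixture space (canonical, deduplicated, in
# deterministic enumeration order). Cached per session.
fixture_space <- function() {
  if (!is.null(.fixture_env$space)) return(.fixture_env$space)
  raw <- unlist(lapply(fixture_scaffolds(), function(sc) {
    aromatic <- grepl("c1", sc$template, fixed = TRUE)
    decorate_template(sc$template, sc$n_dec,
                      fixture_substituents(aromatic))
  }))
  canon <- canonical_smiles(raw)
  canon <- canon[!is.na(canon)]
  # drop anything that slipped past 20 heavy atoms (none should)
  sizes <- vapply(canon, function(s) nrow(smiles_scan(s)), integer(1))
  canon <- canon[sizes <= 20L]
  space <- unique(canon)
  .fixture_env$space <- space
  space
}

#' Deterministic fixture molecules
#'
#' Enumerates distinct, valid, small (<= 20 heavy atoms) drug-like
#' molecules by seeded combinatorial decoration of scaffold templates
#' (benzene, pyridine, pyrimidine, furan, thiophene, pyrrole, cyclohexane,
#' alkanes) with common substituents (halogens, hydroxyl, amine, methyl,
#' carbonyl, acetyl). Every output sanitizes; the list is reproducible for
#' a fixed `(n, seed)`.
#'
#' @param n number of molecules (up to the enumerable space).
#' @param seed integer seed fixing the selection order.
#' @return character vector of `n` distinct canonical SMILES.
#' @export
make_fixture_set <- function(n, seed = 1L) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) abort_config("n must be >= 1")
  space <- fixture_space()
  if (n > length(space)) {
    abort_capacity(sprintf(
      "requested %d fixture molecules but the enumerable space holds %d",
      n, length(space)))
  }
  withr::with_seed(as.integer(seed), sample(space, n))
}
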