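# Builds inst/extdata/sa_fragment_scores_synthetic.tsv: the synthetic
# fragment-contribution table behind sa_score(). Circular fragments
# (radius 0-2) are counted over the package's full enumerable fixture
# space; each fragment's contribution is its log10 relative frequency,
# centered on the median fragment and clamped to [-4, 4], so common
# drug-like fragments score positive (easy) and rare ones negative.
# Run from the repository root: Rscript data-raw/make_sa_table.R
devtools::load_all(".", quiet = TRUE)

space <- molgrow:::fixture_space()
cat("fixture space:", length(space), "molecules\n")

counts <- new.env(parent = emptyenv())
for (s in space) {
  mol <- molgrow:::parse_molecule(s)
  ids <- molgrow:::ecfp_fragment_counts(mol, radius = 2L)
  for (id in names(ids)) {
    counts[[id]] <- (counts[[id]] %||% 0) + ids[[id]]
  }
}
ids <- ls(counts)
cnt <- vapply(ids, function(i) counts[[i]], numeric(1))
cat("distinct fragments:", length(cnt), "\n")

score <- log10(cnt) - stats::median(log10(cnt))
score <- pmin(pmax(score, -4), 4)

df <- data.frame(id = ids, score = round(score, 4))
df <- df[order(-df$score), ]
dir.create("inst/extdata", showWarnings = FALSE, recursive = TRUE)
write.table(df, "inst/extdata/sa_fragment_scores_synthetic.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
cat("wrote", nrow(df), "fragment scores\n")
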