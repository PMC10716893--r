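---
title: "Growing molecules with a graph auto-encoder and tree search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growing molecules with a graph auto-encoder and tree search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

molgrow generates small drug-like molecules by combining two ideas:
a **variational graph auto-encoder (VGAE)** learns where known molecules
live, and a **Monte Carlo tree search (MCTS)** builds new molecules
atom-by-atom inside that learned neighborhood, steered by a
physicochemical reward. This vignette is the package's own account of
the model, the parameters that matter, and the design decisions taken
where more than one reasonable choice existed.

## The model

### Molecular graphs

Every molecule is a fixed-size graph over `max_atoms` node slots
(default 38; the desk-scale experiments in this package use 20, the
size cap of the bundled fixture generator). Node features are the
field-standard atom featurization: one-hot element over
{C, N, O, F, P, S, Cl, Br, I}, one-hot heavy-atom degree (0–5), formal
charge, an aromaticity flag and one-hot hybridization
(sp/sp2/sp3/other) — 21 dimensions. Edge features are a one-hot over
{single, double, triple, aromatic}. Rows and slices beyond the actual
atom count are zero, the edge tensor is symmetric with a zero
diagonal, and hydrogens are implicit. Stereochemistry and isotopes are
stripped during canonicalization: the generator never places stereo
bonds, so carrying them through the pipeline would only create
spurious distinctions between otherwise identical molecules.

Atom ordering inside the feature map follows the toolkit's canonical
ranking, so featurization is deterministic.

### The auto-encoder

The encoder applies three edge-conditioned graph-convolution layers of
width 128 (one weight matrix per bond type plus a self-loop term,
ReLU, padding masked), mean-pools over the real atoms and maps the
pooled vector linearly to a 64-dimensional posterior mean and
log-variance. The decoder is a two-layer perceptron from the latent
vector to (i) a node feature map whose element block is soft-maxed per
slot and (ii) an `max_atoms x max_atoms` edge logit map, symmetrized
as `(L + t(L))/2` and squashed through a logistic sigmoid. The loss is
the evidence lower bound:

* reconstruction — element-wise binary cross-entropy over the
  off-diagonal edge map (the full grid, so the decoder also learns
  that padding slots are unconnected) plus cross-entropy over the node
  feature blocks with padding slots masked;
* regularization — the closed-form KL divergence
  `0.5 * sum(exp(lv) + mu^2 - 1 - lv)` against a standard normal
  prior, which is what makes unconditional generation from `N(0, I)`
  legitimate.

Training uses Adam at learning rate 0.001 with batch size 64, the
standard configuration for this model family; both are configurable.
Everything — initialization, shuffling, reparameterization noise — is
driven by one seed, so training is bit-reproducible. The
implementation is plain R with hand-derived gradients: at these sizes
(a few hundred thousand parameters) a deep-learning framework would
add dependency weight without adding capability, and every activation
used here has the convenient `(prediction - target)` backward form.

### The tree search

Generation draws a latent vector from the prior, decodes it into an
edge-probability map and a node feature map, and then runs
Selection–Expansion–Simulation–Update cycles:

* **Selection** descends to the child minimizing
  `s/n - c * sqrt(ln N / n)` with `c = 1.5`; unvisited children score
  `-Inf` so each is tried once. Minimization (rather than the textbook
  maximization) is the natural orientation because rewards are
  "lower is better" (`1 - QED`). Ties break to the lowest child
  index, deterministically.
* **Expansion** enumerates the feature-map edges with probability
  `>= 0.10` (inclusive) that either attach a new atom to the partial
  molecule or close a ring between placed atoms, each with the bond
  orders that both endpoints' valences admit. The new atom's element
  is sampled from the node map's element weights. Every child is
  valence-checked before it exists; that single invariant is what
  makes validity of the final molecules 1.0 by construction rather
  than by filtering.
* **Simulation** completes the molecule with uniformly random
  admissible actions up to the rollout cap (the feature map's
  `max_atoms` by default). The literature gives no rollout policy for
  this construction; uniform random is the assumption-free choice.
* **Update** backs the rollout reward up the path. Molecules
  containing an aromatic ring get the reward lowered by 0.5 (floored
  at 0) when the aromatic mode is on; molecules that fired a realism
  filter have the backed-up value multiplied by 10, which under
  minimization makes flagged branches strongly unattractive.

After the configured number of iterations (8,000 at study scale; 300
in the desk-scale experiments bundled here) the best molecule seen at
every depth at or above `minimum_depth` is emitted, and the search
moves to the next feature map. `minimum_depth` acts as a size floor on
the output; its objective-specific defaults (21 for distribution
benchmarks, 17 for QED, 6 for penalized logP) mirror the sizes at
which those protocols are typically read out.

Two design points admit more than one defensible reading; molgrow
resolves them as follows, keeping the alternative available:

* an additive bonus that *raises* the value of aromatic nodes would
  make them less likely to be selected under smallest-value selection,
  the opposite of the mode's purpose. molgrow therefore subtracts the
  0.5 bonus from the backed-up reward (floored at 0);
  `aromatic_bonus_mode = "add"` gives the raw additive variant.
* `minimum_depth` is interpreted as a size floor — emit best-per-depth
  for depths at or above it — which is consistent with the
  objective-specific defaults: the penalized-logP protocol both uses
  the smallest floor (6) and tolerates the smallest molecules.

### Aromatic seeding

When the aromatic force cycle mode is on (the default), each feature
map is first scanned for a 6-cycle (then a 5-cycle) among
above-threshold edges. If one exists, the search starts from a
kekulized aromatic ring on those slots — all-carbon for 6-rings, one
O/N/S heteroatom (chosen by node-map weight) for 5-rings — rather than
from a bare atom. Ring sizes are fixed to {5, 6}, the aromatic ring
sizes that occur in drug-like chemistry.

## Rewards

* **QED**: the weighted geometric mean of eight desirability functions
  (molecular weight, logP, H-bond acceptors and donors, polar surface
  area, rotatable bonds, aromatic rings, structural alerts) with the
  published asymmetric-double-sigmoid parameters and "mean" weights.
  Descriptors come from the OpenBabel backend; the acceptor and
  structural-alert definitions are the published SMARTS sets. Against
  an independent toolkit implementation the absolute difference is
  typically below 0.02 (the logP and rotor models differ slightly
  between backends). The search reward is `1 - QED`.
* **Penalized logP**: `logP - SA - max(0, largest ring - 6)`, the
  un-normalized convention of the molecule-generation benchmark
  lineage; a z-score-normalized variant (standardized by drug-like
  training-set statistics) sits behind `normalized = TRUE`. The score
  is squashed to (0, 1) by a logistic sigmoid and the reward is
  `1 - sigmoid(penalized logP)`.
* **SA score**: an Ertl-style synthetic-accessibility score in
  [1, 10] — a fragment-familiarity term from a contribution table plus
  size, ring-complexity, spiro, macrocycle and symmetry corrections.
  The original fragment table is derived from a million-compound
  public database and is far too large to pin inside a source-only
  package, so molgrow ships a **synthetic** table
  (`inst/extdata/sa_fragment_scores_synthetic.tsv`) built with the
  same log-frequency recipe over the package's own enumerable fixture
  space. Absolute values therefore differ from the original scorer;
  orderings of simple-vs-complex molecules (the property the reward
  needs) are preserved, and the table file is labelled synthetic.

## Realism filters

* **Oversized rings**: any ring larger than 7 atoms flags the node.
  Ring sizes are tracked incrementally during construction, so this
  filter is essentially free.
* **Steric strain**: the molecule is embedded in 3D with a force-field
  relaxation (OpenBabel `--gen3d`), every heavy-atom bond angle is
  compared with the ideal angle for the central atom's hybridization,
  and the root-mean-square deviation (degrees) maps to a score
  `1 - exp(-(rms/12)^2)`. The 12-degree scale was calibrated once so
  that relaxed reference systems (benzene ~0.00, cyclohexane ~0.03,
  cyclooctane ~0.27) sit far below the 0.82 default cutoff while
  strained cages (cubane ~0.92) sit above it; the metric itself is
  this package's own definition. During tree search the
  strain filter defaults to **off**: a 3D embedding per rollout
  dominates the entire search cost, and the oversized-ring filter
  already removes the dominant class of unrealistic products at this
  scale. It is on in `druglike_filter()`, where molecules are screened
  in batch after generation — so strained products are still removed
  from anything a user would report. Setting
  `use_strain_filter = TRUE` restores in-search filtering.

## Evaluation stack

`distribution_benchmark()` reports validity (fraction sanitizing),
uniqueness (distinct canonical forms among valid), novelty (unique
forms absent from the reference corpus) and a KL-divergence score: for
each descriptor of a fixed panel (MW, logP, TPSA, H-bond donors and
acceptors, rotatable bonds, aliphatic and aromatic ring counts, plus
the internal pairwise-similarity distribution), the KL divergence of
the generated histogram from the reference histogram is computed on
shared bins with additive smoothing, and the score is the mean of
`exp(-KL)`. Histogram binning (10 bins over the pooled range) was
chosen over kernel estimates for determinism and robustness to
degenerate descriptors; the panel is configurable. An FCD (Fréchet
ChemNet Distance) slot exists as an adapter hook: computing it
requires a pretrained chemical network, which the package deliberately
does not bundle, so the field is `NA` unless a scorer function is
supplied.

Statistical comparison of property distributions uses the two-sided
Mann–Whitney U test (exact for small untied samples, normal
approximation with tie correction otherwise) with Bonferroni
correction, on seeded 500-molecule subsamples by default — the
protocol used when comparing generated sets between models.

`chemical_space_map()` computes 2048-bit circular fingerprints of
diameter 4 (radius 2) and embeds Jaccard distances into 2D. The
embedding is classical multidimensional scaling rather than UMAP: no
UMAP implementation is available to this package's R dependency set,
PCoA is deterministic (axis signs fixed by convention), and for
reading "does set A occupy different territory than set B" a metric
embedding is adequate. The fingerprints themselves are the standard
iterative neighborhood-hashing construction and are tested for the
set-like properties the projection relies on.

## The fixture generator

`make_fixture_set()` enumerates decorated scaffolds — benzene,
pyridine, pyrimidine, furan, thiophene, pyrrole, naphthalene,
cyclohexane and short alkanes, decorated with halogens, hydroxyl,
amine, methyl, hydroxymethyl, formyl and acetyl groups — and returns a
seeded sample of the deduplicated canonical space (~1,100 molecules,
all within 20 heavy atoms). It emulates the *shape* of a drug-like
training corpus: a nondegenerate spread of molecular weights, logP,
ring counts and aromaticity, small enough to train against in
seconds. It does not emulate real corpora's scale, scaffold diversity,
charge states, or stereochemistry — so green tests here demonstrate
the machinery end-to-end (validity by construction, reward shaping,
reproducibility), not distribution-learning quality on ChEMBL- or
ZINC-scale data. Corpus-scale training is supported through the same
`run_pipeline()` interface by pointing `paths$corpus` at a SMILES
file.

## Numerical choices and degenerate inputs

* Cross-entropy computations clamp probabilities at `1e-12` from both
  ends; the KL term needs no clamping (closed form).
* Candidate-edge extraction treats the probability threshold as
  inclusive (`>= 0.10`), so a map that puts mass exactly at the
  cutoff still yields moves.
* Selection ties break to the lowest child index; atom-type sampling
  and rollouts consume the single run seed, so a whole
  `mcts_generate()` call is reproducible bit-for-bit.
* A terminal state fed to the rollout returns itself; an empty state
  expands by placing one first atom (one child per vocabulary
  element) at the best-connected slot of the edge map.
* Single-valued descriptors in the KL panel fall back to smoothed
  bins, never a division by zero; all-tied Mann–Whitney samples warn
  and return p = 1.
* Geometry-embedding failures in the strain filter log a warning and
  leave the flag unset rather than failing the molecule.

## Problem sizes used by the bundled experiments

The test suite and the acceptance script run the scaled-down protocol:
a 500-molecule fixture corpus, 5 training epochs, 50 decoded feature
maps, 300 search iterations per map and a 20-slot feature
configuration; the reward-shaping comparison uses 20 feature maps with
paired seeds. These sizes keep a full from-scratch run in the
minutes range on one CPU while exercising every stage at realistic
intermediate sizes. Study-scale settings (8,000 iterations,
million-molecule corpora, 38 slots) are plain configuration changes.

## Known limitations

* The SA fragment table is synthetic (see above); absolute SA values
  are not comparable to the original scorer's.
* QED descriptors ride on OpenBabel's logP/TPSA/rotor models, which
  differ from other toolkits' by small amounts; QED values are
  typically within 0.02 of an independent implementation but are not
  bit-identical.
* The strain score is this package's own definition, calibrated on
  reference ring systems against the published 0.82 cutoff.
* FCD is an adapter, not an implementation.
* The decoder reconstructs a single edge-existence map (the default
  resolution of an open representational question); per-bond-type
  edge maps would be a straightforward extension of the same decoder
  head.
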