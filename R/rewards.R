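# rewards: property scores and the [0,1] minimization rewards that drive
# the tree search. Lower reward = better molecule, so UCB selection
# minimizes.

#' Reward specification
#'
#' Chooses which property the search optimizes and how it maps onto a
#' `[0, 1]` minimization reward: `qed` uses `1 - QED`; `plogp` uses
#' `1 - sigmoid(penalized logP)`; `custom` wraps a user function (which
#' must itself map into `[0, 1]`, lower = better).
#'
#' @param objective `"qed"`, `"plogp"` or `"custom"`.
#' @param fn for `objective = "custom"`, a function `smiles -> reward`.
#' @param normalized for `"plogp"`, use the z-score-normalized variant of
#'   penalized logP (standardized against drug-like training-set
#'   statistics) before the sigmoid.
#' @return an object of class `reward_spec`.
#' @export
reward_spec <- function(objective = c("qed", "plogp", "custom"),
                        fn = NULL, normalized = FALSE) {
  objective <- match.arg(objective)
  if (objective == "custom" && !is.function(fn)) {
    abort_config("custom objective needs a reward function")
  }
  structure(list(objective = objective, fn = fn, normalized = normalized),
            class = "reward_spec")
}

#' QED minimization reward
#'
#' @param smiles a single SMILES string.
#' @return `1 - QED(smiles)`, in `[0, 1]`.
#' @export
qed_reward <- function(smiles) 1 - qed(smiles)

#' Penalized logP
#'
#' `logP - SA - RingPenalty`, where `RingPenalty = max(0, largest ring - 6)`.
#' With `normalized = TRUE` each term is standardized by drug-like
#' training-set statistics (the convention of several generative-model
#' benchmarks) before summing.
#'
#' @param smiles a single SMILES string.
#' @param normalized standardize the three terms before summing.
#' @return numeric scalar.
#' @export
penalized_logp <- function(smiles, normalized = FALSE) {
  mol <- parse_molecule(smiles)
  if (is.null(mol)) {
    abort_invalid_structure(paste0("cannot parse SMILES: ", smiles))
  }
  obm <- ob_parse(mol$smiles)
  logp <- ob_descriptor(obm, "logP")
  sa <- sa_score(mol$smiles)
  ring_pen <- max(0, mol_largest_ring(mol) - 6)
  if (!normalized) {
    logp - sa - ring_pen
  } else {
    # ZINC250k normalization constants of the JT-VAE lineage
    (logp - 2.4570953396190123) / 1.434324401111988 -
      (sa - 3.0525811293166134) / 0.8335207024513095 -
      (ring_pen - 0.0485696876403053) / 0.2860212110245455
  }
}

#' Squash penalized logP into (0, 1)
#'
#' Standard logistic sigmoid; strictly increasing, 0.5 at 0.
#'
#' @param x finite numeric.
#' @return value in `(0, 1)`.
#' @export
scale_penalized_logp <- function(x) {
  stopifnot(is.finite(x))
  stats::plogis(x)
}

#' Penalized-logP minimization reward
#'
#' @inheritParams penalized_logp
#' @return `1 - sigmoid(penalized_logp)`, in `(0, 1)`.
#' @export
plogp_reward <- function(smiles, normalized = FALSE) {
  1 - scale_penalized_logp(penalized_logp(smiles, normalized = normalized))
}

#' Full property panel for a set of molecules
#'
#' @param smiles character vector of SMILES.
#' @return a data.frame with one row per molecule: `smiles`, `qed`, `logp`,
#'   `sa_score`, `ring_penalty`, `penalized_logp`, `scaled_penalized_logp`.
#' @export
property_scores <- function(smiles) {
  rows <- lapply(smiles, function(s) {
    mol <- parse_molecule(s)
    if (is.null(mol)) {
      return(data.frame(smiles = s, qed = NA_real_, logp = NA_real_,
                        sa_score = NA_real_, ring_penalty = NA_real_,
                        penalized_logp = NA_real_,
                        scaled_penalized_logp = NA_real_))
    }
    obm <- ob_parse(mol$smiles)
    logp <- ob_descriptor(obm, "logP")
    sa <- sa_score(mol$smiles)
    rp <- max(0, mol_largest_ring(mol) - 6)
    pl <- logp - sa - rp
    data.frame(smiles = mol$smiles, qed = qed(mol$smiles), logp = logp,
               sa_score = sa, ring_penalty = rp, penalized_logp = pl,
               scaled_penalized_logp = stats::plogis(pl))
  })
  do.call(rbind, rows)
}

# Memoizing reward evaluator: reward_fn(spec) -> function(smiles) -> reward.
# Canonical-SMILES keyed cache; tree-search rollouts revisit molecules.
reward_fn <- function(spec) {
  stopifnot(inherits(spec, "reward_spec"))
  cache <- new.env(parent = emptyenv())
  base <- switch(spec$objective,
                 qed = qed_reward,
                 plogp = function(s) plogp_reward(s, spec$normalized),
                 custom = spec$fn)
  function(smiles) {
    key <- smiles
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- base(smiles)
    assign(key, val, envir = cache)
    val
  }
}
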