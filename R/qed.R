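# Quantitative estimate of drug-likeness (QED): the weighted geometric
# mean of eight desirability functions over physicochemical descriptors
# (MW, ALOGP, HBA, HBD, PSA, ROTB, AROM, ALERTS), using the published
# asymmetric-double-sigmoid parameters and "mean" weights (see
# qed_constants.R). All descriptors are computed on the OpenBabel
# molecule: MW/logP/TPSA/HBD/rotor counts from its descriptor engines,
# acceptors, aromatic rings and structural alerts as SMARTS counts. This
# keeps a full QED evaluation in the low-millisecond range, which the
# tree-search reward loop depends on.

ads <- function(x, p) {
  v <- p[["a"]] +
    p[["b"]] / (1 + exp(-(x - p[["c"]] + p[["d"]] / 2) / p[["e"]])) *
    (1 - 1 / (1 + exp(-(x - p[["c"]] - p[["d"]] / 2) / p[["f"]])))
  max(v / p[["dmax"]], 1e-10)
}

# Elements a SMARTS pattern provably requires (sound only for patterns
# without OR/negation/recursion, which are screened out). Lets the alert
# loop skip most patterns for molecules that lack sulfur, phosphorus,
# iodine etc.
smarts_required_elements <- function(pattern) {
  if (grepl("[,!$]", pattern)) return(character(0))
  els <- character(0)
  # two-letter first, then one-letter aliphatic/aromatic, then #n
  for (m in regmatches(pattern,
                       gregexpr("Cl|Br|#[0-9]+|[BCNOPSFI]|\\b[cnops]\\b",
                                pattern))[[1L]]) {
    el <- if (startsWith(m, "#")) {
      names(which(c(B = 5, C = 6, N = 7, O = 8, F = 9, P = 15, S = 16,
                    Cl = 17, Br = 35, I = 53) == as.integer(substring(m, 2))))
    } else if (m %in% c("c", "n", "o", "p", "s")) {
      toupper(m)
    } else {
      m
    }
    if (length(el) == 1L) els <- c(els, el)
  }
  unique(els)
}

alert_prescreen <- function() {
  if (is.null(.ob_cache$alert_required)) {
    .ob_cache$alert_required <-
      lapply(.QED_ALERT_SMARTS, smarts_required_elements)
  }
  .ob_cache$alert_required
}

# Count structural alerts; dot-disconnected repeat patterns (e.g.
# "F.F.F.F", meaning >= 4 occurrences) are evaluated as a unique-match
# count threshold on the repeated component.
count_alerts <- function(obmol, elements = NULL) {
  required <- alert_prescreen()
  n <- 0L
  for (k in seq_along(.QED_ALERT_SMARTS)) {
    if (!is.null(elements) && length(required[[k]]) > 0L &&
        !all(required[[k]] %in% elements)) next
    p <- .QED_ALERT_SMARTS[k]
    hit <- if (grepl(".", p, fixed = TRUE)) {
      parts <- table(strsplit(p, ".", fixed = TRUE)[[1L]])
      all(vapply(names(parts), function(q) {
        ob_smarts_count(obmol, q, unique = TRUE) >= parts[[q]]
      }, logical(1)))
    } else {
      ob_smarts_count(obmol, p, unique = TRUE) > 0L
    }
    if (hit) n <- n + 1L
  }
  n
}

count_acceptors <- function(obmol) {
  sum(vapply(.QED_ACCEPTOR_SMARTS,
             function(p) ob_smarts_count(obmol, p, unique = TRUE),
             numeric(1)))
}

# aromatic rings counted as unique SMARTS ring matches (5- and 6-membered
# aromatic rings; larger aromatic rings do not occur in the chemistry
# handled here)
count_aromatic_rings <- function(obmol) {
  ob_smarts_count(obmol, "a1aaaaa1", unique = TRUE) +
    ob_smarts_count(obmol, "a1aaaa1", unique = TRUE)
}

#' QED descriptor panel for one molecule
#'
#' @param smiles a single SMILES string.
#' @return named numeric vector `MW`, `ALOGP`, `HBA`, `HBD`, `PSA`, `ROTB`,
#'   `AROM`, `ALERTS`.
#' @export
qed_properties <- function(smiles) {
  scan <- smiles_scan(smiles)
  if (is.null(scan)) {
    abort_invalid_structure(paste0("cannot parse SMILES: ", smiles))
  }
  obm <- ob_parse(smiles)
  if (is.null(obm)) {
    abort_invalid_structure(paste0("toolkit failed to parse: ", smiles))
  }
  c(MW = ob_descriptor(obm, "MW"),
    ALOGP = ob_descriptor(obm, "logP"),
    HBA = count_acceptors(obm),
    HBD = ob_descriptor(obm, "HBD"),
    PSA = ob_descriptor(obm, "TPSA"),
    ROTB = ob_descriptor(obm, "rotors"),
    AROM = count_aromatic_rings(obm),
    ALERTS = count_alerts(obm, elements = unique(scan$symbol)))
}

#' Quantitative estimate of drug-likeness
#'
#' Weighted geometric mean of the eight desirability functions;
#' `weights = "mean"` reproduces the commonly reported QED variant.
#'
#' @param smiles a single SMILES string.
#' @param weights `"mean"`, `"max"` or `"unit"`.
#' @return QED score in `[0, 1]`; higher is more drug-like.
#' @export
qed <- function(smiles, weights = c("mean", "max", "unit")) {
  weights <- match.arg(weights)
  w <- switch(weights,
              mean = .QED_WEIGHTS_MEAN,
              max = .QED_WEIGHTS_MAX,
              unit = stats::setNames(rep(1, 8), names(.QED_WEIGHTS_MEAN)))
  props <- qed_properties(smiles)
  d <- vapply(names(.QED_ADS),
              function(nm) ads(props[[nm]], .QED_ADS[[nm]]), numeric(1))
  exp(sum(w * log(d)) / sum(w))
}
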