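# Thin layer over the OpenBabel SWIG bindings shipped with ChemmineOB.
# Parsed molecules, compiled SMARTS patterns and descriptor engines are
# cached per session: repeated property calls during tree search must stay
# in the sub-millisecond range.

.ob_cache <- new.env(parent = emptyenv())

ob_fun <- function(name) {
  f <- .ob_cache[[paste0("fun_", name)]]
  if (is.null(f)) {
    f <- get(name, envir = getNamespace("ChemmineOB"))
    assign(paste0("fun_", name), f, envir = .ob_cache)
  }
  f
}

# Parse a single SMILES into an OpenBabel molecule reference, NULL on failure.
# OpenBabel recovers silently from some malformed strings; strict syntax
# checking happens upstream in smiles_scan().
ob_parse <- function(smiles) {
  mols <- tryCatch(
    suppressWarnings(ChemmineOB::forEachMol("SMILES", smiles, identity)),
    error = function(e) NULL
  )
  if (is.null(mols) || length(mols) != 1L) return(NULL)
  m <- mols[[1L]]
  n <- tryCatch(ob_fun("OBMol_NumAtoms")(m), error = function(e) 0L)
  if (n < 1L) return(NULL)
  m
}

ob_convert <- function(from, to, text) {
  tryCatch(ChemmineOB::convertFormat(from, to, source = text),
           error = function(e) "")
}

# Canonical SMILES (first whitespace-delimited token of OB "can" output).
ob_canonical_raw <- function(smiles) {
  out <- ob_convert("SMI", "CAN", smiles)
  out <- strsplit(trimws(out), "[ \t\n]+")[[1L]]
  if (length(out) < 1L || !nzchar(out[1L])) NULL else out[1L]
}

# Molblock (MDL ctab) text for a SMILES; OpenBabel writes a kekulized bond
# block, which is what the internal graph model expects.
ob_molblock <- function(smiles) {
  out <- ob_convert("SMI", "SDF", smiles)
  if (!nzchar(out) || !grepl("V2000", out, fixed = TRUE)) NULL else out
}

ob_descriptor <- function(obmol, name) {
  key <- paste0("desc_", name)
  d <- .ob_cache[[key]]
  if (is.null(d)) {
    d <- ob_fun("OBDescriptor_FindType")(name)
    assign(key, d, envir = .ob_cache)
  }
  ob_fun("OBDescriptor_Predict")(d, obmol)
}

# Count SMARTS matches against a pre-parsed molecule; the compiled pattern
# object is cached so the 90-odd structural-alert queries amortize.
ob_smarts_count <- function(obmol, smarts, unique = TRUE) {
  key <- paste0("pat_", smarts)
  pat <- .ob_cache[[key]]
  if (is.null(pat)) {
    pat <- ob_fun("OBSmartsPattern")()
    if (!ob_fun("OBSmartsPattern_Init")(pat, smarts)) {
      abort_config(paste0("invalid SMARTS pattern: ", smarts))
    }
    assign(key, pat, envir = .ob_cache)
  }
  ob_fun("OBSmartsPattern_Match")(pat, obmol)
  if (unique) {
    length(ob_fun("OBSmartsPattern_GetUMapList")(pat))
  } else {
    ob_fun("OBSmartsPattern_NumMatches")(pat)
  }
}
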