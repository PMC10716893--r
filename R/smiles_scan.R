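# Strict lexical scan of a SMILES string. OpenBabel silently repairs some
# malformed inputs ("C(" parses as methane), so structural validity is
# enforced here before any string reaches the toolkit: balanced parentheses
# and ring-bond digits, known atom tokens only.
#
# The scanner also returns the atom sequence (symbol + aromatic flag) in
# written order, which matches OpenBabel's SMILES->SDF atom order; the
# internal graph model uses that to carry aromaticity through the kekulized
# ctab.

.ORGANIC_SUBSET <- c("Cl", "Br", "B", "C", "N", "O", "P", "S", "F", "I")
.AROMATIC_ORGANIC <- c("b", "c", "n", "o", "p", "s")

smiles_scan <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles)) {
    return(NULL)
  }
  chars <- strsplit(smiles, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  i <- 1L
  depth <- 0L
  ring_open <- integer(0)            # open ring-closure labels
  atoms_seen <- 0L
  symbol <- character(0)
  aromatic <- logical(0)
  prev_is_atom <- FALSE

  push_atom <- function(sym, arom) {
    symbol[[length(symbol) + 1L]] <<- sym
    aromatic[[length(aromatic) + 1L]] <<- arom
    atoms_seen <<- atoms_seen + 1L
    prev_is_atom <<- TRUE
  }

  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) return(NULL)                      # unclosed bracket
      body <- paste0(chars[(i + 1L):(j - 1L)], collapse = "")
      m <- regmatches(body, regexec(
        "^([0-9]*)(se|as|[A-Z][a-z]?|[bcnops])(@{0,2})(H[0-9]*)?([+-][0-9+-]*)?$",
        body))[[1L]]
      if (length(m) == 0L) return(NULL)
      sym <- m[3L]
      arom <- sym %in% c(.AROMATIC_ORGANIC, "se", "as")
      if (arom) sym <- paste0(toupper(substr(sym, 1, 1)), substring(sym, 2))
      push_atom(sym, arom)
      i <- j + 1L
    } else if (i < n && paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
      push_atom(paste0(ch, chars[i + 1L]), FALSE)
      i <- i + 2L
    } else if (ch %in% .ORGANIC_SUBSET) {
      push_atom(ch, FALSE)
      i <- i + 1L
    } else if (ch %in% .AROMATIC_ORGANIC) {
      push_atom(toupper(ch), TRUE)
      i <- i + 1L
    } else if (ch == "(") {
      if (!prev_is_atom) return(NULL)              # branch needs an atom
      depth <- depth + 1L
      i <- i + 1L
    } else if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) return(NULL)
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\", "~", ".")) {
      i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9]{2}$",
                               paste0(chars[i + 1L], chars[i + 2L]))) {
        return(NULL)
      }
      lab <- as.integer(paste0(chars[i + 1L], chars[i + 2L]))
      if (lab %in% ring_open) ring_open <- setdiff(ring_open, lab)
      else ring_open <- c(ring_open, lab)
      i <- i + 3L
    } else if (grepl("^[0-9]$", ch)) {
      if (!prev_is_atom && length(symbol) == 0L) return(NULL)
      lab <- as.integer(ch)
      if (lab %in% ring_open) ring_open <- setdiff(ring_open, lab)
      else ring_open <- c(ring_open, lab)
      i <- i + 1L
    } else {
      return(NULL)                                 # unknown character
    }
  }
  if (depth != 0L || length(ring_open) > 0L || atoms_seen == 0L) return(NULL)
  data.frame(symbol = symbol, aromatic = aromatic,
             stringsAsFactors = FALSE)
}

smiles_syntax_ok <- function(smiles) !is.null(smiles_scan(smiles))

# Remove stereochemistry and isotope labels: tetrahedral marks, cis/trans
# bond slashes and leading isotope digits inside brackets. Degenerate
# brackets left over (e.g. "[CH]" from "[C@@H]") are harmless to OpenBabel,
# and the string is re-canonicalized afterwards anyway.
smiles_strip_stereo <- function(smiles) {
  s <- gsub("[/\\\\]", "-", smiles)
  s <- gsub("@", "", s, fixed = TRUE)
  s <- gsub("\\[([0-9]+)([A-Za-z])", "[\\2", s)
  s
}
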