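#' Feature configuration for molecular graphs
#'
#' Defines the fixed-size featurization every molecule is mapped to: the
#' element vocabulary, the bond-type vocabulary, the maximum heavy-atom
#' count (`max_atoms`, the number of node slots), and the named node/edge
#' feature blocks with their dimensions.
#'
#' Node features are the de-facto standard atom featurization for molecular
#' graph auto-encoders: one-hot element, one-hot heavy-atom degree (0-5),
#' formal charge, aromaticity flag and one-hot hybridization
#' (sp/sp2/sp3/other). Edge features are a one-hot over the bond-type
#' vocabulary.
#'
#' @param allowed_elements ordered element vocabulary.
#' @param bond_types ordered bond-type vocabulary.
#' @param max_atoms maximum heavy-atom count per graph (>= 1). The default,
#'   38, is the maximum heavy-atom count of common drug-like training sets.
#' @return an object of class `feature_config`.
#' @examples
#' cfg <- feature_config(max_atoms = 20)
#' cfg$d_node
#' @export
feature_config <- function(allowed_elements = c("C", "N", "O", "F", "P", "S",
                                                "Cl", "Br", "I"),
                           bond_types = c("single", "double", "triple",
                                          "aromatic"),
                           max_atoms = 38L) {
  max_atoms <- as.integer(max_atoms)
  if (is.na(max_atoms) || max_atoms < 1L) {
    abort_config("max_atoms must be >= 1")
  }
  if (length(allowed_elements) == 0L || anyDuplicated(allowed_elements)) {
    abort_config("allowed_elements must be non-empty and duplicate-free")
  }
  if (length(bond_types) == 0L || anyDuplicated(bond_types) ||
      !all(bond_types %in% c("single", "double", "triple", "aromatic"))) {
    abort_config("bond_types must be a duplicate-free subset of single/double/triple/aromatic")
  }
  unknown <- setdiff(allowed_elements, names(.MAX_VALENCE))
  if (length(unknown) > 0L) {
    abort_config(paste0("no valence table entry for: ",
                        paste(unknown, collapse = ", ")))
  }
  node_spec <- list(element = length(allowed_elements),
                    degree = 6L, formal_charge = 1L, aromatic = 1L,
                    hybridization = 4L)
  edge_spec <- list(bond_type = length(bond_types))
  cfg <- structure(list(allowed_elements = allowed_elements,
                        element_maxv = max_valence_of(allowed_elements),
                        bond_types = bond_types,
                        max_atoms = max_atoms,
                        node_feature_spec = node_spec,
                        edge_feature_spec = edge_spec,
                        d_node = sum(unlist(node_spec)),
                        d_edge = sum(unlist(edge_spec))),
                   class = "feature_config")
  cfg
}

#' @export
print.feature_config <- function(x, ...) {
  cat("feature_config\n")
  cat("  elements:  ", paste(x$allowed_elements, collapse = " "), "\n")
  cat("  bond types:", paste(x$bond_types, collapse = " "), "\n")
  cat("  max_atoms: ", x$max_atoms, "\n")
  cat("  d_node:", x$d_node, " d_edge:", x$d_edge, "\n")
  invisible(x)
}

feature_config_to_list <- function(cfg) {
  list(allowed_elements = cfg$allowed_elements,
       bond_types = cfg$bond_types,
       max_atoms = cfg$max_atoms)
}

feature_config_from_list <- function(lst) {
  known <- c("allowed_elements", "bond_types", "max_atoms")
  extra <- setdiff(names(lst), known)
  if (length(extra) > 0L) {
    abort_config(paste0("unknown feature_config keys: ",
                        paste(extra, collapse = ", ")))
  }
  do.call(feature_config, lst[intersect(known, names(lst))])
}

feature_config_equal <- function(a, b) {
  identical(feature_config_to_list(a), feature_config_to_list(b))
}
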