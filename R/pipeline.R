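# Run configuration + end-to-end pipeline: featurize -> train -> generate
# -> evaluate, with a manifest for exact re-runs.

#' Default run configuration
#'
#' A nested list serializable to/from YAML. Unknown keys are rejected on
#' load so typos cannot silently change an experiment.
#'
#' @param ... overrides merged over the defaults (must use known keys).
#' @return an object of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    paths = list(corpus = NULL, checkpoint = "model.rds",
                 molecules = "molecules.smi", provenance = "provenance.csv",
                 report = "report.json", outdir = "."),
    features = list(allowed_elements = c("C", "N", "O", "F", "P", "S",
                                         "Cl", "Br", "I"),
                    bond_types = c("single", "double", "triple", "aromatic"),
                    max_atoms = 38L),
    vgae = list(latent_dim = 64L, hidden_dim = 128L, n_layers = 3L,
                learning_rate = 0.001, batch_size = 64L, epochs = 50L,
                val_frac = 0.1),
    mcts = list(c = 1.5, edge_threshold = 0.10, iterations = 8000L,
                minimum_depth = NULL, aromatic_force = TRUE,
                aromatic_bonus = 0.5, aromatic_bonus_mode = "subtract",
                filter_penalty_factor = 10, max_ring_size = 7L,
                rollout_cap = NULL, use_strain_filter = FALSE,
                strain_cutoff = 0.82),
    reward = list(objective = "qed", normalized = FALSE),
    generation = list(n_feature_maps = 10L),
    fixtures = list(n = NULL),
    seed = 1L,
    log_level = "info")
  overrides <- list(...)
  cfg <- merge_config(defaults, overrides, path = "")
  structure(cfg, class = "run_config")
}

merge_config <- function(defaults, overrides, path) {
  if (length(overrides) == 0L) return(defaults)
  keys <- names(overrides)
  if (is.null(keys) || any(!nzchar(keys))) {
    abort_config(paste0("unnamed entries in config section '", path, "'"))
  }
  unknown <- setdiff(keys, names(defaults))
  if (length(unknown) > 0L) {
    abort_config(paste0("unknown config key(s): ",
                        paste0(path, unknown, collapse = ", ")))
  }
  for (k in keys) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(defaults[[k]],
                                    as.list(overrides[[k]]),
                                    paste0(path, k, "$"))
    } else {
      defaults[k] <- list(overrides[[k]])   # keeps explicit NULLs
    }
  }
  defaults
}

#' Read / write a run configuration
#'
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_io(paste0("config file not found: ", path))
  lst <- yaml::read_yaml(path)
  do.call(run_config, lst)
}

#' @rdname read_run_config
#' @param config a [run_config()].
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

pipeline_log <- function(config, level, ...) {
  levels <- c(debug = 1L, info = 2L, warn = 3L)
  if (levels[[level]] >= levels[[config$log_level %||% "info"]]) {
    message(sprintf("[%s] %s", level, paste0(...)))
  }
}

#' Run the full pipeline
#'
#' Featurizes the corpus (or a generated fixture set), trains the
#' auto-encoder, generates molecules with the tree search and writes the
#' benchmark report; a manifest records the configuration hash and seed so
#' re-runs are byte-identical.
#'
#' Stage failures halt with a `molgrow_stage_error` carrying the stage
#' name and a machine-readable code.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list with the output paths, the trained model and
#'   the benchmark report.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  outdir <- config$paths$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  out_path <- function(p) file.path(outdir, p)

  # --- stage: corpus -----------------------------------------------------
  corpus <- tryCatch({
    if (!is.null(config$paths$corpus)) {
      read_molecule_file(config$paths$corpus)$smiles
    } else if (!is.null(config$fixtures$n)) {
      make_fixture_set(config$fixtures$n, seed = config$seed)
    } else {
      abort_config("config needs either paths$corpus or fixtures$n")
    }
  }, molgrow_error = function(e) abort_stage("corpus", conditionMessage(e),
                                             "E_CORPUS"))
  if (length(corpus) == 0L) abort_stage("corpus", "empty corpus", "E_CORPUS")
  pipeline_log(config, "info", "corpus: ", length(corpus), " molecules")

  # --- stage: featurize --------------------------------------------------
  feat <- feature_config_from_list(config$features)
  graphs <- tryCatch({
    gs <- list()
    skipped <- 0L
    for (s in corpus) {
      g <- tryCatch(smiles_to_graph(s, feat),
                    molgrow_error = function(e) NULL)
      if (is.null(g)) skipped <- skipped + 1L else gs[[length(gs) + 1L]] <- g
    }
    if (skipped > 0L) {
      pipeline_log(config, "info", "featurize: skipped ", skipped,
                   " oversize/out-of-vocabulary molecule(s)")
    }
    gs
  }, error = function(e) abort_stage("featurize", conditionMessage(e),
                                     "E_FEATURIZE"))
  if (length(graphs) == 0L) {
    abort_stage("featurize", "no featurizable molecules", "E_FEATURIZE")
  }

  # --- stage: train ------------------------------------------------------
  model <- tryCatch(
    vgae_train(graphs, feat, hyper = config$vgae, seed = config$seed + 1L),
    error = function(e) abort_stage("train", conditionMessage(e), "E_TRAIN"))
  save_model(model, out_path(config$paths$checkpoint))
  pipeline_log(config, "info", "train: final loss ",
               sprintf("%.3f", utils::tail(model$history$train, 1L)))

  # --- stage: generate ---------------------------------------------------
  spec <- reward_spec(config$reward$objective,
                      normalized = isTRUE(config$reward$normalized))
  mcfg <- do.call(mcts_config, config$mcts)
  gen <- tryCatch(
    mcts_generate(model, spec, mcfg,
                  n_feature_maps = config$generation$n_feature_maps,
                  seed = config$seed + 2L),
    error = function(e) abort_stage("generate", conditionMessage(e),
                                    "E_GENERATE"))
  write_molecule_file(gen$smiles, out_path(config$paths$molecules))
  utils::write.csv(gen, out_path(config$paths$provenance),
                   row.names = FALSE)
  pipeline_log(config, "info", "generate: ", nrow(gen), " molecules")

  # --- stage: evaluate ---------------------------------------------------
  report <- tryCatch({
    if (nrow(gen) > 0L) distribution_benchmark(gen$smiles, corpus) else NULL
  }, error = function(e) abort_stage("evaluate", conditionMessage(e),
                                     "E_EVALUATE"))
  if (!is.null(report)) {
    jsonlite::write_json(unclass(report), out_path(config$paths$report),
                         auto_unbox = TRUE, digits = NA)
  }

  # --- manifest ----------------------------------------------------------
  cfg_yaml <- out_path("config_used.yaml")
  write_run_config(config, cfg_yaml)
  manifest <- list(config_md5 = unname(tools::md5sum(cfg_yaml)),
                   seed = config$seed,
                   n_corpus = length(corpus),
                   n_generated = nrow(gen))
  jsonlite::write_json(manifest, out_path("manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(paths = list(checkpoint = out_path(config$paths$checkpoint),
                              molecules = out_path(config$paths$molecules),
                              provenance = out_path(config$paths$provenance),
                              report = out_path(config$paths$report),
                              manifest = out_path("manifest.json")),
                 model = model, generated = gen, report = report))
}

#' Generate molecules from an existing checkpoint
#'
#' The generate-only entry point used by the CLI; fails with a stage error
#' when the checkpoint is missing.
#'
#' @param config a [run_config()].
#' @return the generation data.frame (see [mcts_generate()]).
#' @export
generate_from_checkpoint <- function(config) {
  stopifnot(inherits(config, "run_config"))
  ckpt <- file.path(config$paths$outdir, config$paths$checkpoint)
  if (!file.exists(ckpt)) {
    abort_stage("generate", paste0("checkpoint not found: ", ckpt),
                "E_NO_CHECKPOINT")
  }
  model <- load_model(ckpt)
  spec <- reward_spec(config$reward$objective,
                      normalized = isTRUE(config$reward$normalized))
  mcfg <- do.call(mcts_config, config$mcts)
  mcts_generate(model, spec, mcfg,
                n_feature_maps = config$generation$n_feature_maps,
                seed = config$seed + 2L)
}
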