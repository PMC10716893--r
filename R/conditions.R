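# Structured conditions so callers can distinguish bad molecules (skippable)
# from bad configuration (programming errors).

abort_molgrow <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "molgrow_error")))
}

abort_invalid_structure <- function(msg, smiles = NULL) {
  abort_molgrow("molgrow_invalid_structure", msg, smiles = smiles)
}

abort_capacity <- function(msg, smiles = NULL) {
  abort_molgrow("molgrow_capacity_error", msg, smiles = smiles)
}

abort_config <- function(msg) {
  abort_molgrow("molgrow_config_error", msg)
}

abort_io <- function(msg) {
  abort_molgrow("molgrow_io_error", msg)
}

abort_stage <- function(stage, msg, code) {
  abort_molgrow("molgrow_stage_error",
                sprintf("[stage %s] %s", stage, msg),
                stage = stage, code = code)
}
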