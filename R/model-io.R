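# Model checkpointing: a single-file serialization of the network
# configuration, the trained parameters and the vocabulary, with a format
# version for forward compatibility.

DDI_CHECKPOINT_VERSION <- 1L

#' Save / load a model checkpoint
#'
#' @param model a `ddi_model`.
#' @param path checkpoint file path.
#' @return `save_ddi_model` returns `path` invisibly; `load_ddi_model`
#'   returns the model.
#' @export
save_ddi_model <- function(model, path) {
  stopifnot(inherits(model, "ddi_model"))
  saveRDS(list(version = DDI_CHECKPOINT_VERSION, model = model), path)
  invisible(path)
}

#' @rdname save_ddi_model
#' @export
load_ddi_model <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || is.null(obj$version) || is.null(obj$model)) {
    stopf("'%s' is not a model checkpoint", path)
  }
  if (obj$version > DDI_CHECKPOINT_VERSION) {
    stopf("checkpoint version %d is newer than this package supports", obj$version)
  }
  obj$model
}

#' Write a resolved configuration snapshot as YAML
#'
#' Captures every hyperparameter of a run so any artifact-producing run can
#' be reproduced from its snapshot and seed.
#'
#' @param config list (or config object) of settings.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_config_snapshot <- function(config, path) {
  yaml::write_yaml(lapply(unclass(config), function(x) {
    if (is.function(x)) NULL else x
  }), path)
  invisible(path)
}
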