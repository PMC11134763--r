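## Single-file model checkpoints.

VOCAB_VERSION <- 1L   # token vocabulary: 0-99 defect, 100 PAD, 101 CLS

config_fingerprint <- function(cfg) {
  paste(vapply(cfg[order(names(cfg))], function(v) paste(format(v), collapse = ","),
               character(1)), collapse = ";")
}

#' Save / load a similarity model
#'
#' Writes a single-file checkpoint holding the configuration, all
#' parameters, the token-vocabulary version and a configuration
#' fingerprint; loading validates the fingerprint and vocabulary version
#' so that a checkpoint cannot silently be read into an incompatible
#' architecture.
#'
#' @param model A `ms2sim_model`.
#' @param path Checkpoint file path.
#' @return `save_model()`: `path` invisibly; `load_model()`: the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ms2sim_model"))
  obj <- list(config = model$config, params = model$params,
              history = model$history, trained = isTRUE(model$trained),
              vocab_version = VOCAB_VERSION,
              fingerprint = config_fingerprint(model$config))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$vocab_version, VOCAB_VERSION)) {
    abort("checkpoint uses an incompatible token vocabulary version")
  }
  if (!identical(obj$fingerprint, config_fingerprint(obj$config))) {
    abort("checkpoint configuration fingerprint mismatch")
  }
  structure(list(config = obj$config, params = obj$params,
                 history = obj$history, trained = obj$trained),
            class = "ms2sim_model")
}
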