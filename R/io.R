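# Checkpoint and report I/O. Checkpoints are JSON (text) so they survive
# source-only distribution; parameters round-trip exactly via jsonlite's
# R-type-preserving serialization.

#' Save a model checkpoint
#'
#' Stores parameters, configuration and (for completion models) the
#' vocabulary as JSON, together with a configuration hash.
#'
#' @param model a \code{center_model} or \code{synthon_model}.
#' @param path output file.
#' @export
save_model <- function(model, path) {
  payload <- list(type = class(model)[1L], hash = config_hash(model$cfg),
                  hidden = model$cfg$hidden, ta = model$cfg$ta,
                  payload = jsonlite::base64_enc(serialize(model, NULL,
                                                           xdr = TRUE)))
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE), path)
  invisible(path)
}

#' Load a model checkpoint
#' @param path file written by \code{\link{save_model}}.
#' @return the model object.
#' @export
load_model <- function(path) {
  payload <- jsonlite::fromJSON(paste(readLines(path), collapse = "\n"))
  unserialize(jsonlite::base64_dec(payload$payload))
}

#' Stable hash of a configuration object
#' @param x any serializable object.
#' @return hex string.
#' @export
config_hash <- function(x) {
  txt <- paste(deparse(x), collapse = "")
  v <- utf8ToInt(txt)
  h <- 0
  for (k in seq_along(v)) h <- (h * 31 + v[k]) %% 2147483647
  sprintf("%08x", h)
}

#' Run configuration for the full pipeline
#'
#' Bundles the tunables of a training/inference run: encoder width and
#' iteration count, beam widths, optimization settings and the seed.
#'
#' @param hidden,ta encoder width and message-passing iterations.
#' @param K,N center and reactant beam widths.
#' @param epochs,lr,batch_size training settings.
#' @param seed RNG seed.
#' @param reaction_type_known condition atom features on the reaction class.
#' @param max_steps attachment cap per completion path.
#' @return list of class \code{run_config} with a stable hash attribute.
#' @export
run_config <- function(hidden = 300L, ta = 5L, K = 10L, N = 10L,
                       epochs = 60L, lr = 1e-3, batch_size = 32L,
                       seed = 1L, reaction_type_known = FALSE,
                       max_steps = 30L) {
  cfg <- structure(list(hidden = as.integer(hidden), ta = as.integer(ta),
                        K = as.integer(K), N = as.integer(N),
                        epochs = as.integer(epochs), lr = lr,
                        batch_size = as.integer(batch_size),
                        seed = as.integer(seed),
                        reaction_type_known = isTRUE(reaction_type_known),
                        max_steps = as.integer(max_steps)),
                   class = "run_config")
  attr(cfg, "hash") <- config_hash(unclass(cfg))
  cfg
}
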