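# Self-describing JSON checkpoints: model configuration plus flattened
# parameter arrays (with shapes), versioned for forward compatibility.

CHECKPOINT_SCHEMA <- 1L

#' Save a model checkpoint
#'
#' Writes a versioned JSON container holding the configuration and every
#' parameter array with its shape.
#'
#' @param model A `sigmeth_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  flat <- flatten_params(model$params)
  obj <- list(
    schema = CHECKPOINT_SCHEMA,
    config = unclass(model$config),
    params = lapply(flat, function(x) {
      list(dim = if (is.matrix(x)) dim(x) else length(x), data = as.numeric(x))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Checkpoint written by [save_model()].
#' @return A `sigmeth_model`.
#' @export
load_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(obj$schema) || obj$schema != CHECKPOINT_SCHEMA) {
    stop_invalid("unsupported checkpoint schema in %s", path)
  }
  cfg <- obj$config
  config <- model_config(f = cfg$f, H = cfg$H, L_enc = cfg$L_enc,
                         L_dec = cfg$L_dec, d_ff = cfg$d_ff, b = cfg$b,
                         l = cfg$l, mode = cfg$mode, K = cfg$K,
                         dropout = cfg$dropout, use_decoder = cfg$use_decoder)
  template <- init_params(config, seed = 0L)
  flat <- flatten_params(template)
  for (nm in names(flat)) {
    rec <- obj$params[[nm]]
    if (is.null(rec)) stop_invalid("checkpoint %s is missing parameter %s", path, nm)
    x <- as.numeric(rec$data)
    dims <- as.integer(rec$dim)
    if (length(dims) == 2L) x <- matrix(x, dims[1], dims[2])
    if (length(x) != length(flat[[nm]])) {
      stop_invalid("checkpoint parameter %s has %d values; config expects %d",
                   nm, length(x), length(flat[[nm]]))
    }
    flat[[nm]] <- x
  }
  structure(list(config = config, params = unflatten_params(flat, template),
                 history = NULL),
            class = "sigmeth_model")
}
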