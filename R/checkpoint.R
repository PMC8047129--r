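# Versioned plain-text (JSON) checkpoints for fitted models.

CHECKPOINT_VERSION <- 1L

#' Save a fitted model to a JSON checkpoint
#'
#' Parameters, configuration, and training history are stored at full double
#' precision in a versioned JSON file, so a save/load round trip reproduces
#' the model exactly.
#'
#' @param object a fitted `"sebiograph"`.
#' @param path output path.
#' @export
save_sebiograph <- function(object, path) {
  ser_mat <- function(M) list(dim = dim(M), data = as.vector(M))
  ser <- function(x) if (is.list(x)) lapply(x, ser_mat) else ser_mat(x)
  payload <- list(
    version = CHECKPOINT_VERSION,
    config = unclass(object$config),
    cluster_counts = object$cluster_counts,
    params = lapply(object$params, ser),
    history = as.list(object$history)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(NULL)
}

#' Load a fitted model from a JSON checkpoint
#'
#' @param path path written by [save_sebiograph()].
#' @return a `"sebiograph"` object.
#' @export
load_sebiograph <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  if (!identical(as.integer(payload$version), CHECKPOINT_VERSION)) {
    stop("unsupported checkpoint version: ", payload$version, call. = FALSE)
  }
  de_mat <- function(x) matrix(x$data, x$dim[1L], x$dim[2L])
  de <- function(x) {
    if (!is.null(x$dim)) de_mat(x) else lapply(x, de)
  }
  cfg <- payload$config
  cfg$cluster_counts <- payload$cluster_counts
  cfg <- do.call(sebiograph_config, cfg)
  structure(list(params = lapply(payload$params, de), config = cfg,
                 cluster_counts = payload$cluster_counts,
                 history = as.data.frame(payload$history)),
            class = "sebiograph")
}
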