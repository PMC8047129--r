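#' Default model and training configuration
#'
#' Returns the full configuration list used across the package, with any
#' supplied values overriding the defaults. The configuration controls the
#' encoder architecture, the hierarchical representation gate, the prototype
#' construction, the auxiliary reconstruction constraint, and episodic
#' training.
#'
#' Key entries:
#' \describe{
#'   \item{hidden_dim, out_dim}{width of the two graph-convolution layers
#'     (32 each by default).}
#'   \item{activation}{nonlinearity between the encoder layers (`"relu"`
#'     default, none on the output layer).}
#'   \item{levels, cluster_counts}{hierarchy depth D and cluster counts per
#'     coarsened level; `cluster_counts = NULL` resolves to
#'     `max(2, ceiling(m/4))` for the single coarsening of the default D = 2.}
#'   \item{attn_norm}{`"softmax"` (default) or `"ratio"` for the literal
#'     score-ratio normalization of the level-attention weights.}
#'   \item{gated}{whether the hierarchical gate modulates the shared
#'     output-layer weight block.}
#'   \item{distance}{`"sqeuclidean"` (default) or `"cosine"`.}
#'   \item{prototype}{`"structured"` (relation-graph convolution + max pool,
#'     default) or `"mean"` (plain mean of support embeddings).}
#'   \item{relation_k_hop, relation_lambda}{neighborhood order and blend
#'     weight of the intra-class relation graphs.}
#'   \item{beta}{weight of the auxiliary reconstruction loss.}
#'   \item{gamma}{learning rate.}
#'   \item{optimizer}{`"gd"` (plain gradient descent, default) or `"adam"`.}
#'   \item{ways, shots, queries}{episode shape.}
#'   \item{epochs, episodes_per_epoch}{training length.}
#'   \item{init_std}{standard deviation of the zero-mean Gaussian weight
#'     initialization.}
#' }
#'
#' @param ... named overrides of individual entries.
#' @return a named list of class `"sebiograph_config"`.
#' @export
#' @examples
#' cfg <- sebiograph_config(beta = 0, shots = 5)
#' cfg$distance
sebiograph_config <- function(...) {
  cfg <- list(
    # encoder
    hidden_dim = 32L,
    out_dim = 32L,
    activation = "relu",
    gated = TRUE,
    # hierarchy
    levels = 2L,
    cluster_counts = NULL,
    fgnn_dim = 32L,
    attn_norm = "softmax",
    # prototypes / metric
    distance = "sqeuclidean",
    prototype = "structured",
    relation_k_hop = 2L,
    relation_lambda = 1,
    loss_reduction = "mean",
    # decoder
    beta = 0.1,
    decoder_dim = 16L,
    decoder_link = "none",
    recon_reduction = "mean",
    # training
    gamma = 0.005,
    optimizer = "gd",
    adam_beta1 = 0.9,
    adam_beta2 = 0.999,
    adam_eps = 1e-8,
    epochs = 1L,
    episodes_per_epoch = 200L,
    ways = 4L,
    shots = 5L,
    queries = 10L,
    init_std = 0.1,
    seed = 1L,
    patience = Inf
  )
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1L]]) && is.null(names(over))) {
    over <- over[[1L]]
  }
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg[names(over)] <- over
  validate_config(cfg)
  structure(cfg, class = "sebiograph_config")
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$gamma >= 0, cfg$beta >= 0,
    cfg$ways >= 1, cfg$shots >= 1, cfg$queries >= 1,
    cfg$levels >= 1,
    cfg$hidden_dim >= 1, cfg$out_dim >= 1
  )
  if (!cfg$distance %in% c("sqeuclidean", "cosine")) {
    stop("distance must be 'sqeuclidean' or 'cosine'", call. = FALSE)
  }
  if (!cfg$prototype %in% c("structured", "mean")) {
    stop("prototype must be 'structured' or 'mean'", call. = FALSE)
  }
  if (!cfg$attn_norm %in% c("softmax", "ratio")) {
    stop("attn_norm must be 'softmax' or 'ratio'", call. = FALSE)
  }
  if (!cfg$optimizer %in% c("gd", "adam")) {
    stop("optimizer must be 'gd' or 'adam'", call. = FALSE)
  }
  invisible(cfg)
}

#' Read a configuration from a JSON file
#'
#' @param path path to a JSON file whose keys are configuration entries.
#' @return a `"sebiograph_config"` list.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(sebiograph_config, raw)
}
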