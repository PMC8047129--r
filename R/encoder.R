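# Gated graph-convolutional encoder. Every graph convolution in the package
# uses the same propagation rule: add self-loops, symmetric degree
# normalization, i.e. Ahat = D~^{-1/2} (A + I) D~^{-1/2}.

#' Symmetrically normalized adjacency with self-loops
#'
#' @param A square (weighted) adjacency matrix, or an autodiff node holding
#'   one when called inside a training tape.
#' @return the normalized matrix (same type as the input).
#' @export
normalize_adjacency <- function(A) {
  m <- nrow(vof(A))
  I <- diag(m)
  At <- ad_add(A, I)
  ds <- ad_rsqrt(ad_rowsums(At))
  ad_hadamard(At, ad_mm_t(ds, ds))
}

# one graph-convolution layer on a pre-normalized adjacency
gcn_layer <- function(Ahat, X, W, act = "none") {
  ad_activate(ad_mm(ad_mm(Ahat, X), W), act)
}

#' Initialize encoder/gate/prototype/decoder parameters
#'
#' All weights are drawn from a zero-mean Gaussian with standard deviation
#' `config$init_std`; the gate bias starts at zero.
#'
#' @param h input feature dimension.
#' @param config a [sebiograph_config()].
#' @param m number of nodes of a representative graph (used to resolve the
#'   default cluster counts of the hierarchy).
#' @return named list of parameter matrices.
#' @export
init_params <- function(h, config = sebiograph_config(), m = NULL) {
  ks <- resolve_cluster_counts(config, m)
  sd <- config$init_std
  rnm <- function(r, c) matrix(stats::rnorm(r * c, sd = sd), r, c)
  ntrans <- max(1L, config$levels - 1L)
  wf <- vector("list", ntrans)
  wa <- vector("list", max(0L, config$levels - 1L))
  widths <- c(h, rep(config$fgnn_dim, ntrans))
  for (t in seq_len(ntrans)) wf[[t]] <- rnm(widths[t], config$fgnn_dim)
  for (t in seq_along(wa)) wa[[t]] <- rnm(widths[t], ks[t])
  list(
    W1 = rnm(h, config$hidden_dim),
    alpha = rnm(config$hidden_dim, config$out_dim),
    W_g = rnm(config$hidden_dim, config$fgnn_dim),
    b_g = matrix(0, config$hidden_dim, 1),
    q = rnm(config$fgnn_dim, 1),
    W_a = wa,
    W_f = wf,
    W_p = rnm(config$out_dim, config$out_dim),
    W_dec = rnm(config$out_dim, config$decoder_dim)
  )
}

# cluster counts for levels 2..D; default single coarsening to max(2, m/4)
resolve_cluster_counts <- function(config, m = NULL) {
  if (!is.null(config$cluster_counts)) return(as.integer(config$cluster_counts))
  if (config$levels <= 1L) return(integer(0))
  if (is.null(m)) stop("need m to resolve default cluster counts", call. = FALSE)
  ks <- integer(config$levels - 1L)
  prev <- m
  for (t in seq_along(ks)) {
    ks[t] <- max(2L, ceiling(prev / 4))
    prev <- ks[t]
  }
  ks
}

#' Encode the nodes of a graph
#'
#' Two rounds of neighborhood aggregation (symmetric-normalized adjacency with
#' self-loops), each followed by a linear map; a rectifier sits between the
#' layers and the output layer is linear. When a gate vector is supplied the
#' globally shared output-layer block `alpha` is replaced by `g * alpha`
#' (row-wise modulation) before the forward pass.
#'
#' @param graph a [bio_graph()] (or a list with `adjacency` and `features`).
#' @param params parameter list from [init_params()].
#' @param gate optional gate vector of length `hidden_dim` (entries in (0,1)),
#'   e.g. from [build_hierarchy()].
#' @param config a [sebiograph_config()].
#' @return m x out_dim embedding matrix.
#' @export
encode <- function(graph, params, gate = NULL, config = sebiograph_config()) {
  if (any(!is.finite(vof(graph$features)))) {
    stop("non-finite values in features", call. = FALSE)
  }
  Ahat <- normalize_adjacency(graph$adjacency)
  encode_on(Ahat, graph$features, params, gate, config)
}

# core forward given a pre-normalized adjacency; works on nodes or matrices
encode_on <- function(Ahat, N, params, gate = NULL,
                      config = sebiograph_config()) {
  if (ncol(vof(N)) != nrow(vof(params$W1))) {
    stop("feature width (", ncol(vof(N)), ") does not match encoder input (",
         nrow(vof(params$W1)), ")", call. = FALSE)
  }
  W2 <- params$alpha
  if (!is.null(gate)) {
    g <- if (is_adnode(gate) || is.matrix(gate)) gate else matrix(gate, ncol = 1)
    if (nrow(vof(g)) != nrow(vof(W2))) {
      stop("gate length must equal the shared block's row count", call. = FALSE)
    }
    W2 <- ad_scale_rows(W2, g)
  }
  X1 <- gcn_layer(Ahat, N, params$W1, act = config$activation)
  gcn_layer(Ahat, X1, W2, act = "none")
}
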