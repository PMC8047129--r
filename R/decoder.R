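# Graph-autoencoder reconstruction constraint.

#' Adjacency reconstruction loss
#'
#' One-layer graph convolution maps the encoder output `H` to decoder
#' embeddings `Z = GNN_dec(A, H)`; the loss is the squared Frobenius distance
#' between the adjacency and the Gram matrix of the decoder outputs,
#' `||A - Z t(Z)||_F^2`, summed over all entries (or the per-entry mean with
#' `reduction = "mean"`). With `link = "sigmoid"` the Gram matrix is passed
#' through a logistic link first (the standard graph-autoencoder variant).
#'
#' @param graph a [bio_graph()] (raw adjacency is the reconstruction target).
#' @param H m x width encoder output.
#' @param W_dec decoder-convolution weight matrix.
#' @param link `"none"` (default, literal Gram matrix) or `"sigmoid"`.
#' @param reduction `"sum"` (default) or `"mean"` per entry.
#' @return scalar loss (1 x 1 matrix, or a tape node inside training).
#' @export
reconstruction_loss <- function(graph, H, W_dec, link = "none",
                                reduction = "sum") {
  A <- graph$adjacency
  if (nrow(vof(H)) != nrow(A)) {
    stop("embedding rows (", nrow(vof(H)), ") != number of nodes (", nrow(A),
         ")", call. = FALSE)
  }
  Z <- gcn_layer(normalize_adjacency(A), H, W_dec)
  G <- ad_mm_t(Z, Z)
  if (link == "sigmoid") G <- ad_sigmoid(G)
  L <- ad_sumsq(ad_sub(A, G))
  if (reduction == "mean") L <- ad_scale(L, 1 / length(A))
  L
}
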