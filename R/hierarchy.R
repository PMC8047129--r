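# Hierarchical graph-representation gate: soft assignment of nodes to
# communities, coarsening, per-level max-pooled representations, attention
# aggregation across levels, and the sigmoid gate that modulates the shared
# encoder block.

#' Soft node-to-community assignment
#'
#' One-layer graph convolution producing `K_next` logits per node, followed by
#' a row softmax, so each row is a distribution over the next level's
#' communities.
#'
#' @param A_d adjacency at the current level (raw, not normalized).
#' @param N_d node features at the current level.
#' @param W_a assignment-convolution weight matrix (width x K_next).
#' @param K_next number of communities at the next level.
#' @return row-stochastic assignment matrix (K_d x K_next).
#' @export
assign_nodes <- function(A_d, N_d, W_a, K_next) {
  stopifnot(K_next >= 1)
  if (K_next > nrow(vof(A_d))) {
    message("over-clustering: K_next (", K_next, ") exceeds current level size (",
            nrow(vof(A_d)), ")")
  }
  Ahat <- normalize_adjacency(A_d)
  logits <- gcn_layer(Ahat, N_d, W_a)
  if (any(!is.finite(vof(logits)))) stop("non-finite assignment logits",
                                         call. = FALSE)
  ad_row_softmax(logits)
}

#' Coarsen a graph one level
#'
#' `A_next = t(P) A_d P`; `N_next = t(P) FGNN(A_d, N_d)` with the fusion GNN a
#' one-layer graph convolution.
#'
#' @param A_d,N_d adjacency and features at the current level.
#' @param P row-stochastic assignment matrix.
#' @param W_f fusion-convolution weight matrix.
#' @return list with `A_next` and `N_next`.
#' @export
coarsen <- function(A_d, N_d, P, W_f) {
  fused <- gcn_layer(normalize_adjacency(A_d), N_d, W_f)
  list(A_next = ad_mm(ad_mm(ad_t(P), A_d), P),
       N_next = ad_mm(ad_t(P), fused))
}

#' Per-level graph representation
#'
#' Coordinate-wise maximum over the coarsened node rows `t(P) FGNN(A_d, N_d)`.
#'
#' @inheritParams coarsen
#' @return 1 x width representation.
#' @export
level_representation <- function(A_d, N_d, P, W_f) {
  if (ncol(vof(P)) == 0L) stop("empty level: no communities", call. = FALSE)
  ad_col_max(coarsen(A_d, N_d, P, W_f)$N_next)
}

#' Attention aggregation of level representations
#'
#' Scores each level representation against a learnable query vector and
#' combines the levels with weights normalized to sum to one — softmax over the
#' scores by default, or the literal score-ratio form with
#' `attn_norm = "ratio"` (only meaningful for positive scores).
#'
#' @param level_reps list of 1 x width level representations.
#' @param q query column vector.
#' @param attn_norm `"softmax"` or `"ratio"`.
#' @return list with the aggregate `h` (width x 1) and the weights `w`.
#' @export
aggregate_levels <- function(level_reps, q, attn_norm = "softmax") {
  stopifnot(length(level_reps) >= 1)
  H <- ad_rbind_rows(level_reps)            # D x width
  s <- ad_mm(H, q)                          # D x 1
  if (any(!is.finite(vof(s)))) stop("non-finite attention scores", call. = FALSE)
  w <- if (attn_norm == "ratio") ad_ratio_norm(s) else ad_vec_softmax(s)
  list(h = ad_mm(ad_t(H), w), w = w)
}

#' Graph-representation gate
#'
#' `g = sigmoid(W_g h + b_g)`; entries lie strictly in (0,1).
#'
#' @param h aggregate graph representation (width x 1 column).
#' @param W_g,b_g gate weight matrix and bias column.
#' @return gate column vector.
#' @export
compute_gate <- function(h, W_g, b_g) {
  hm <- if (is_adnode(h) || is.matrix(h)) h else matrix(h, ncol = 1)
  ad_sigmoid(ad_add(ad_mm(W_g, hm), b_g))
}

#' Build the full hierarchy and gate for a graph
#'
#' Level 1 is the input graph; its representation is the column-wise maximum of
#' the fused node features. Each further level d+1 applies soft assignment,
#' coarsening, and max pooling. The level representations are combined by the
#' attention aggregator and mapped through the sigmoid gate.
#'
#' @param graph a [bio_graph()].
#' @param params parameter list from [init_params()].
#' @param config a [sebiograph_config()].
#' @return list of class `"hierarchy_state"`: per-level `A`, `N`, assignment
#'   matrices `P`, level representations `levels`, attention weights
#'   `attn_weights`, aggregate `h`, and `gate`.
#' @export
build_hierarchy <- function(graph, params, config = sebiograph_config()) {
  ks <- resolve_cluster_counts(config, n_nodes(graph))
  A <- graph$adjacency
  N <- graph$features
  As <- list(A); Ns <- list(N); Ps <- list(); reps <- list()
  reps[[1L]] <- ad_col_max(gcn_layer(normalize_adjacency(A), N, params$W_f[[1L]]))
  for (t in seq_along(ks)) {
    P <- assign_nodes(A, N, params$W_a[[t]], ks[t])
    co <- coarsen(A, N, P, params$W_f[[t]])
    Ps[[t]] <- P
    A <- co$A_next; N <- co$N_next
    As[[t + 1L]] <- A; Ns[[t + 1L]] <- N
    reps[[t + 1L]] <- ad_col_max(N)
  }
  agg <- aggregate_levels(reps, params$q, config$attn_norm)
  gate <- compute_gate(agg$h, params$W_g, params$b_g)
  structure(list(A = As, N = Ns, P = Ps, levels = reps,
                 attn_weights = agg$w, h = agg$h, gate = gate),
            class = "hierarchy_state")
}
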