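# Structured class prototypes: intra-class relation graphs over support nodes,
# a one-layer graph convolution over each relation graph, max pooling to one
# vector per class, and the distance-softmax episode loss.

#' Intra-class relation graph over support nodes
#'
#' Pairwise similarity between same-class support nodes combining the inverse
#' shortest-path distance in the full graph with the Jaccard overlap of k-hop
#' neighborhoods:
#' `w(u,v) = 1/(1 + spd(u,v)) + lambda * |common k-hop| / max(1, |k-hop union|)`.
#' Disconnected pairs contribute zero through the first term.
#'
#' @param graph a [bio_graph()].
#' @param members node indices (1-based) of the class's support nodes.
#' @param k_hop neighborhood order for the overlap term.
#' @param lambda blend weight of the overlap term.
#' @return symmetric non-negative similarity matrix with zero diagonal
#'   (`|members| x |members|`).
#' @export
build_relation_graph <- function(graph, members, k_hop = 2L, lambda = 1) {
  stopifnot(length(members) >= 1, k_hop >= 1)
  n <- length(members)
  D <- matrix(0, n, n)
  if (n == 1L) return(D)
  ig <- graph_igraph(graph)
  spd <- igraph::distances(ig, v = members, to = members)
  hoods <- lapply(igraph::ego(ig, order = k_hop, nodes = members,
                              mindist = 1L), as.integer)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      inv <- if (is.finite(spd[i, j])) 1 / (1 + spd[i, j]) else 0
      com <- length(intersect(hoods[[i]], hoods[[j]]))
      uni <- length(union(hoods[[i]], hoods[[j]]))
      w <- inv + lambda * com / max(1, uni)
      D[i, j] <- w
      D[j, i] <- w
    }
  }
  D
}

# cached igraph view of a bio_graph (topology only, weights ignored for spd)
graph_igraph <- function(graph) {
  env <- attr(graph, "igraph_cache")
  if (is.null(env)) {
    # cache on the adjacency's attributes is not possible for a plain list
    # component, so recompute; callers that loop should use prepare_graph()
    return(igraph::graph_from_adjacency_matrix(graph$adjacency != 0,
                                               mode = "undirected"))
  }
  env$ig
}

# attach a persistent igraph cache (used by the trainer's per-graph caches)
prepare_graph <- function(graph) {
  env <- new.env(parent = emptyenv())
  env$ig <- igraph::graph_from_adjacency_matrix(graph$adjacency != 0,
                                                mode = "undirected")
  attr(graph, "igraph_cache") <- env
  graph
}

#' Structured class prototype
#'
#' One-layer graph convolution of the member embeddings over the (normalized)
#' relation adjacency, followed by a coordinate-wise maximum over members.
#'
#' @param relation relation adjacency from [build_relation_graph()].
#' @param member_embeddings embeddings of the members, rows aligned with
#'   `relation`.
#' @param W_p prototype-convolution weight matrix.
#' @return 1 x width prototype.
#' @export
compute_prototype <- function(relation, member_embeddings, W_p) {
  if (nrow(vof(member_embeddings)) == 0L) stop("empty member set", call. = FALSE)
  Dhat <- normalize_adjacency(relation)
  ad_col_max(gcn_layer(Dhat, member_embeddings, W_p))
}

# prototypes for all classes of an episode; returns K x width (node or matrix)
episode_prototypes <- function(graph, support_idx, support_y, H, params,
                               config) {
  classes <- sort(unique(support_y))
  rows <- lapply(classes, function(k) {
    mem <- support_idx[support_y == k]
    E <- ad_rows(H, mem)
    if (config$prototype == "mean") {
      ad_col_mean(E)
    } else {
      rel <- build_relation_graph(graph, mem, config$relation_k_hop,
                                  config$relation_lambda)
      compute_prototype(rel, E, params$W_p)
    }
  })
  list(C = ad_rbind_rows(rows), classes = classes)
}

# distance matrix between query embeddings and prototypes
proto_distances <- function(Eq, C, distance) {
  if (distance == "cosine") {
    ad_sub(1, ad_mm_t(ad_row_normalize(Eq), ad_row_normalize(C)))
  } else {
    ad_sqdist(Eq, C)
  }
}

#' Episode loss
#'
#' Negative log-likelihood of the query labels under the distance softmax over
#' class prototypes, `-log softmax_k(-d(f(n), c_k))`, computed with
#' log-sum-exp stabilization.
#'
#' @param query_embeddings embeddings of the query nodes (rows).
#' @param query_labels integer class per query, indexing rows of `prototypes`.
#' @param prototypes K x width prototype matrix.
#' @param distance `"sqeuclidean"` or `"cosine"`.
#' @param reduction `"mean"` (default) or `"sum"` over queries.
#' @return scalar loss (1 x 1 matrix, or a tape node inside training).
#' @export
episode_loss <- function(query_embeddings, query_labels, prototypes,
                         distance = "sqeuclidean", reduction = "mean") {
  K <- nrow(vof(prototypes))
  if (any(query_labels < 1 | query_labels > K)) {
    stop("query class absent from the prototype set", call. = FALSE)
  }
  D <- proto_distances(query_embeddings, prototypes, distance)
  ad_proto_nll(D, query_labels, reduction)
}

#' Classify embeddings against prototypes
#'
#' Assigns each row the class of the nearest prototype; probabilities are the
#' distance softmax. Exact distance ties break to the lowest class index.
#'
#' @param embeddings rows to classify.
#' @param prototypes K x width prototype matrix.
#' @param distance `"sqeuclidean"` or `"cosine"`.
#' @return list with integer `labels` and the `probabilities` matrix.
#' @export
classify_nodes <- function(embeddings, prototypes, distance = "sqeuclidean") {
  if (nrow(prototypes) == 0L) stop("empty prototype set", call. = FALSE)
  D <- vof(proto_distances(embeddings, prototypes, distance))
  P <- row_softmax_val(-D)
  list(labels = apply(D, 1, which.min), probabilities = P)
}
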