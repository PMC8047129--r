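# Readers/writers for the plain-text graph formats:
#   edge list  <u>\t<v>[\t<w>]   ('#' comment lines ignored)
#   features   <id>\t<f1>...\t<fh>
#   labels     <id>\t<class>     (positive integer classes; NA = unlabeled)

#' Construct a BioGraph
#'
#' A `bio_graph` bundles one undirected graph: a square symmetric adjacency
#' with zero diagonal, a node-aligned feature matrix, optional integer labels
#' (NA marks unlabeled nodes), and the external node identifiers. Internal
#' indices are contiguous and 0-based on disk, 1-based inside R.
#'
#' @param adjacency m x m symmetric numeric matrix, zero diagonal.
#' @param features m x h numeric matrix.
#' @param labels optional integer vector of length m (NA = unlabeled).
#' @param node_ids character vector of external identifiers (default "n1"...).
#' @return an object of class `"bio_graph"`.
#' @export
bio_graph <- function(adjacency, features, labels = NULL, node_ids = NULL) {
  adjacency <- as.matrix(adjacency)
  features <- as.matrix(features)
  m <- nrow(adjacency)
  if (ncol(adjacency) != m) stop("adjacency must be square", call. = FALSE)
  if (nrow(features) != m) {
    stop("feature rows (", nrow(features), ") != number of nodes (", m, ")",
         call. = FALSE)
  }
  if (m > 0 && max(abs(adjacency - t(adjacency))) > 1e-12) {
    stop("adjacency must be symmetric", call. = FALSE)
  }
  if (m > 0 && any(diag(adjacency) != 0)) {
    stop("adjacency diagonal must be zero (self-loops are added only inside ",
         "the encoder)", call. = FALSE)
  }
  if (any(!is.finite(features))) stop("non-finite feature values", call. = FALSE)
  if (is.null(node_ids)) node_ids <- sprintf("n%d", seq_len(m))
  if (length(node_ids) != m) stop("node_ids length mismatch", call. = FALSE)
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != m) stop("labels length mismatch", call. = FALSE)
    if (any(!is.na(labels) & labels < 1)) {
      stop("labels must be positive integers", call. = FALSE)
    }
  }
  structure(
    list(adjacency = adjacency, features = features, labels = labels,
         node_ids = as.character(node_ids)),
    class = "bio_graph")
}

#' @export
print.bio_graph <- function(x, ...) {
  m <- nrow(x$adjacency)
  ne <- sum(x$adjacency[upper.tri(x$adjacency)] != 0)
  nl <- if (is.null(x$labels)) 0L else sum(!is.na(x$labels))
  cat(sprintf("<bio_graph> %d nodes, %d undirected edges, %d features, %d labeled\n",
              m, ne, ncol(x$features), nl))
  invisible(x)
}

n_nodes <- function(graph) nrow(graph$adjacency)

#' Read a graph from edge-list, feature, and optional label files
#'
#' The edge list holds two (or three, weighted) whitespace-separated columns;
#' duplicate edges collapse; edges given in either orientation are stored
#' symmetrically; conflicting weights for (u,v) vs (v,u) are rejected. Node
#' identity and order come from the feature table, so nodes without any edge
#' are kept as isolated nodes.
#'
#' @param edge_list_path path to the edge-list file.
#' @param features_path path to the node feature TSV.
#' @param labels_path optional path to the node label TSV.
#' @return a [bio_graph()].
#' @export
#' @examples
#' d <- tempfile(); dir.create(d)
#' writeLines(c("a\tb", "b\tc"), file.path(d, "edges.tsv"))
#' writeLines(c("a\t0.1\t1", "b\t0.2\t0", "c\t0.3\t1"), file.path(d, "feat.tsv"))
#' g <- read_graph(file.path(d, "edges.tsv"), file.path(d, "feat.tsv"))
#' rowSums(g$adjacency)  # degrees 1, 2, 1
read_graph <- function(edge_list_path, features_path, labels_path = NULL) {
  feat <- utils::read.table(features_path, sep = "\t", header = FALSE,
                            comment.char = "#", colClasses = "character",
                            quote = "")
  ids <- feat[[1L]]
  if (anyDuplicated(ids)) {
    stop("duplicate node id in feature table: ", ids[duplicated(ids)][1L],
         call. = FALSE)
  }
  fmat <- as.matrix(feat[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(fmat) <- "double")
  if (anyNA(fmat)) {
    bad <- which(is.na(fmat), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric feature value at row %d, column %d",
                 bad[1L], bad[2L] + 1L), call. = FALSE)
  }
  dimnames(fmat) <- NULL
  m <- length(ids)
  idx <- stats::setNames(seq_len(m), ids)

  A <- matrix(0, m, m)
  el <- tryCatch(
    utils::read.table(edge_list_path, sep = "", header = FALSE,
                      comment.char = "#", colClasses = "character", quote = ""),
    error = function(e) NULL)  # empty edge list
  if (!is.null(el) && nrow(el)) {
    if (!ncol(el) %in% c(2L, 3L)) {
      stop("edge list must have 2 or 3 columns", call. = FALSE)
    }
    u <- el[[1L]]; v <- el[[2L]]
    unknown <- setdiff(unique(c(u, v)), ids)
    if (length(unknown)) {
      stop("edge list mentions node id absent from feature table: ",
           unknown[1L], call. = FALSE)
    }
    w <- if (ncol(el) == 3L) as.numeric(el[[3L]]) else rep(1, length(u))
    if (anyNA(w)) stop("non-numeric edge weight", call. = FALSE)
    iu <- idx[u]; iv <- idx[v]
    keep <- iu != iv  # drop self-loops on disk
    iu <- iu[keep]; iv <- iv[keep]; w <- w[keep]
    # canonical orientation, detect weight conflicts, collapse duplicates
    lo <- pmin(iu, iv); hi <- pmax(iu, iv)
    key <- paste(lo, hi)
    for (k in unique(key)) {
      ws <- w[key == k]
      if (length(unique(ws)) > 1L) {
        pr <- strsplit(k, " ")[[1L]]
        stop(sprintf("conflicting weights for edge (%s, %s): %s",
                     ids[as.integer(pr[1L])], ids[as.integer(pr[2L])],
                     paste(unique(ws), collapse = " vs ")), call. = FALSE)
      }
    }
    dup <- !duplicated(key)
    A[cbind(lo[dup], hi[dup])] <- w[dup]
    A[cbind(hi[dup], lo[dup])] <- w[dup]
  }

  labels <- NULL
  if (!is.null(labels_path)) {
    lab <- utils::read.table(labels_path, sep = "\t", header = FALSE,
                             comment.char = "#", colClasses = "character",
                             quote = "")
    unknown <- setdiff(lab[[1L]], ids)
    if (length(unknown)) {
      stop("label table mentions node id absent from feature table: ",
           unknown[1L], call. = FALSE)
    }
    labels <- rep(NA_integer_, m)
    labels[idx[lab[[1L]]]] <- as.integer(lab[[2L]])
  }
  bio_graph(A, fmat, labels = labels, node_ids = ids)
}

#' Write a graph to edge-list, feature, and label files
#'
#' Inverse of [read_graph()]: `read_graph` of the written files reproduces the
#' (adjacency, features, labels) triple exactly.
#'
#' @param graph a [bio_graph()].
#' @param edge_list_path,features_path output paths.
#' @param labels_path optional output path for labels (labeled nodes only).
#' @export
write_graph <- function(graph, edge_list_path, features_path,
                        labels_path = NULL) {
  A <- graph$adjacency
  ut <- which(upper.tri(A) & A != 0, arr.ind = TRUE)
  weighted <- any(A[ut] != 1)
  lines <- if (nrow(ut)) {
    if (weighted) {
      sprintf("%s\t%s\t%s", graph$node_ids[ut[, 1L]], graph$node_ids[ut[, 2L]],
              format(A[ut], digits = 17, trim = TRUE, scientific = FALSE))
    } else {
      sprintf("%s\t%s", graph$node_ids[ut[, 1L]], graph$node_ids[ut[, 2L]])
    }
  } else character(0)
  writeLines(lines, edge_list_path)
  write_matrix_tsv(graph$node_ids, graph$features, features_path)
  if (!is.null(labels_path)) {
    keep <- which(!is.na(graph$labels))
    writeLines(sprintf("%s\t%d", graph$node_ids[keep], graph$labels[keep]),
               labels_path)
  }
  invisible(NULL)
}

write_matrix_tsv <- function(ids, mat, path) {
  if (length(ids) == 0L) {
    writeLines(character(0), path)
    return(invisible(NULL))
  }
  rows <- vapply(seq_along(ids), function(i) {
    paste(c(ids[i], sprintf("%.17g", mat[i, ])), collapse = "\t")
  }, character(1))
  writeLines(rows, path)
  invisible(NULL)
}

#' Write node embeddings to a TSV
#'
#' One line per node: external id followed by the embedding coordinates at
#' full double precision, so a write/read round trip is exact.
#'
#' @param graph the [bio_graph()] supplying node identifiers.
#' @param embeddings numeric matrix with one row per node.
#' @param path output path.
#' @export
write_embeddings <- function(graph, embeddings, path) {
  embeddings <- as.matrix(embeddings)
  if (nrow(embeddings) != n_nodes(graph)) {
    stop("embedding rows (", nrow(embeddings), ") != number of nodes (",
         n_nodes(graph), ")", call. = FALSE)
  }
  write_matrix_tsv(graph$node_ids, embeddings, path)
}

#' Read an embeddings TSV written by [write_embeddings()]
#'
#' @param path path to the TSV.
#' @return numeric matrix with node ids as row names.
#' @export
read_embeddings <- function(path) {
  tab <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      colClasses = "character", quote = ""),
    error = function(e) NULL)
  if (is.null(tab) || !nrow(tab)) {
    return(matrix(numeric(0), nrow = 0, ncol = 0))
  }
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  dimnames(mat) <- list(tab[[1L]], NULL)
  mat
}

#' Construct a graph bank
#'
#' A bank is an ordered collection of [bio_graph()]s sharing one feature
#' dimension and one label alphabet, each tagged auxiliary or target.
#'
#' @param graphs list of `bio_graph` objects.
#' @param roles character vector, one of `"auxiliary"`/`"target"` per graph.
#' @return an object of class `"graph_bank"`.
#' @export
graph_bank <- function(graphs, roles) {
  stopifnot(length(graphs) == length(roles),
            all(roles %in% c("auxiliary", "target")))
  hs <- vapply(graphs, function(g) ncol(g$features), integer(1))
  if (length(unique(hs)) > 1L) {
    stop("all graphs in a bank must share the feature dimension", call. = FALSE)
  }
  structure(list(graphs = graphs, roles = roles), class = "graph_bank")
}

#' @export
print.graph_bank <- function(x, ...) {
  cat(sprintf("<graph_bank> %d graphs (%d auxiliary, %d target)\n",
              length(x$graphs), sum(x$roles == "auxiliary"),
              sum(x$roles == "target")))
  invisible(x)
}

bank_auxiliary <- function(bank) which(bank$roles == "auxiliary")
bank_target <- function(bank) {
  i <- which(bank$roles == "target")
  if (!length(i)) stop("bank has no target graph", call. = FALSE)
  bank$graphs[[i[1L]]]
}

#' Read a graph bank from a directory
#'
#' Expects files `graph<i>_{edges,features,labels}.tsv` plus a `manifest.json`
#' with the role of each graph, as written by [write_bank()] and
#' [generate_bank()].
#'
#' @param dir directory path.
#' @return a [graph_bank()].
#' @export
read_bank <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  graphs <- lapply(seq_along(man$roles), function(i) {
    lp <- file.path(dir, sprintf("graph%d_labels.tsv", i))
    read_graph(file.path(dir, sprintf("graph%d_edges.tsv", i)),
               file.path(dir, sprintf("graph%d_features.tsv", i)),
               if (file.exists(lp)) lp else NULL)
  })
  graph_bank(graphs, man$roles)
}

#' Write a graph bank to a directory
#'
#' @param bank a [graph_bank()].
#' @param dir output directory (created if needed).
#' @export
write_bank <- function(bank, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(bank$graphs)) {
    g <- bank$graphs[[i]]
    write_graph(g,
                file.path(dir, sprintf("graph%d_edges.tsv", i)),
                file.path(dir, sprintf("graph%d_features.tsv", i)),
                if (!is.null(g$labels))
                  file.path(dir, sprintf("graph%d_labels.tsv", i)) else NULL)
  }
  jsonlite::write_json(list(roles = bank$roles),
                       file.path(dir, "manifest.json"), auto_unbox = FALSE)
  invisible(NULL)
}
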