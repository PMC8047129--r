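# Evaluation harnesses: few-shot node classification on the target graph
# (micro/macro F1) and prototype-based link prediction on held-out edges.

#' Micro- and macro-averaged F1
#'
#' Micro-F1 pools true/false positives and negatives over all classes;
#' Macro-F1 is the unweighted mean of per-class F1 scores (a class with no
#' true or predicted members scores 0).
#'
#' @param truth,pred integer class vectors of equal length.
#' @param classes class alphabet (default: union of truth and pred).
#' @return named numeric vector `c(micro, macro)`.
#' @export
f1_scores <- function(truth, pred, classes = sort(unique(c(truth, pred)))) {
  stopifnot(length(truth) == length(pred))
  tp <- fp <- fn <- numeric(length(classes))
  per_class <- numeric(length(classes))
  for (i in seq_along(classes)) {
    k <- classes[i]
    tp[i] <- sum(truth == k & pred == k)
    fp[i] <- sum(truth != k & pred == k)
    fn[i] <- sum(truth == k & pred != k)
    denom <- 2 * tp[i] + fp[i] + fn[i]
    per_class[i] <- if (denom > 0) 2 * tp[i] / denom else 0
  }
  TP <- sum(tp); FP <- sum(fp); FN <- sum(fn)
  micro <- if (2 * TP + FP + FN > 0) 2 * TP / (2 * TP + FP + FN) else 0
  c(micro = micro, macro = mean(per_class))
}

#' Few-shot node classification on the target graph
#'
#' Samples a `shots`-per-class support set among the target's labeled nodes,
#' builds prototypes with the frozen fitted parameters, classifies the
#' remaining labeled nodes, and reports micro/macro F1. A class with fewer
#' than `shots + 1` labeled nodes contributes all but one of them as support
#' (so every class retains at least one query); a class needs at least two
#' labeled nodes.
#'
#' @param object a fitted `"sebiograph"` (from [sebiograph()] or
#'   [train_scratch()]).
#' @param target the target [bio_graph()] with labels.
#' @param shots support nodes per class.
#' @param seed seed for the support draw.
#' @return list with `micro_f1`, `macro_f1`, the drawn `support_idx`, and the
#'   query predictions.
#' @export
evaluate_node_classification <- function(object, target, shots = 10L,
                                         seed = 1L) {
  set.seed(as.integer(seed))
  target <- prepare_graph(target)
  labeled <- which(!is.na(target$labels))
  y <- target$labels[labeled]
  classes <- sort(unique(y))
  sup <- integer(0)
  for (k in classes) {
    mem <- labeled[y == k]
    if (length(mem) < 2L) {
      stop(sprintf("class %d has %d labeled nodes; need at least 2",
                   k, length(mem)), call. = FALSE)
    }
    nk <- min(shots, length(mem) - 1L)  # keep at least one query per class
    if (nk < shots) {
      message(sprintf("class %d: only %d labeled nodes; using %d support shots",
                      k, length(mem), nk))
    }
    sup <- c(sup, sample(mem, nk))
  }
  qry <- setdiff(labeled, sup)
  missing <- setdiff(target$labels[qry], target$labels[sup])
  if (length(missing)) {
    stop("query class absent from support: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  pr <- predict(object, target, support_idx = sup,
                support_y = target$labels[sup], nodes = qry)
  f1 <- f1_scores(target$labels[qry], pr$labels, classes)
  list(micro_f1 = unname(f1["micro"]), macro_f1 = unname(f1["macro"]),
       support_idx = sup, query_idx = qry, predicted = pr$labels)
}

#' Prototype-based link prediction on the target graph
#'
#' Pairs (edges and an equal number of sampled non-edges) are embedded as the
#' coordinate-wise product of their endpoint embeddings. Edges are split
#' 80/20; a `shots`-pair support per class drawn from the training portion
#' forms the two class prototypes (mean pooling), and accuracy is reported on
#' the held-out 20% of edges plus matched non-edges. With `folds > 1` the
#' edge set is partitioned into folds, each held out once, and the mean is
#' returned.
#'
#' @param object a fitted `"sebiograph"`.
#' @param target the target [bio_graph()].
#' @param shots support pairs per class.
#' @param folds number of cross-validation folds (1 = single 80/20 split).
#' @param seed seed for splits and negative sampling.
#' @return list with `accuracy` (mean over folds) and `fold_accuracy`.
#' @export
evaluate_link_prediction <- function(object, target, shots = 10L, folds = 1L,
                                     seed = 1L) {
  set.seed(as.integer(seed))
  H <- embed_graph(object, target)
  A <- target$adjacency
  eidx <- which(upper.tri(A) & A != 0, arr.ind = TRUE)
  ne <- nrow(eidx)
  if (ne < shots + 1L) stop("fewer known edges than shots", call. = FALSE)
  negs <- sample_nonedges(A, ne)
  pairs_pos <- pair_features(H, eidx)
  pairs_neg <- pair_features(H, negs)
  nfold <- if (folds > 1L) folds else 5L
  fold_of <- rep_len(seq_len(nfold), ne)[sample.int(ne)]
  fold_neg <- rep_len(seq_len(nfold), ne)[sample.int(ne)]
  use_folds <- if (folds > 1L) seq_len(nfold) else 1L
  acc <- vapply(use_folds, function(f) {
    te_p <- which(fold_of == f); tr_p <- which(fold_of != f)
    te_n <- which(fold_neg == f); tr_n <- which(fold_neg != f)
    link_fold_accuracy(pairs_pos, pairs_neg, tr_p, te_p, tr_n, te_n, shots,
                       object$config$distance)
  }, numeric(1))
  list(accuracy = mean(acc), fold_accuracy = acc)
}

link_fold_accuracy <- function(pairs_pos, pairs_neg, tr_p, te_p, tr_n, te_n,
                               shots, distance) {
  if (length(tr_p) < shots || length(tr_n) < shots) {
    stop("fewer known training pairs than shots", call. = FALSE)
  }
  sup_p <- pairs_pos[sample(tr_p, shots), , drop = FALSE]
  sup_n <- pairs_neg[sample(tr_n, shots), , drop = FALSE]
  C <- rbind(colMeans(sup_p), colMeans(sup_n))  # class 1 = edge, 2 = non-edge
  test <- rbind(pairs_pos[te_p, , drop = FALSE], pairs_neg[te_n, , drop = FALSE])
  truth <- c(rep(1L, length(te_p)), rep(2L, length(te_n)))
  pred <- classify_nodes(test, C, distance)$labels
  mean(pred == truth)
}

pair_features <- function(H, idx) {
  H[idx[, 1L], , drop = FALSE] * H[idx[, 2L], , drop = FALSE]
}

# uniform sample of n unconnected (u < v) pairs
sample_nonedges <- function(A, n) {
  m <- nrow(A)
  out <- matrix(0L, 0, 2)
  seen <- character(0)
  while (nrow(out) < n) {
    u <- sample.int(m, n, replace = TRUE)
    v <- sample.int(m, n, replace = TRUE)
    lo <- pmin(u, v); hi <- pmax(u, v)
    ok <- lo != hi & A[cbind(lo, hi)] == 0
    key <- paste(lo, hi)
    ok <- ok & !duplicated(key) & !(key %in% seen)
    out <- rbind(out, cbind(lo[ok], hi[ok]))
    seen <- c(seen, key[ok])
  }
  out[seq_len(n), , drop = FALSE]
}
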