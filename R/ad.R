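# Minimal reverse-mode automatic differentiation on dense matrices.
#
# Every value on the tape is a base R matrix (scalars are 1x1). An op whose
# inputs are all plain matrices returns a plain matrix, so the same forward
# code serves both inference (no tape) and training (gradients). Nodes are
# environments; creation order is a valid topological order, so the backward
# sweep simply walks the tape in reverse.

.ad <- new.env(parent = emptyenv())
.ad$tape <- NULL

ad_begin <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  .ad$tape <- t
  invisible(t)
}

ad_end <- function() {
  .ad$tape <- NULL
  invisible(NULL)
}

is_adnode <- function(x) inherits(x, "adnode")

# value of a node or pass-through for a plain matrix
vof <- function(x) if (is_adnode(x)) x$val else x

ad_node <- function(val, back = NULL) {
  t <- .ad$tape
  if (is.null(t)) stop("no active tape; call ad_begin() first", call. = FALSE)
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$back <- back
  t$n <- t$n + 1L
  if (t$n > length(t$nodes)) t$nodes <- c(t$nodes, vector("list", length(t$nodes)))
  t$nodes[[t$n]] <- nd
  class(nd) <- "adnode"
  nd
}

ad_param <- function(val) ad_node(val)

ad_accum <- function(nd, g) {
  if (is_adnode(nd)) nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

# Backward sweep from a scalar (1x1) node.
ad_backward <- function(loss) {
  stopifnot(is_adnode(loss), length(loss$val) == 1L)
  loss$grad <- matrix(1, 1, 1)
  t <- .ad$tape
  for (i in seq.int(t$n, 1L)) {
    nd <- t$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$back)) nd$back(nd$grad)
  }
  invisible(NULL)
}

# -- op constructors ----------------------------------------------------------

ad_op1 <- function(a, fwd, bk) {
  if (!is_adnode(a)) return(fwd(a))
  av <- a$val
  ov <- fwd(av)
  out <- ad_node(ov)
  out$back <- function(g) ad_accum(a, bk(g, av, ov))
  out
}

ad_op2 <- function(a, b, fwd, ba, bb) {
  if (!is_adnode(a) && !is_adnode(b)) return(fwd(a, b))
  av <- vof(a); bv <- vof(b)
  out <- ad_node(fwd(av, bv))
  out$back <- function(g) {
    if (is_adnode(a)) ad_accum(a, ba(g, av, bv))
    if (is_adnode(b)) ad_accum(b, bb(g, av, bv))
  }
  out
}

# -- arithmetic ---------------------------------------------------------------

ad_mm <- function(a, b) ad_op2(a, b, `%*%`,
  function(g, av, bv) g %*% t(bv),
  function(g, av, bv) t(av) %*% g)

# a %*% t(b)
ad_mm_t <- function(a, b) ad_op2(a, b, function(av, bv) av %*% t(bv),
  function(g, av, bv) g %*% bv,
  function(g, av, bv) t(g) %*% av)

ad_add <- function(a, b) ad_op2(a, b, `+`,
  function(g, av, bv) g,
  function(g, av, bv) g)

ad_sub <- function(a, b) ad_op2(a, b, `-`,
  function(g, av, bv) g,
  function(g, av, bv) -g)

ad_hadamard <- function(a, b) ad_op2(a, b, `*`,
  function(g, av, bv) g * bv,
  function(g, av, bv) g * av)

# multiply row i of `mat` by s[i]; s is a k x 1 column
ad_scale_rows <- function(mat, s) ad_op2(mat, s,
  function(mv, sv) mv * as.vector(sv),
  function(g, mv, sv) g * as.vector(sv),
  function(g, mv, sv) matrix(rowSums(g * mv), ncol = 1))

ad_scale <- function(a, k) ad_op1(a, function(v) v * k, function(g, v, o) g * k)

ad_t <- function(a) ad_op1(a, t, function(g, v, o) t(g))

ad_sumsq <- function(a) ad_op1(a,
  function(v) matrix(sum(v * v), 1, 1),
  function(g, v, o) 2 * v * as.numeric(g))

ad_rowsums <- function(a) ad_op1(a,
  function(v) matrix(rowSums(v), ncol = 1),
  function(g, v, o) matrix(as.vector(g), nrow(v), ncol(v)))

ad_rsqrt <- function(a) ad_op1(a,
  function(v) 1 / sqrt(v),
  function(g, v, o) g * (-0.5) * o / v)

# row subset; idx may repeat, backward aggregates
ad_rows <- function(a, idx) ad_op1(a,
  function(v) v[idx, , drop = FALSE],
  function(g, v, o) {
    out <- matrix(0, nrow(v), ncol(v))
    for (j in seq_along(idx)) out[idx[j], ] <- out[idx[j], ] + g[j, ]
    out
  })

# stack a list of 1 x c rows into a length(lst) x c matrix
ad_rbind_rows <- function(lst) {
  anynode <- any(vapply(lst, is_adnode, logical(1)))
  vals <- lapply(lst, vof)
  ov <- do.call(rbind, vals)
  if (!anynode) return(ov)
  out <- ad_node(ov)
  out$back <- function(g) {
    for (i in seq_along(lst)) ad_accum(lst[[i]], g[i, , drop = FALSE])
  }
  out
}

# -- nonlinearities -----------------------------------------------------------

ad_relu <- function(a) ad_op1(a,
  function(v) pmax(v, 0),
  function(g, v, o) g * (v > 0))

ad_tanh <- function(a) ad_op1(a, tanh, function(g, v, o) g * (1 - o * o))

ad_sigmoid <- function(a) ad_op1(a,
  function(v) 1 / (1 + exp(-v)),
  function(g, v, o) g * o * (1 - o))

ad_activate <- function(a, act) {
  switch(act,
    none = a,
    relu = ad_relu(a),
    tanh = ad_tanh(a),
    sigmoid = ad_sigmoid(a),
    stop("unknown activation: ", act, call. = FALSE))
}

# -- softmax family -----------------------------------------------------------

row_softmax_val <- function(v) {
  mx <- apply(v, 1, max)
  e <- exp(v - mx)
  e / rowSums(e)
}

ad_row_softmax <- function(a) ad_op1(a, row_softmax_val,
  function(g, v, o) o * (g - rowSums(g * o)))

# normalize a column vector of scores to weights s / sum(s) (literal ratio form)
ad_ratio_norm <- function(a) ad_op1(a,
  function(v) v / sum(v),
  function(g, v, o) (g - sum(g * o)) / sum(v))

ad_vec_softmax <- function(a) ad_op1(a,
  function(v) { e <- exp(v - max(v)); e / sum(e) },
  function(g, v, o) o * (g - sum(g * o)))

# -- pooling ------------------------------------------------------------------

ad_col_max <- function(a) {
  ad_op1(a,
    function(v) matrix(apply(v, 2, max), 1),
    function(g, v, o) {
      out <- matrix(0, nrow(v), ncol(v))
      idx <- apply(v, 2, which.max)
      out[cbind(idx, seq_len(ncol(v)))] <- as.vector(g)
      out
    })
}

ad_col_mean <- function(a) ad_op1(a,
  function(v) matrix(colMeans(v), 1),
  function(g, v, o) matrix(as.vector(g), nrow(v), ncol(v), byrow = TRUE) / nrow(v))

# rows scaled to unit Euclidean norm (for cosine distance); eps guards zeros
ad_row_normalize <- function(a, eps = 1e-12) ad_op1(a,
  function(v) v / pmax(sqrt(rowSums(v * v)), eps),
  function(g, v, o) {
    nrm <- pmax(sqrt(rowSums(v * v)), eps)
    (g - o * rowSums(g * o)) / nrm
  })

# -- distances and the episode loss ------------------------------------------

# pairwise squared Euclidean distances: X (q x c) vs C (k x c) -> q x k
ad_sqdist <- function(X, C) ad_op2(X, C,
  function(xv, cv) {
    outer(rowSums(xv * xv), rowSums(cv * cv), `+`) - 2 * xv %*% t(cv)
  },
  function(g, xv, cv) 2 * (xv * rowSums(g) - g %*% cv),
  function(g, xv, cv) 2 * (cv * colSums(g) - t(g) %*% xv))

# negative log softmax(-D) likelihood of labels y (1-based column per row)
ad_proto_nll <- function(D, y, reduction = "mean") {
  fwd <- function(dv) {
    nd <- -dv
    mx <- apply(nd, 1, max)
    lse <- mx + log(rowSums(exp(nd - mx)))
    li <- lse + dv[cbind(seq_len(nrow(dv)), y)]
    matrix(if (reduction == "mean") mean(li) else sum(li), 1, 1)
  }
  ad_op1(D, fwd, function(g, dv, o) {
    p <- row_softmax_val(-dv)
    oneh <- matrix(0, nrow(dv), ncol(dv))
    oneh[cbind(seq_len(nrow(dv)), y)] <- 1
    scl <- if (reduction == "mean") nrow(dv) else 1
    as.numeric(g) * (oneh - p) / scl
  })
}

# gather parameter gradients from a named list of param nodes
ad_grads <- function(param_nodes) {
  rapply(param_nodes, how = "replace", f = function(nd) {
    if (is.null(nd$grad)) nd$val * 0 else nd$grad
  })
}
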