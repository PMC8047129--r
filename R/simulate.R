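# Seeded generator of graph banks with the structure the method assumes:
# stochastic-block-model topology planted on the class labels, and Gaussian
# class-conditional node features whose class means are shared across every
# graph of the bank (the transferable structure).

#' Simulation preset
#'
#' Named parameter bundles for the synthetic graph banks.
#' `"easy"`: 5 auxiliary graphs + 1 target, m = 200 nodes, K = 4 classes,
#' h = 16 features, within/between edge probabilities 0.15/0.01, class-mean
#' separation s = 5 feature standard deviations, label fraction 0.3.
#' `"hard"`: the same but s = 1.5, p_in = 0.08, p_out = 0.03.
#'
#' @param name `"easy"` or `"hard"`.
#' @return a named list of class `"sim_preset"`.
#' @export
sim_preset <- function(name = c("easy", "hard")) {
  name <- match.arg(name)
  p <- list(
    name = name,
    n_auxiliary = 5L, n_target = 1L,
    m = 200L, K = 4L, h = 16L,
    p_in = 0.15, p_out = 0.01,
    s = 5,
    label_fraction = 0.3
  )
  if (name == "hard") {
    p$s <- 1.5
    p$p_in <- 0.08
    p$p_out <- 0.03
  }
  structure(p, class = "sim_preset")
}

validate_preset <- function(p) {
  stopifnot(p$p_in >= p$p_out, p$p_out >= 0, p$s >= 0,
            p$label_fraction > 0, p$label_fraction <= 1,
            p$K >= 2, p$K <= p$h, p$m >= p$K)
  invisible(p)
}

#' Generate a graph bank
#'
#' Each graph draws node labels uniformly over the K classes, edges from a
#' stochastic block model (Bernoulli `p_in` within a class, `p_out` between),
#' and features as the class mean plus unit Gaussian noise. The class means
#' are `s` times orthogonal unit directions, shared across every graph in the
#' bank, so pairs of class means sit `s * sqrt(2)` feature standard deviations
#' apart. A `label_fraction` subset of each graph's nodes keeps its label; the
#' rest are unlabeled. Output is fully determined by the seed.
#'
#' @param preset a [sim_preset()] (or a compatible list).
#' @param seed integer seed.
#' @param dir optional directory: when given, the bank and a `preset.json`
#'   manifest are written there via the package's text formats.
#' @return a [graph_bank()]; each graph additionally carries `true_labels`
#'   (the full planted labeling) for evaluation.
#' @export
#' @examples
#' bank <- generate_bank(sim_preset("easy"), seed = 1)
#' bank
generate_bank <- function(preset, seed = 1L, dir = NULL) {
  validate_preset(preset)
  set.seed(as.integer(seed))
  K <- preset$K; m <- preset$m; h <- preset$h
  mu <- diag(1, K, h) * preset$s  # orthogonal class means, norm s
  ngraph <- preset$n_auxiliary + preset$n_target
  roles <- c(rep("auxiliary", preset$n_auxiliary),
             rep("target", preset$n_target))
  graphs <- vector("list", ngraph)
  for (gi in seq_len(ngraph)) {
    z <- sample_classes(m, K)
    A <- sbm_adjacency(z, preset$p_in, preset$p_out)
    X <- mu[z, , drop = FALSE] + matrix(stats::rnorm(m * h), m, h)
    lab <- rep(NA_integer_, m)
    nlab <- max(K, round(preset$label_fraction * m))
    keep <- sample.int(m, nlab)
    lab[keep] <- z[keep]
    g <- bio_graph(A, X, labels = lab,
                   node_ids = sprintf("g%d_n%d", gi, seq_len(m)))
    g$true_labels <- z
    graphs[[gi]] <- g
  }
  bank <- graph_bank(graphs, roles)
  if (!is.null(dir)) {
    write_bank(bank, dir)
    jsonlite::write_json(c(unclass(preset), list(seed = as.integer(seed))),
                         file.path(dir, "preset.json"), auto_unbox = TRUE)
  }
  bank
}

# uniform class labels, resampled (bounded) until every class is non-empty
sample_classes <- function(m, K, max_retry = 100L) {
  for (i in seq_len(max_retry)) {
    z <- sample.int(K, m, replace = TRUE)
    if (length(unique(z)) == K) return(z)
  }
  stop("could not draw labels with every class non-empty", call. = FALSE)
}

sbm_adjacency <- function(z, p_in, p_out) {
  m <- length(z)
  P <- ifelse(outer(z, z, `==`), p_in, p_out)
  U <- matrix(0, m, m)
  ut <- upper.tri(U)
  U[ut] <- as.numeric(stats::runif(sum(ut)) < P[ut])
  U + t(U)
}
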