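# Fixture builders shared across the suite. All graphs are generated in code.

# small two-community graph with class-separated 1-d..h-d features
toy_graph <- function(seed, m = 6L, K = 2L, h = 3L, p_in = 0.8, p_out = 0.2,
                      sep = 2) {
  set.seed(seed)
  z <- rep(seq_len(K), length.out = m)
  A <- matrix(0, m, m)
  for (i in seq_len(m - 1L)) {
    for (j in seq.int(i + 1L, m)) {
      p <- if (z[i] == z[j]) p_in else p_out
      if (stats::runif(1) < p) { A[i, j] <- 1; A[j, i] <- 1 }
    }
  }
  X <- diag(1, K, h)[z, , drop = FALSE] * sep + matrix(stats::rnorm(m * h), m, h)
  bio_graph(A, X, labels = z)
}

toy_bank <- function(seed, n_graphs = 2L, ...) {
  graph_bank(lapply(seq_len(n_graphs), function(i) toy_graph(seed + i, ...)),
             rep("auxiliary", n_graphs))
}

# small parameter/config pair for a given feature width
toy_config <- function(...) {
  sebiograph_config(hidden_dim = 4L, out_dim = 3L, fgnn_dim = 3L,
                    decoder_dim = 2L, cluster_counts = 2L,
                    ways = 2L, shots = 2L, queries = 2L, ...)
}

toy_params <- function(h = 3L, config = toy_config(), seed = 1L, m = 6L) {
  set.seed(seed)
  init_params(h, config, m = m)
}

# reference normalized adjacency, written independently of the package
ref_norm_adj <- function(A) {
  At <- A + diag(nrow(A))
  d <- rowSums(At)
  diag(1 / sqrt(d)) %*% At %*% diag(1 / sqrt(d))
}

# independent textbook prototypical-network loss (mean prototypes, squared
# Euclidean distance, mean reduction) computed with plain loops
brute_proto_loss <- function(H, sup_i, sup_y, qry_i, qry_y) {
  classes <- sort(unique(sup_y))
  protos <- t(vapply(classes, function(k) {
    colMeans(H[sup_i[sup_y == k], , drop = FALSE])
  }, numeric(ncol(H))))
  total <- 0
  for (j in seq_along(qry_i)) {
    d <- vapply(seq_len(nrow(protos)), function(r) {
      sum((H[qry_i[j], ] - protos[r, ])^2)
    }, numeric(1))
    p <- exp(-d) / sum(exp(-d))
    total <- total - log(p[match(qry_y[j], classes)])
  }
  total / length(qry_i)
}

# finite-difference gradient of the full episode objective for every entry
fd_episode_grad <- function(graph, episode, params, config, h = 1e-5) {
  loss_at <- function(p) {
    as.numeric(sebiograph:::vof(
      sebiograph:::episode_objective(graph, episode, p, config)$total))
  }
  out <- rapply(params, function(x) x * 0, how = "replace")
  for (nm in names(params)) {
    pcs <- if (is.list(params[[nm]])) seq_along(params[[nm]]) else NA_integer_
    for (pc in pcs) {
      M <- if (is.na(pc)) params[[nm]] else params[[nm]][[pc]]
      G <- M * 0
      for (i in seq_along(M)) {
        pp <- params; pm <- params
        if (is.na(pc)) {
          pp[[nm]][i] <- M[i] + h; pm[[nm]][i] <- M[i] - h
        } else {
          pp[[nm]][[pc]][i] <- M[i] + h; pm[[nm]][[pc]][i] <- M[i] - h
        }
        G[i] <- (loss_at(pp) - loss_at(pm)) / (2 * h)
      }
      if (is.na(pc)) out[[nm]] <- G else out[[nm]][[pc]] <- G
    }
  }
  out
}

max_rel_grad_err <- function(analytic, fd, floor = 1e-6) {
  flat <- function(x) unlist(rapply(x, as.vector, how = "unlist"))
  a <- flat(analytic); b <- flat(fd)
  max(abs(a - b) / pmax(abs(a), abs(b), floor))
}
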