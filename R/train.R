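# Episodic meta-training: sample an episode from the auxiliary graphs, run
# hierarchy -> gated encoder -> structured prototypes -> episode loss plus the
# reconstruction constraint, backpropagate, and update all parameters.

params_to_nodes <- function(p) {
  lapply(p, function(x) if (is.list(x)) lapply(x, ad_param) else ad_param(x))
}

map2_params <- function(a, b, f) {
  out <- a
  for (nm in names(a)) {
    out[[nm]] <- if (is.list(a[[nm]])) {
      mapply(f, a[[nm]], b[[nm]], SIMPLIFY = FALSE)
    } else {
      f(a[[nm]], b[[nm]])
    }
  }
  out
}

#' Sample a few-shot episode from a graph bank
#'
#' Draws a graph uniformly from the bank's auxiliary graphs, then `ways`
#' classes and, per class, `shots` support and up to `queries` query nodes
#' among the graph's labeled nodes, all without replacement; support and
#' query sets are disjoint by construction. Classes with fewer than
#' `shots + 1` labeled nodes are skipped; if that leaves fewer than `ways`
#' eligible classes the episode uses all of them (at least two).
#'
#' @param bank a [graph_bank()].
#' @param config a [sebiograph_config()] supplying `ways`, `shots`, `queries`.
#' @param graph_index optional fixed graph index (used at evaluation time);
#'   default samples among auxiliary graphs.
#' @return list of class `"episode"`: `graph_index`, `support_idx`,
#'   `support_y`, `query_idx`, `query_y` (labels in the graph's alphabet).
#' @export
sample_episode <- function(bank, config, graph_index = NULL) {
  pool <- bank_auxiliary(bank)
  if (is.null(graph_index)) {
    if (!length(pool)) stop("bank has no auxiliary graphs", call. = FALSE)
    graph_index <- pool[sample.int(length(pool), 1L)]
  }
  g <- bank$graphs[[graph_index]]
  episode_from_pool(which(!is.na(g$labels)), g$labels, config, graph_index)
}

# Draw an episode from a pool of labeled node indices. Each selected class
# contributes exactly `shots` support nodes plus up to `queries` query nodes
# (fewer when the class has fewer labeled members; at least one). When fewer
# than `ways` classes have enough labeled nodes the episode uses all eligible
# classes; below two the episode is infeasible.
episode_from_pool <- function(pool_idx, labels, config, graph_index = NA) {
  y <- labels[pool_idx]
  tab <- table(y)
  eligible <- as.integer(names(tab)[tab >= config$shots + 1L])
  if (length(eligible) < min(2L, config$ways)) {
    short <- as.integer(names(tab)[tab < config$shots + 1L])
    stop(sprintf(
      "graph %s: insufficient labeled nodes for a %d-way %d-shot episode (short classes: %s)",
      graph_index, config$ways, config$shots,
      paste(short, collapse = ", ")), call. = FALSE)
  }
  classes <- sample(eligible, min(config$ways, length(eligible)))
  sup_i <- integer(0); sup_y <- integer(0)
  qry_i <- integer(0); qry_y <- integer(0)
  for (k in classes) {
    mem <- pool_idx[y == k]
    nq <- min(config$queries, length(mem) - config$shots)
    pick <- sample(mem, config$shots + nq)
    sup_i <- c(sup_i, pick[seq_len(config$shots)])
    sup_y <- c(sup_y, rep(k, config$shots))
    qry_i <- c(qry_i, pick[config$shots + seq_len(nq)])
    qry_y <- c(qry_y, rep(k, nq))
  }
  structure(list(graph_index = graph_index, support_idx = sup_i,
                 support_y = sup_y, query_idx = qry_i, query_y = qry_y),
            class = "episode")
}

# Forward pass of the full objective for one episode. `params` may be plain
# matrices (inference) or tape nodes (training). Returns loss components.
episode_objective <- function(graph, episode, params, config) {
  gate <- if (config$gated) build_hierarchy(graph, params, config)$gate else NULL
  H <- encode(graph, params, gate = gate, config = config)
  proto <- episode_prototypes(graph, episode$support_idx, episode$support_y,
                              H, params, config)
  qy <- match(episode$query_y, proto$classes)
  if (anyNA(qy)) {
    stop("query class absent from the episode's support classes", call. = FALSE)
  }
  L_i <- episode_loss(ad_rows(H, episode$query_idx), qy, proto$C,
                      config$distance, config$loss_reduction)
  L_d <- reconstruction_loss(graph, H, params$W_dec, config$decoder_link,
                             config$recon_reduction)
  total <- if (config$beta > 0) ad_add(L_i, ad_scale(L_d, config$beta)) else L_i
  list(L_i = L_i, L_d = L_d, total = total)
}

#' Loss and analytic gradients for one episode
#'
#' Runs the full forward pass (hierarchy gate, gated encoder, structured
#' prototypes, episode loss, reconstruction loss) on the autodiff tape and
#' returns the total loss with the gradient of every parameter.
#'
#' @param graph the episode's [bio_graph()].
#' @param episode an episode from [sample_episode()].
#' @param params parameter list from [init_params()].
#' @param config a [sebiograph_config()].
#' @return list with scalars `loss`, `loss_episode`, `loss_recon` and the
#'   nested gradient list `grads` (same shape as `params`).
#' @export
episode_grad <- function(graph, episode, params, config) {
  ad_begin()
  on.exit(ad_end())
  pn <- params_to_nodes(params)
  obj <- episode_objective(graph, episode, pn, config)
  ad_backward(obj$total)
  list(loss = as.numeric(vof(obj$total)),
       loss_episode = as.numeric(vof(obj$L_i)),
       loss_recon = as.numeric(vof(obj$L_d)),
       grads = ad_grads(pn))
}

# -- optimizers ---------------------------------------------------------------

opt_init <- function(params, config) {
  if (config$optimizer == "adam") {
    zeros <- rapply(params, function(x) x * 0, how = "replace")
    list(kind = "adam", m = zeros, v = zeros, t = 0L)
  } else {
    list(kind = "gd")
  }
}

opt_step <- function(params, grads, state, config) {
  if (state$kind == "gd") {
    params <- map2_params(params, grads, function(p, g) p - config$gamma * g)
  } else {
    state$t <- state$t + 1L
    b1 <- config$adam_beta1; b2 <- config$adam_beta2
    state$m <- map2_params(state$m, grads, function(m, g) b1 * m + (1 - b1) * g)
    state$v <- map2_params(state$v, grads, function(v, g) b2 * v + (1 - b2) * g * g)
    corr1 <- 1 - b1^state$t; corr2 <- 1 - b2^state$t
    upd <- map2_params(state$m, state$v, function(m, v) {
      (m / corr1) / (sqrt(v / corr2) + config$adam_eps)
    })
    params <- map2_params(params, upd, function(p, u) p - config$gamma * u)
  }
  list(params = params, state = state)
}

# -- the fitting function -----------------------------------------------------

#' Fit the few-shot graph model by episodic meta-training
#'
#' Repeatedly samples episodes from the bank's auxiliary graphs; each episode
#' builds the hierarchical representation gate, encodes the graph with the
#' gate-modulated shared weights, forms structured class prototypes from the
#' support set, and minimizes the query distance-softmax loss plus `beta`
#' times the adjacency reconstruction loss by gradient descent (or Adam).
#' The run is fully reproducible from `config$seed`.
#'
#' @param bank a [graph_bank()] with at least one auxiliary graph.
#' @param config a [sebiograph_config()].
#' @return an object of class `"sebiograph"`: fitted `params`, the `config`,
#'   the resolved `cluster_counts`, and a `history` data frame with per-episode
#'   episode/reconstruction/total losses.
#' @export
#' @examples
#' \donttest{
#' bank <- generate_bank(sim_preset("easy"), seed = 1)
#' fit <- sebiograph(bank, sebiograph_config(episodes_per_epoch = 20, seed = 1))
#' print(fit)
#' }
sebiograph <- function(bank, config = sebiograph_config()) {
  stopifnot(inherits(bank, "graph_bank"))
  validate_config(config)
  set.seed(as.integer(config$seed))
  bank$graphs <- lapply(bank$graphs, prepare_graph)
  m0 <- n_nodes(bank$graphs[[1L]])
  if (is.null(config$cluster_counts)) {
    config$cluster_counts <- resolve_cluster_counts(config, m0)
  }
  h <- ncol(bank$graphs[[1L]]$features)
  params <- init_params(h, config, m = m0)
  run_training(bank, params, config, sampler = function() sample_episode(bank, config))
}

run_training <- function(bank, params, config, sampler) {
  opt <- opt_init(params, config)
  nep <- config$epochs * config$episodes_per_epoch
  hist <- data.frame(episode = seq_len(nep), graph = NA_integer_,
                     loss_episode = NA_real_, loss_recon = NA_real_,
                     loss_total = NA_real_)
  best <- Inf; stall <- 0L
  for (e in seq_len(nep)) {
    ep <- sampler()
    g <- bank$graphs[[ep$graph_index]]
    res <- episode_grad(g, ep, params, config)
    if (!is.finite(res$loss)) {
      stop(sprintf("non-finite loss at episode %d (graph %d)", e,
                   ep$graph_index), call. = FALSE)
    }
    st <- opt_step(params, res$grads, opt, config)
    params <- st$params; opt <- st$state
    hist$graph[e] <- ep$graph_index
    hist$loss_episode[e] <- res$loss_episode
    hist$loss_recon[e] <- res$loss_recon
    hist$loss_total[e] <- res$loss
    if (e %% config$episodes_per_epoch == 0L && is.finite(config$patience)) {
      epoch_mean <- mean(hist$loss_total[(e - config$episodes_per_epoch + 1L):e])
      if (epoch_mean < best - 1e-8) { best <- epoch_mean; stall <- 0L }
      else {
        stall <- stall + 1L
        if (stall >= config$patience) { hist <- hist[seq_len(e), ]; break }
      }
    }
  }
  structure(list(params = params, config = config,
                 cluster_counts = config$cluster_counts, history = hist),
            class = "sebiograph")
}

#' Train an identically sized model from scratch on a target support set
#'
#' No-transfer baseline: the same architecture, freshly initialized, trained
#' episodically on pseudo-episodes carved out of the target graph's support
#' set alone (each pseudo-episode splits every class's support members into a
#' prototype half and a query half).
#'
#' @param target the target [bio_graph()].
#' @param support_idx,support_y the support nodes and labels available on the
#'   target.
#' @param config a [sebiograph_config()].
#' @return a `"sebiograph"` fit.
#' @export
train_scratch <- function(target, support_idx, support_y, config) {
  validate_config(config)
  set.seed(as.integer(config$seed))
  target <- prepare_graph(target)
  if (is.null(config$cluster_counts)) {
    config$cluster_counts <- resolve_cluster_counts(config, n_nodes(target))
  }
  params <- init_params(ncol(target$features), config, m = n_nodes(target))
  bank1 <- graph_bank(list(target), "auxiliary")
  bank1$graphs <- lapply(bank1$graphs, prepare_graph)
  classes <- sort(unique(support_y))
  sampler <- function() {
    sup_i <- integer(0); sup_y <- integer(0)
    qry_i <- integer(0); qry_y <- integer(0)
    for (k in classes) {
      mem <- sample(support_idx[support_y == k])
      np <- max(1L, floor(length(mem) / 2))
      if (length(mem) < 2L) {  # single member: it serves both roles
        sup_i <- c(sup_i, mem); sup_y <- c(sup_y, k)
        qry_i <- c(qry_i, mem); qry_y <- c(qry_y, k)
      } else {
        sup_i <- c(sup_i, mem[seq_len(np)])
        sup_y <- c(sup_y, rep(k, np))
        qry_i <- c(qry_i, mem[-seq_len(np)])
        qry_y <- c(qry_y, rep(k, length(mem) - np))
      }
    }
    structure(list(graph_index = 1L, support_idx = sup_i, support_y = sup_y,
                   query_idx = qry_i, query_y = qry_y), class = "episode")
  }
  run_training(bank1, params, config, sampler)
}

# -- S3 methods ---------------------------------------------------------------

#' @export
print.sebiograph <- function(x, ...) {
  n <- nrow(x$history)
  cat("Few-shot graph model (gated GCN encoder + structured prototypes)\n")
  cat(sprintf("  episodes trained : %d\n", n))
  cat(sprintf("  hidden/out width : %d/%d, hierarchy depth %d\n",
              x$config$hidden_dim, x$config$out_dim, x$config$levels))
  cat(sprintf("  final loss       : %.4f (episode %.4f + beta*recon)\n",
              x$history$loss_total[n], x$history$loss_episode[n]))
  invisible(x)
}

#' @export
summary.sebiograph <- function(object, ...) {
  h <- object$history
  n <- nrow(h)
  head_n <- min(20L, n)
  out <- list(
    episodes = n,
    initial_loss = mean(h$loss_total[seq_len(head_n)]),
    final_loss = mean(h$loss_total[seq.int(max(1L, n - head_n + 1L), n)]),
    config = object$config
  )
  class(out) <- "summary.sebiograph"
  out
}

#' @export
print.summary.sebiograph <- function(x, ...) {
  cat(sprintf("episodes: %d\n", x$episodes))
  cat(sprintf("mean loss, first %s episodes : %.4f\n", "20", x$initial_loss))
  cat(sprintf("mean loss, last %s episodes  : %.4f\n", "20", x$final_loss))
  cat(sprintf("beta = %g, gamma = %g, optimizer = %s\n",
              x$config$beta, x$config$gamma, x$config$optimizer))
  invisible(x)
}

#' @export
coef.sebiograph <- function(object, ...) object$params

#' @export
plot.sebiograph <- function(x, ...) {
  h <- x$history
  graphics::plot(h$episode, h$loss_total, type = "l", xlab = "episode",
                 ylab = "loss", main = "training loss", ...)
  graphics::lines(h$episode, h$loss_episode, lty = 2)
  graphics::legend("topright", legend = c("total", "episode"), lty = c(1, 2),
                   bty = "n")
  invisible(x)
}

#' Embed a graph with a fitted model
#'
#' Builds the graph's hierarchical gate and returns the gated encoder output.
#'
#' @param object a fitted `"sebiograph"`.
#' @param graph a [bio_graph()].
#' @return m x out_dim embedding matrix.
#' @export
embed_graph <- function(object, graph) {
  cfg <- object$config
  gate <- if (cfg$gated) build_hierarchy(graph, object$params, cfg)$gate else NULL
  encode(graph, object$params, gate = gate, config = cfg)
}

#' Predict node classes on a new graph
#'
#' Builds prototypes from the graph's labeled nodes (or a supplied support
#' set) with the frozen fitted parameters, then assigns every requested node
#' the class of the nearest prototype.
#'
#' @param object a fitted `"sebiograph"`.
#' @param graph a [bio_graph()].
#' @param support_idx,support_y optional explicit support set; default uses
#'   all labeled nodes of `graph`.
#' @param nodes node indices to classify (default: all unlabeled nodes, or all
#'   nodes if the graph carries no labels).
#' @param ... unused.
#' @return list with `labels` (integer classes in the graph's alphabet) and
#'   `probabilities`.
#' @export
predict.sebiograph <- function(object, graph, support_idx = NULL,
                               support_y = NULL, nodes = NULL, ...) {
  cfg <- object$config
  graph <- prepare_graph(graph)
  if (is.null(support_idx)) {
    support_idx <- which(!is.na(graph$labels))
    support_y <- graph$labels[support_idx]
  }
  if (!length(support_idx)) stop("no support nodes available", call. = FALSE)
  if (is.null(nodes)) {
    nodes <- if (is.null(graph$labels)) seq_len(n_nodes(graph)) else
      which(is.na(graph$labels))
    if (!length(nodes)) nodes <- seq_len(n_nodes(graph))
  }
  H <- embed_graph(object, graph)
  proto <- episode_prototypes(graph, support_idx, support_y, H,
                              object$params, cfg)
  cl <- classify_nodes(H[nodes, , drop = FALSE], vof(proto$C), cfg$distance)
  list(labels = proto$classes[cl$labels], probabilities = cl$probabilities,
       classes = proto$classes, nodes = nodes)
}
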