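test_that("assignment rows are softmax distributions", {
  # equal logits -> uniform rows
  g <- toy_graph(21)
  W0 <- matrix(0, 3, 4)
  P <- assign_nodes(g$adjacency, g$features, W0, 4L)
  expect_equal(P, matrix(1 / 4, 6, 4))

  # hand softmax of logits (1, 2)
  sm <- sebiograph:::row_softmax_val(matrix(c(1, 2), 1))
  expect_equal(as.vector(sm), exp(c(1, 2)) / sum(exp(c(1, 2))))
  expect_equal(round(as.vector(sm), 4), c(0.2689, 0.7311))

  # any input: rows sum to 1
  for (s in 1:20) {
    set.seed(s)
    g <- toy_graph(s, m = 5)
    W <- matrix(stats::rnorm(9), 3, 3)
    P <- assign_nodes(g$adjacency, g$features, W, 3L)
    expect_equal(unname(rowSums(P)), rep(1, 5), tolerance = 1e-6)
    expect_true(all(P >= 0))
  }
})

test_that("over-clustering is allowed but reported", {
  g <- toy_graph(22, m = 4)
  W <- matrix(stats::rnorm(3 * 6), 3, 6)
  expect_message(assign_nodes(g$adjacency, g$features, W, 6L),
                 "over-clustering")
})

test_that("coarsening computes P'AP and preserves symmetry", {
  # both nodes of a single edge merged into one cluster
  A <- matrix(c(0, 1, 1, 0), 2)
  N <- matrix(1, 2, 1)
  P <- matrix(1, 2, 1)
  co <- coarsen(A, N, P, W_f = matrix(1))
  expect_equal(co$A_next, matrix(2, 1, 1))

  # identity assignment with identity fusion leaves the adjacency unchanged
  g <- toy_graph(23, m = 4, h = 4)
  co2 <- coarsen(g$adjacency, g$features, diag(4), diag(4))
  expect_equal(co2$A_next, g$adjacency)

  # symmetry for random row-stochastic P
  for (s in 1:20) {
    set.seed(s)
    g <- toy_graph(300 + s, m = 6)
    P <- sebiograph:::row_softmax_val(matrix(stats::rnorm(12), 6, 2))
    co <- coarsen(g$adjacency, g$features, P, matrix(stats::rnorm(9), 3, 3))
    expect_lt(max(abs(co$A_next - t(co$A_next))), 1e-12)
  }
})

test_that("level representation is the coordinate-wise max of coarsened rows", {
  # empty adjacency + identity fusion + identity assignment: rows pass through
  A <- matrix(0, 2, 2)
  N <- matrix(c(1, 3, 5, 2), 2, 2)  # rows (1,5), (3,2)
  h <- level_representation(A, N, diag(2), diag(2))
  expect_equal(h, matrix(c(3, 5), 1))

  # single cluster: the representation equals that cluster's row
  P1 <- matrix(c(1, 0), 2, 1)  # only node 1 assigned
  h1 <- level_representation(A, N, P1, diag(2))
  expect_equal(h1, matrix(c(1, 5), 1))

  # duplicating a coarsened row leaves the max unchanged
  Pdup <- cbind(diag(2), c(1, 0))
  hdup <- level_representation(A, N, Pdup, diag(2))
  expect_equal(hdup, h)

  expect_error(level_representation(A, N, matrix(numeric(0), 2, 0), diag(2)),
               "empty level")
})

test_that("attention weights are a proper convex combination of levels", {
  q <- matrix(c(1, 0), 2, 1)
  # single level: aggregate equals that level
  r1 <- matrix(c(0.3, -1), 1)
  agg <- aggregate_levels(list(r1), q)
  expect_equal(agg$h, t(r1))
  expect_equal(as.vector(agg$w), 1)

  # equal scores -> unweighted mean
  reps <- list(matrix(c(2, 5), 1), matrix(c(2, -3), 1))  # both score 2 on q
  agg2 <- aggregate_levels(reps, q)
  expect_equal(agg2$h, matrix(c(2, 1), 2, 1))

  # weights sum to 1 over random draws, both normalizations
  for (s in 1:100) {
    set.seed(s)
    reps <- lapply(1:3, function(i) matrix(stats::rnorm(4), 1))
    qv <- matrix(stats::rnorm(4), ncol = 1)
    expect_equal(sum(aggregate_levels(reps, qv)$w), 1, tolerance = 1e-9)
    repsp <- lapply(reps, abs)  # positive scores for the literal ratio form
    qp <- abs(qv)
    expect_equal(sum(aggregate_levels(repsp, qp, "ratio")$w), 1,
                 tolerance = 1e-9)
  }
})

test_that("the gate is a sigmoid squashing into (0,1)", {
  h <- matrix(c(1, -2), 2, 1)
  # zero weights: gate 0.5 everywhere
  expect_equal(compute_gate(h, matrix(0, 3, 2), matrix(0, 3, 1)),
               matrix(0.5, 3, 1))
  # sigma(0) and sigma(log 3) = 3/4
  g <- compute_gate(h, matrix(0, 2, 2), matrix(c(0, log(3)), 2, 1))
  expect_equal(g, matrix(c(0.5, 0.75), 2, 1))
  # saturation: large bias drives the gate toward 1, staying inside (0,1)
  gsat <- compute_gate(h, matrix(0, 2, 2), matrix(15, 2, 1))
  expect_true(all(gsat > 0.999 & gsat < 1))
  expect_equal(as.vector(compute_gate(h, matrix(0, 2, 2), matrix(50, 2, 1))),
               c(1, 1), tolerance = 1e-12)
})

test_that("build_hierarchy composes the stage invariants", {
  cfg <- toy_config()
  for (s in 1:10) {
    g <- toy_graph(400 + s, m = 8)
    params <- toy_params(config = cfg, seed = s, m = 8)
    hs <- build_hierarchy(g, params, cfg)
    for (P in hs$P) {
      expect_equal(unname(rowSums(P)), rep(1, nrow(P)), tolerance = 1e-6)
    }
    for (A in hs$A) expect_lt(max(abs(A - t(A))), 1e-10)
    expect_true(all(hs$gate > 0 & hs$gate < 1))
    expect_equal(sum(hs$attn_weights), 1, tolerance = 1e-9)
  }

  # D = 1: no coarsening; gate comes from max-pooled fused input features
  cfg1 <- toy_config(levels = 1L, cluster_counts = integer(0))
  params <- toy_params(config = cfg1, m = 6)
  g <- toy_graph(55)
  hs1 <- build_hierarchy(g, params, cfg1)
  expect_length(hs1$P, 0)
  fused <- ref_norm_adj(g$adjacency) %*% g$features %*% params$W_f[[1]]
  expect_equal(as.vector(hs1$h), apply(fused, 2, max))
})

test_that("hierarchy and gate are invariant under node permutation", {
  cfg <- toy_config()
  for (s in 1:5) {
    g <- toy_graph(500 + s, m = 7)
    params <- toy_params(config = cfg, seed = s, m = 7)
    set.seed(s)
    p <- sample(7)
    gp <- bio_graph(g$adjacency[p, p], g$features[p, , drop = FALSE])
    h1 <- build_hierarchy(g, params, cfg)
    h2 <- build_hierarchy(gp, params, cfg)
    expect_lt(max(abs(h1$gate - h2$gate)), 1e-6)
    expect_lt(max(abs(h1$h - h2$h)), 1e-6)
  }
})

test_that("trained assignments separate two well-marked triangles", {
  # two triangles joined by one edge, strongly separated features
  A <- matrix(0, 6, 6)
  tri <- list(1:3, 4:6)
  for (t in tri) for (i in t) for (j in t) if (i != j) A[i, j] <- 1
  A[3, 4] <- A[4, 3] <- 1
  z <- rep(1:2, each = 3)
  X <- cbind(ifelse(z == 1, 5, -5), ifelse(z == 1, -5, 5))
  g <- bio_graph(A, X, labels = z)

  # brute-force oracle: the bipartition maximizing within-cluster edge mass
  best <- NULL; best_mass <- -Inf
  for (code in 0:(2^6 - 1)) {
    part <- as.integer(intToBits(code)[1:6])
    if (length(unique(part)) < 2) next
    mass <- sum(A[part == 0, part == 0]) + sum(A[part == 1, part == 1])
    if (mass > best_mass) { best_mass <- mass; best <- part }
  }
  expect_true(all(best[1:3] == best[1]) && all(best[4:6] == best[4]))

  cfg <- toy_config(ways = 2L, shots = 2L, queries = 1L,
                    optimizer = "adam", gamma = 0.01, episodes_per_epoch = 60L,
                    seed = 7L)
  bank <- graph_bank(list(g), "auxiliary")
  fit <- sebiograph(bank, cfg)
  hs <- build_hierarchy(g, fit$params, fit$config)
  cl <- apply(hs$P[[1]], 1, which.max)
  expect_true(all(cl[1:3] == cl[1]) && all(cl[4:6] == cl[4]) && cl[1] != cl[4])
})
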