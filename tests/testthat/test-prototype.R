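test_that("relation graph weights follow the inverse-distance + overlap formula", {
  # isolated adjacent pair: spd 1, no common neighbors -> weight 0.5
  A <- matrix(0, 4, 4); A[1, 2] <- A[2, 1] <- 1; A[3, 4] <- A[4, 3] <- 1
  g <- bio_graph(A, matrix(0, 4, 2))
  D <- build_relation_graph(g, c(1, 2), k_hop = 1)
  expect_equal(D, matrix(c(0, 0.5, 0.5, 0), 2))

  # members in different components with no shared neighborhood: weight 0
  D2 <- build_relation_graph(g, c(1, 3), k_hop = 1)
  expect_equal(D2, matrix(0, 2, 2))

  # single member: 1x1 zero matrix
  expect_equal(build_relation_graph(g, 2, k_hop = 2), matrix(0, 1, 1))

  # triangle: spd 1 and full neighborhood overlap at k_hop = 1
  A3 <- matrix(1, 3, 3) - diag(3)
  g3 <- bio_graph(A3, matrix(0, 3, 1))
  D3 <- build_relation_graph(g3, c(1, 2), k_hop = 1, lambda = 1)
  # N(1)={2,3}, N(2)={1,3}: common {3}, union {1,2,3} -> 1/2 + 1/3
  expect_equal(D3[1, 2], 0.5 + 1 / 3)
})

test_that("prototypes reduce correctly in degenerate relation graphs", {
  # one member, identity weights: prototype equals the member's embedding
  E <- matrix(c(1.5, -2, 0.5), 1)
  expect_equal(compute_prototype(matrix(0, 1, 1), E, diag(3)), E)

  # zero relation weights, identity weights: coordinate-wise max of members
  E2 <- rbind(c(1, -1, 4), c(2, -3, 0))
  expect_equal(compute_prototype(matrix(0, 2, 2), E2, diag(3)),
               matrix(c(2, -1, 4), 1))

  # duplicating a member leaves the max-pooled prototype unchanged
  E3 <- rbind(E2, E2[1, ])
  expect_equal(compute_prototype(matrix(0, 3, 3), E3, diag(3)),
               compute_prototype(matrix(0, 2, 2), E2, diag(3)))

  expect_error(compute_prototype(matrix(0, 0, 0), E2[0, , drop = FALSE],
                                 diag(3)), "empty")
})

test_that("episode loss matches hand-computed softmax values", {
  # one class: softmax over a single prototype is 1, loss exactly 0
  Eq <- matrix(c(3, 1), 1)
  expect_equal(as.numeric(episode_loss(Eq, 1L, matrix(c(0, 0), 1))), 0)

  # query equidistant from two prototypes: loss = ln 2
  C <- rbind(c(1, 0), c(-1, 0))
  q <- matrix(c(0, 5), 1)
  expect_equal(as.numeric(episode_loss(q, 1L, C)), log(2))

  # prototypes at (0,0) and (3,0), query at (1,0): distances 1 and 4
  C2 <- rbind(c(0, 0), c(3, 0))
  q2 <- matrix(c(1, 0), 1)
  expect_equal(as.numeric(episode_loss(q2, 1L, C2)), log(1 + exp(-3)),
               tolerance = 1e-12)

  # sum vs mean reduction
  qq <- rbind(q2, q2)
  expect_equal(as.numeric(episode_loss(qq, c(1L, 1L), C2, reduction = "sum")),
               2 * log(1 + exp(-3)), tolerance = 1e-12)

  expect_error(episode_loss(q2, 3L, C2), "absent")
})

test_that("episode loss is non-negative and invariant to support/query reordering", {
  cfg <- toy_config()
  for (s in 1:5) {
    g <- toy_graph(600 + s, m = 8)
    params <- toy_params(config = cfg, seed = s, m = 8)
    bank <- graph_bank(list(g), "auxiliary")
    set.seed(s)
    ep <- sample_episode(bank, cfg, graph_index = 1L)
    base <- sebiograph:::episode_objective(g, ep, params, cfg)
    expect_gte(as.numeric(sebiograph:::vof(base$L_i)), 0)

    # permute support and query order
    sp <- sample(length(ep$support_idx)); qp <- sample(length(ep$query_idx))
    ep2 <- ep
    ep2$support_idx <- ep$support_idx[sp]; ep2$support_y <- ep$support_y[sp]
    ep2$query_idx <- ep$query_idx[qp]; ep2$query_y <- ep$query_y[qp]
    perm <- sebiograph:::episode_objective(g, ep2, params, cfg)
    expect_equal(as.numeric(sebiograph:::vof(perm$L_i)),
                 as.numeric(sebiograph:::vof(base$L_i)), tolerance = 1e-12)

    # episode-local class relabeling (swap the two class ids)
    ep3 <- ep
    ids <- sort(unique(ep$support_y))
    swap <- stats::setNames(rev(ids), ids)
    ep3$support_y <- unname(swap[as.character(ep$support_y)])
    ep3$query_y <- unname(swap[as.character(ep$query_y)])
    g3 <- g
    rel <- sebiograph:::episode_objective(g3, ep3, params, cfg)
    expect_equal(as.numeric(sebiograph:::vof(rel$L_i)),
                 as.numeric(sebiograph:::vof(base$L_i)), tolerance = 1e-12)
  }
})

test_that("the mean-prototype loss equals an independent brute-force implementation", {
  cfg <- toy_config(prototype = "mean")
  for (s in 1:5) {
    g <- toy_graph(700 + s, m = 6)
    params <- toy_params(config = cfg, seed = s, m = 6)
    H <- encode(g, params, config = cfg)
    bank <- graph_bank(list(g), "auxiliary")
    set.seed(s)
    ep <- sample_episode(bank, cfg, graph_index = 1L)
    proto <- sebiograph:::episode_prototypes(g, ep$support_idx, ep$support_y,
                                             H, params, cfg)
    L <- episode_loss(H[ep$query_idx, , drop = FALSE],
                      match(ep$query_y, proto$classes), proto$C)
    oracle <- brute_proto_loss(H, ep$support_idx, ep$support_y,
                               ep$query_idx, ep$query_y)
    expect_lt(abs(as.numeric(L) - oracle), 1e-8)
  }
})

test_that("classification picks the nearest prototype with deterministic ties", {
  C <- rbind(c(0, 0), c(3, 0), c(0, 3), c(6, 6), c(3, 0))
  # node exactly at prototype 2 (class 5 duplicates it: tie -> lowest index 2)
  r <- classify_nodes(matrix(c(3, 0), 1), C)
  expect_equal(r$labels, 2L)
  expect_gt(r$probabilities[1, 2], 1 / nrow(C))

  # probabilities sum to 1 across random draws
  for (s in 1:100) {
    set.seed(s)
    E <- matrix(stats::rnorm(8), 2, 4)
    Cp <- matrix(stats::rnorm(12), 3, 4)
    pr <- classify_nodes(E, Cp)$probabilities
    expect_equal(unname(rowSums(pr)), c(1, 1), tolerance = 1e-9)
  }

  # cosine distance route
  rc <- classify_nodes(matrix(c(1, 0), 1), rbind(c(2, 0), c(0, 2)), "cosine")
  expect_equal(rc$labels, 1L)

  expect_error(classify_nodes(matrix(0, 1, 2), matrix(0, 0, 2)), "empty")
})
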