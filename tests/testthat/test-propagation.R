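test_that("walk_params validates its inputs", {
  expect_error(walk_params(r = 0), "probability")
  expect_error(walk_params(r = 1.2), "probability")
  expect_error(walk_params(k = 0), "positive integer")
  expect_error(walk_params(weights = c(pp = 1)), "must name")
  expect_error(walk_params(weights = c(pp = 1, pf = -1, fp = 1,
                                       ff_up = 1, ff_down = 1)),
               "positive")
  expect_equal(walk_params(r = 1)$r, 1)
})

test_that("transition rows are biased by traversal type then normalized", {
  # P2 has a protein neighbor (P1, P3) and one function neighbor (F1)
  mi <- mixed_interactome()
  op <- build_transition_operator(
    mi, walk_params(weights = c(pp = 1, pf = 2, fp = 3,
                                ff_up = 4, ff_down = 5)))
  W <- as.matrix(op$W)
  rownames(W) <- colnames(W) <- mi$nodes$node_id
  # P2 row: two pp moves (weight 1 each) and one pf move (weight 2)
  expect_equal(W["P2", c("P1", "P3", "F1")], c(P1 = 1, P3 = 1, F1 = 2) / 4)
  # F1 row: fp move to P2 (3) and up move to F2 (4)
  expect_equal(W["F1", c("P2", "F2")], c(P2 = 3, F2 = 4) / 7)
  # F2 row: only the down move back to its child
  expect_equal(W["F2", "F1"], 1)
  # row-stochastic within 1e-12
  expect_true(all(abs(Matrix::rowSums(op$W) - 1) < 1e-12))
  expect_length(op$dangling, 0L)
})

test_that("equal weights reduce to the simple random walk operator", {
  mi <- mixed_interactome()
  op <- build_transition_operator(mi, walk_params())
  W <- as.matrix(op$W)
  deg <- rowSums(W > 0)
  expect_equal(W[W > 0], (1 / deg[row(W)])[W > 0])
})

test_that("two-node fixed point matches the closed form", {
  mi <- build_interactome(edge_df("A", "B", "protein_protein"))
  wp <- walk_params(r = 0.5, k = 1000)
  op <- build_transition_operator(mi, wp)
  s <- make_seed_vector(mi, "A")
  p <- propagate(op, s, wp)
  expect_lt(max(abs(p$values - c(2 / 3, 1 / 3))), 1e-9)
  # the oracle solves the same system exactly
  po <- stationary_oracle(op, s, r = 0.5)
  expect_equal(po$values, c(2 / 3, 1 / 3), tolerance = 1e-14)
})

test_that("pure restart returns the seed distribution", {
  mi <- path_interactome(5)
  op <- build_transition_operator(mi, walk_params())
  s <- make_seed_vector(mi, c("P1", "P3"))
  po <- stationary_oracle(op, s, r = 1)
  expect_equal(po$values, s$values / 2, tolerance = 1e-12)
})

test_that("an isolated seed keeps all mass under the restart policy", {
  # P3-P4 edge plus isolated pair member: use a seed on a dangling node by
  # seeding a node absent from all edges is impossible, so build a graph
  # where one protein only appears via a protein_function edge to a leaf
  mi <- build_interactome(
    edge_df("P1", "P2", "protein_protein"),
    edge_df("P9", "F1", "protein_function"))
  # drop the function-protein back-traversal to make F1 a sink? not
  # expressible; instead test the dangling path on a manually pruned operator
  op <- build_transition_operator(mi, walk_params())
  expect_length(op$dangling, 0L)

  # dangling redirection conserves mass: zero out P1's outgoing row
  op$W[node_index(mi, "P1"), ] <- 0
  op$dangling <- node_index(mi, "P1")
  s <- make_seed_vector(mi, "P2")
  p <- propagate(op, s, walk_params(k = 200))
  expect_equal(sum(p$values), 1, tolerance = 1e-9)
  # self-loop policy also conserves mass
  p2 <- propagate(op, s, walk_params(k = 200, dangling = "self_loop"))
  expect_equal(sum(p2$values), 1, tolerance = 1e-9)
  # and the oracle agrees with the iteration under both policies
  for (pol in c("restart", "self_loop")) {
    wp <- walk_params(k = 1000, dangling = pol)
    expect_lt(sum(abs(propagate(op, s, wp)$values -
                      stationary_oracle(op, s, params = wp)$values)), 1e-8)
  }
})

test_that("profiles on a mirror-symmetric graph are symmetric", {
  # path P1..P5 seeded at the center P3
  mi <- path_interactome(5)
  wp <- walk_params(k = 500)
  op <- build_transition_operator(mi, wp)
  p <- propagate(op, make_seed_vector(mi, "P3"), wp)
  v <- p$values
  names(v) <- p$node_ids
  expect_equal(v[["P1"]], v[["P5"]], tolerance = 1e-12)
  expect_equal(v[["P2"]], v[["P4"]], tolerance = 1e-12)
})

test_that("propagation conserves mass and stays nonnegative", {
  for (seed in 1:5) {
    mi <- random_interactome(40, 8, seed = seed)
    wp <- walk_params(k = 300)
    op <- build_transition_operator(mi, wp)
    proteins <- mi$nodes$node_id[mi$nodes$node_type == "protein"]
    set.seed(seed)
    s <- make_seed_vector(mi, sample(proteins, 4))
    p <- propagate(op, s, wp)
    expect_true(all(p$values >= 0))
    expect_lt(abs(sum(p$values) - 1), 1e-9)
  }
})

test_that("k-step propagation converges to the stationary oracle", {
  wp <- walk_params(k = 1000)
  for (seed in 1:6) {
    mi <- random_interactome(50, 10, seed = seed)
    op <- build_transition_operator(mi, wp)
    proteins <- mi$nodes$node_id[mi$nodes$node_type == "protein"]
    set.seed(100 + seed)
    s <- make_seed_vector(mi, sample(proteins, 3))
    expect_lt(sum(abs(propagate(op, s, wp)$values -
                      stationary_oracle(op, s, params = wp)$values)),
              1e-8)
  }
})

test_that("the profile is localized around the seed on a path", {
  mi <- path_interactome(9)
  wp <- walk_params(k = 500)
  op <- build_transition_operator(mi, wp)
  p <- propagate(op, make_seed_vector(mi, "P1"), wp)
  v <- p$values[match(sprintf("P%d", 1:9), p$node_ids)]
  # seed mass beats every node at distance >= half the diameter; note the
  # seed's degree-1 endpoint neighbor may collect more than the seed itself
  expect_true(all(v[1] > v[5:9]))
  # strictly decaying beyond the immediate neighborhood
  expect_true(all(diff(v[2:9]) < 0))
})

test_that("node relabeling permutes the profile identically", {
  mi <- random_interactome(30, 6, seed = 9)
  wp <- walk_params(k = 300)
  op <- build_transition_operator(mi, wp)
  proteins <- mi$nodes$node_id[mi$nodes$node_type == "protein"]
  seeds <- proteins[1:3]
  p <- propagate(op, make_seed_vector(mi, seeds), wp)

  relabel <- function(x) paste0("x", rev(as.integer(factor(x))), "_", x)
  e <- mi$edges
  remap <- stats::setNames(relabel(mi$nodes$node_id), mi$nodes$node_id)
  mi2 <- build_interactome(
    edge_df(unname(remap[e$from[e$edge_type == "protein_protein"]]),
            unname(remap[e$to[e$edge_type == "protein_protein"]]),
            "protein_protein"),
    if (any(e$edge_type == "protein_function"))
      edge_df(unname(remap[e$from[e$edge_type == "protein_function"]]),
              unname(remap[e$to[e$edge_type == "protein_function"]]),
              "protein_function"),
    if (any(e$edge_type == "function_function"))
      edge_df(unname(remap[e$from[e$edge_type == "function_function"]]),
              unname(remap[e$to[e$edge_type == "function_function"]]),
              "function_function"))
  op2 <- build_transition_operator(mi2, wp)
  p2 <- propagate(op2, make_seed_vector(mi2, unname(remap[seeds])), wp)
  expect_equal(p2$values[match(unname(remap[p$node_ids]), p2$node_ids)],
               p$values, tolerance = 1e-12)
})

test_that("cosine similarity has the closed-form values and symmetries", {
  expect_equal(cosine_similarity(c(1, 1, 0) / 2, c(1, 0, 0)), 1 / sqrt(2))
  expect_equal(cosine_similarity(c(0.2, 0.8), c(0.2, 0.8)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  # symmetric and scale-invariant
  set.seed(1)
  x <- runif(20); y <- runif(20)
  expect_equal(cosine_similarity(x, y), cosine_similarity(y, x))
  expect_equal(cosine_similarity(3.7 * x, y), cosine_similarity(x, y),
               tolerance = 1e-14)
  expect_error(cosine_similarity(c(0, 0), c(1, 0)), "zero-norm")
  expect_error(cosine_similarity(c(1, 0), c(1, 0, 0)), "length mismatch")
})

test_that("profiles export and re-read bit-exactly", {
  mi <- random_interactome(25, 5, seed = 2)
  wp <- walk_params(k = 200)
  op <- build_transition_operator(mi, wp)
  proteins <- mi$nodes$node_id[mi$nodes$node_type == "protein"]
  p <- propagate(op, make_seed_vector(mi, proteins[1:2]), wp)
  f <- tempfile(fileext = ".tsv")
  write_profile(p, f)
  back <- read_profile(f)
  expect_identical(back$values, p$values)
  expect_identical(back$node_ids, p$node_ids)
})
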