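make_graph <- function(edges_df, extra_nodes = character(0)) {
  ids <- unique(c(edges_df$from, edges_df$to, extra_nodes))
  pathway_graph("p",
                stats::setNames(lapply(tolower(ids), function(g)
                  node_spec("single", g)), ids),
                edges_df)
}

test_that("path requirements: plain activation chain and external inhibitor", {
  g <- make_graph(data.frame(from = c("A", "B"), to = c("B", "C"),
                             sign = "activation"))
  r <- path_requirements(c("A", "B", "C"), g)
  expect_equal(r$active, c("A", "B", "C"))
  expect_equal(r$inactive, character(0))
  expect_true(r$consistent && r$net_activating)

  gi <- make_graph(data.frame(from = c("A", "B", "I"), to = c("B", "C", "B"),
                              sign = c("activation", "activation",
                                       "inhibition")))
  ri <- path_requirements(c("A", "B", "C"), gi)
  expect_equal(ri$inactive, "I")
  expect_true(ri$consistent)
})

test_that("an on-path node inhibiting its own path is a contradiction (probability 0)", {
  g <- make_graph(data.frame(
    from = c("A", "B", "C", "A"), to = c("B", "C", "D", "C"),
    sign = c("activation", "activation", "activation", "inhibition")))
  # path A,B,C,D: A is on the path and also inhibits on-path node C
  r <- path_requirements(c("A", "B", "C", "D"), g)
  expect_false(r$consistent)
  expect_equal(path_probability(r, c(A = 1, B = 1, C = 1, D = 1)), 0,
               ignore_attr = TRUE)
})

test_that("in-path inhibition parity decides net transmission", {
  g <- make_graph(data.frame(from = c("A", "B"), to = c("B", "C"),
                             sign = c("inhibition", "activation")))
  r <- path_requirements(c("A", "B", "C"), g)
  expect_true(r$consistent)
  expect_false(r$net_activating)      # one inhibition: net-inhibitory
  g2 <- make_graph(data.frame(from = c("A", "B"), to = c("B", "C"),
                              sign = c("inhibition", "inhibition")))
  r2 <- path_requirements(c("A", "B", "C"), g2)
  expect_true(r2$net_activating)      # two inhibitions cancel
})

test_that("path probability is the independence product with inhibitor complements", {
  req <- list(active = c("A", "B"), inactive = character(0),
              consistent = TRUE)
  expect_equal(path_probability(req, c(A = 0.9, B = 0.8)), 0.72,
               ignore_attr = TRUE)
  req$inactive <- "I"
  # an inhibitor that is never active has no effect
  expect_equal(path_probability(req, c(A = 0.9, B = 0.8, I = 0)), 0.72,
               ignore_attr = TRUE)
  # an always-active inhibitor blocks transmission entirely
  expect_equal(path_probability(req, c(A = 0.9, B = 0.8, I = 1)), 0,
               ignore_attr = TRUE)
})

test_that("circuit probability: single path, disjoint two-path union, frozen shared-stem value", {
  chain <- make_graph(data.frame(from = c("A", "B"), to = c("B", "C"),
                                 sign = "activation"))
  np <- c(A = 0.9, B = 0.8, C = 0.7)
  expect_equal(circuit_probability(list(c("A", "B", "C")), chain, np),
               prod(np), ignore_attr = TRUE)

  # two node-disjoint paths: p + q - pq
  g2 <- make_graph(data.frame(from = c("A", "A", "B", "C"),
                              to = c("B", "C", "D", "D"),
                              sign = "activation"))
  np2 <- c(A = 1, B = 0.6, C = 0.5, D = 1)
  expect_equal(
    circuit_probability(list(c("A", "B", "D"), c("A", "C", "D")), g2, np2),
    0.6 + 0.5 - 0.3, ignore_attr = TRUE)

  # the worked-example bifurcation: shared stem A,B,D then F or G to H
  fig6 <- toy_pathways(1)$fig6
  np6 <- stats::setNames(rep(0.9, 10), names(fig6$nodes))
  p <- 0.9
  expect_equal(
    as.numeric(circuit_probability(
      list(c("ProtA", "ProtB", "ProtD", "ProtF", "ProtH"),
           c("ProtA", "ProtB", "ProtD", "ProtG", "ProtH")), fig6, np6)),
    p^3 * (2 * p^2 - p^3), tolerance = 1e-12)
})

test_that("inclusion-exclusion agrees with the Bernoulli-sampling oracle on random graphs", {
  draws <- 1e5
  set.seed(314)
  checked <- 0
  for (seed in 1:25) {
    g <- random_pathway(8, inhib_prob = 0.3, seed = seed, pathway_id = "g")
    circuits <- suppressWarnings(enumerate_circuits(g))
    if (length(circuits) == 0) next
    np <- random_node_probs(g)
    for (circ in circuits[seq_len(min(2, length(circuits)))]) {
      exact <- as.numeric(circuit_probability(circ, g, np))
      mc <- oracle_circuit_probability(circ$paths, g, np, draws)
      se <- sqrt(max(mc * (1 - mc), 1e-12) / draws)
      expect_lt(abs(exact - mc), 3 * se + 1e-9,
                label = paste("seed", seed, circ$circuit_id,
                              "exact", exact, "mc", mc))
      checked <- checked + 1
    }
  }
  expect_gte(checked, 20)
})

test_that("union bounds, path-order invariance and monotonicity hold", {
  set.seed(77)
  for (seed in 1:10) {
    g <- random_pathway(8, inhib_prob = 0.3, seed = seed, pathway_id = "g")
    circuits <- suppressWarnings(enumerate_circuits(g))
    if (length(circuits) == 0) next
    np <- random_node_probs(g)
    circ <- circuits[[which.max(vapply(circuits, function(x)
      length(x$paths), 0L))]]
    reqs <- lapply(circ$paths, path_requirements, graph = g)
    keep <- vapply(reqs, function(r) r$consistent && r$net_activating, TRUE)
    path_ps <- vapply(reqs[keep], function(r)
      as.numeric(path_probability(r, np)), 0)
    u <- as.numeric(circuit_probability(circ, g, np))
    if (length(path_ps)) {
      expect_gte(u + 1e-12, max(path_ps))
      expect_lte(u, min(1, sum(path_ps)) + 1e-12)
    } else {
      expect_equal(u, 0)
    }
    # permuting path order leaves the union unchanged
    perm <- sample(length(circ$paths))
    expect_equal(as.numeric(circuit_probability(circ$paths[perm], g, np)),
                 u, tolerance = 1e-12)
    # raising an on-path activation probability never decreases the union
    onpath <- circ$paths[[1]][1]
    np_up <- np; np_up[onpath] <- min(1, np[onpath] + 0.2)
    expect_gte(as.numeric(circuit_probability(circ, g, np_up)) + 1e-12, u)
  }
})

test_that("raising an external inhibitor's activity never increases transmission", {
  g <- make_graph(data.frame(from = c("A", "B", "I"), to = c("B", "C", "B"),
                             sign = c("activation", "activation",
                                      "inhibition")))
  np <- c(A = 0.9, B = 0.8, C = 0.7, I = 0.2)
  p_low <- as.numeric(circuit_probability(list(c("A", "B", "C")), g, np))
  np[["I"]] <- 0.9
  p_high <- as.numeric(circuit_probability(list(c("A", "B", "C")), g, np))
  expect_lte(p_high, p_low)
})

test_that("the Monte-Carlo fallback engages above the exact cap and tracks the oracle", {
  g <- make_graph(data.frame(from = c("A", "A", "B", "C"),
                             to = c("B", "C", "D", "D"),
                             sign = "activation"))
  np <- c(A = 0.9, B = 0.6, C = 0.5, D = 0.95)
  paths <- list(c("A", "B", "D"), c("A", "C", "D"))
  exact <- as.numeric(circuit_probability(paths, g, np))
  set.seed(12)
  approx <- circuit_probability(paths, g, np, max_exact_paths = 1L,
                                mc_draws = 2e5)
  expect_true(attr(approx, "approximate"))
  expect_lt(abs(as.numeric(approx) - exact), 0.005)
})

test_that("circuit activity matrices handle samples, saturation and missing nodes", {
  graphs <- toy_pathways(1)["toyinhib"]
  cs <- pathway_circuits(graphs)
  nodes <- names(graphs$toyinhib$nodes)
  # identical samples give identical columns; external inhibitor at 1
  # blocks an otherwise saturated circuit
  m <- matrix(1, 4, 2, dimnames = list(nodes, c("s1", "s2")))
  act <- circuit_activity(cs, m)
  expect_equal(act[, 1], act[, 2])
  key <- "toyinhib:RA->EC"
  expect_equal(unname(act[key, 1]), 0)
  # all nodes at 1 with the inhibitor silenced -> probability exactly 1
  m2 <- m; m2["INH", ] <- 0
  act2 <- circuit_activity(cs, m2)
  expect_equal(unname(act2[key, ]), c(1, 1), ignore_attr = TRUE)
  # unmeasured node: NA row is skipped and flagged incomplete
  m3 <- m2; m3["MB", ] <- NA_real_
  act3 <- suppressWarnings(circuit_activity(cs, m3))
  expect_true(attr(act3, "incomplete")[key])
  expect_true(all(act3 >= 0 & act3 <= 1))
})
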