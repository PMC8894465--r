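test_that("modularity matches the direct formula on worked examples", {
  bow <- bowtie_graph()
  expect_equal(modularity_q(bow, c(a = 1, b = 1, c = 1, d = 2, e = 2, f = 2)),
               2 * (3 / 7 - (7 / 14)^2))
  # one community -> 0 for any graph
  expect_equal(modularity_q(bow, rep(1, 6)), 0)
  g <- er_fixture(15, 0.3, seed = 3, connected = FALSE)
  expect_equal(modularity_q(g, rep(1, 15)), 0)
  # M isolated equal cliques at the true partition -> 1 - 1/M
  g5 <- generate_modular(100, 5, 1, 0, seed = 1)
  expect_equal(modularity_q(g5, attr(g5, "planted")), 1 - 1 / 5)
  expect_error(modularity_q(bow, c(a = 1, b = 1, c = 1, d = 2, e = 2)),
               "missing")
  expect_error(modularity_q(network(nodes = c("a", "b")), c(1, 2)), "no edges")
})

test_that("modularity is invariant under node relabeling", {
  g <- er_fixture(12, 0.35, seed = 7)
  mem <- rep(1:3, each = 4)
  perm <- withr::with_seed(1, sample(12))
  g2 <- network(cbind(perm[g$edges[, 1]], perm[g$edges[, 2]]),
                nodes = as.character(1:12))
  mem2 <- integer(12)
  mem2[perm] <- mem
  expect_equal(modularity_q(g, mem), modularity_q(g2, mem2))
  # permuting community labels leaves Q unchanged
  expect_equal(modularity_q(g, mem), modularity_q(g, c(3, 1, 2)[mem]))
})

test_that("Louvain attains the exhaustive-enumeration optimum on small graphs", {
  fixtures <- list(
    bowtie = bowtie_graph(),
    k4 = complete_graph(4),
    k6 = complete_graph(6),
    path6 = path_graph(6),
    cycle5 = cycle_graph(5),
    cycle8 = cycle_graph(8),
    star5 = star_graph(5),
    er8a = er_fixture(8, 0.4, seed = 101),
    er8b = er_fixture(8, 0.5, seed = 102),
    er7 = er_fixture(7, 0.45, seed = 103),
    two_k3_bridge = network(rbind(c(1, 2), c(1, 3), c(2, 3), c(3, 4),
                                  c(4, 5), c(4, 6), c(5, 6)))
  )
  for (name in names(fixtures)) {
    g <- fixtures[[name]]
    oracle <- max_modularity_oracle(g)
    lp <- louvain_partition(g, n_runs = 20, seed = 11)
    expect_equal(lp$Q, oracle$Q, tolerance = 1e-12, label = name)
    expect_equal(lp$Q, modularity_q(g, lp$membership), tolerance = 1e-12)
  }
  # bowtie optimum is the two-triangle split
  bow_lp <- louvain_partition(fixtures$bowtie, n_runs = 20, seed = 11)
  expect_equal(bow_lp$Q, 0.35714285714, tolerance = 1e-9)
  expect_equal(bow_lp$n_communities, 2)
  # complete graph: a single community, Q = 0
  expect_equal(louvain_partition(fixtures$k6, seed = 1)$n_communities, 1)
})

test_that("closed forms: disjoint cliques give Q = 1 - 1/M", {
  expect_equal(louvain_partition(two_cliques(5), seed = 2)$Q, 0.5)
  g5 <- generate_modular(100, 5, 1, 0, seed = 4)
  expect_equal(segregation_score(g5, seed = 3), 0.8)
})

test_that("Louvain is deterministic given a seed and never worse with restarts", {
  g <- er_fixture(40, 0.2, seed = 55)
  a <- louvain_partition(g, seed = 9)
  b <- louvain_partition(g, seed = 9)
  expect_identical(a$membership, b$membership)
  expect_identical(a$Q, b$Q)
  expect_gte(louvain_partition(g, n_runs = 10, seed = 9)$Q,
             louvain_partition(g, n_runs = 1, seed = 9)$Q)
  # all-singletons never beats the optimum
  expect_gte(a$Q, modularity_q(g, seq_len(n_nodes(g))))
})

test_that("ER graphs score below planted-partition graphs at equal density", {
  seg_er <- seg_pp <- numeric(10)
  for (i in 1:10) {
    pp <- generate_modular(60, 4, 0.5, 0.05, seed = 200 + i)
    d <- edge_density(pp)
    er <- generate_er(60, d * 59, seed = 300 + i)
    seg_pp[i] <- segregation_score(pp, n_runs = 5, seed = i)
    seg_er[i] <- segregation_score(er, n_runs = 5, seed = i)
    expect_gt(seg_er[i], 0)
  }
  expect_gt(mean(seg_pp), mean(seg_er))
})
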