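test_that("edge similarity matches hand-evaluated inclusive-neighborhood Jaccard", {
  # bare path i-k-j: intersection {k}, union {i,j,k}
  p <- network(rbind(c("i", "k"), c("k", "j")))
  expect_equal(edge_similarity(p, c("i", "k"), c("k", "j")), 1 / 3)
  # two edges of a triangle with adjacent endpoints: identical neighborhoods
  tri <- complete_graph(3)
  expect_equal(edge_similarity(tri, c("1", "3"), c("2", "3")), 1)
  # bowtie: bridge vs triangle edge sharing node c
  bow <- bowtie_graph()
  expect_equal(edge_similarity(bow, c("a", "c"), c("c", "d")), 1 / 6)
  expect_error(edge_similarity(bow, c("a", "b"), c("d", "e")),
               "share exactly one")
})

test_that("link-community covers match hand-derived dendrogram cuts", {
  # K4: all six edges one community at partition density 1
  cov <- link_community_cover(complete_graph(4))
  expect_equal(cov$n_communities, 1)
  expect_equal(cov$partition_density, 1)
  expect_equal(overlap_score(cov), 1)

  # two disjoint K4s: componentwise result
  cov2 <- link_community_cover(two_cliques(4))
  expect_equal(cov2$n_communities, 2)
  expect_equal(cov2$partition_density, 1)
  expect_equal(overlap_score(cov2), 1)

  # bowtie: two triangle communities + the bridge alone; overlap 4/3
  bow <- bowtie_graph()
  cov3 <- link_community_cover(bow)
  expect_equal(cov3$n_communities, 3)
  expect_equal(cov3$partition_density, 6 / 7)
  expect_equal(overlap_score(cov3), 4 / 3)
  # bridge endpoints c,d hold two memberships, the rest one
  expect_equal(lengths(cov3$node_memberships)[c("c", "d")],
               c(c = 2L, d = 2L))
  # reported density matches the direct evaluator
  expect_equal(cov3$partition_density,
               partition_density(bow, cov3$edge_assignment),
               tolerance = 1e-12)
})

test_that("returned cut maximizes partition density over all dendrogram cuts", {
  fixtures <- list(
    bowtie = bowtie_graph(),
    k4 = complete_graph(4),
    path5 = path_graph(5),
    cycle6 = cycle_graph(6),
    star4 = star_graph(4),
    er8 = er_fixture(8, 0.4, seed = 101),
    er7 = er_fixture(7, 0.5, seed = 77)
  )
  for (name in names(fixtures)) {
    g <- fixtures[[name]]
    if (n_edges(g) > 12) next
    cov <- link_community_cover(g)
    expect_equal(cov$partition_density, all_cuts_max_density(g),
                 tolerance = 1e-12, label = name)
    expect_equal(cov$partition_density,
                 partition_density(g, cov$edge_assignment),
                 tolerance = 1e-12, label = name)
  }
})

test_that("membership bookkeeping is consistent and relabel-invariant", {
  for (s in 1:5) {
    g <- er_fixture(20, 0.25, seed = 400 + s)
    cov <- link_community_cover(g)
    # sum of per-node membership counts == sum over communities of n_c
    n_c <- vapply(unique(cov$edge_assignment), function(cc) {
      length(unique(c(g$edges[cov$edge_assignment == cc, ])))
    }, numeric(1))
    expect_equal(sum(lengths(cov$node_memberships)), sum(n_c))
    # every non-isolated node has at least one membership
    expect_true(all(lengths(cov$node_memberships) >= 1))
  }
  # relabeling nodes leaves the overlap score unchanged
  g <- er_fixture(15, 0.3, seed = 21)
  perm <- withr::with_seed(3, sample(15))
  g2 <- network(cbind(perm[g$edges[, 1]], perm[g$edges[, 2]]),
                nodes = as.character(1:15))
  expect_equal(overlap_score(g), overlap_score(g2))
})

test_that("isolated nodes receive one singleton membership", {
  g <- network(rbind(c("a", "b"), c("b", "c"), c("a", "c")),
               nodes = c("a", "b", "c", "z"))
  cov <- link_community_cover(g)
  expect_equal(lengths(cov$node_memberships)[["z"]], 1L)
  expect_equal(cov$n_communities, 2)
  expect_equal(overlap_score(cov), 1)
})

test_that("null-normalized overlap behaves at its fixed points", {
  g <- er_fixture(40, 0.2, seed = 31)
  # zero rewiring attempts leave the null identical to g -> ratio exactly 1
  ns <- null_spec(swap_iterations_per_edge = 0)
  res <- normalized_overlap_score(g, n_null = 1, seed = 5, null_spec = ns)
  expect_equal(res$normalized_overlap, 1)
  # planted-partition at moderate segregation scores above its nulls
  gm <- generate_modular(100, 5, 0.55, 0.03, seed = 7)
  res2 <- normalized_overlap_score(gm, n_null = 5, seed = 6)
  expect_gt(res2$normalized_overlap, 1)
  expect_true(res2$maintains_segregation)
})

test_that("segregated-structure check is inclusive at the boundary", {
  expect_true(maintains_segregated_structure(5, 5))
  expect_false(maintains_segregated_structure(3, 5))
  bow_cover <- link_community_cover(bowtie_graph())
  m_ref <- louvain_partition(bowtie_graph(), seed = 1)$n_communities
  expect_true(maintains_segregated_structure(bow_cover, m_ref))  # 3 >= 2
})
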