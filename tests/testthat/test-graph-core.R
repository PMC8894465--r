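test_that("edge lists deduplicate, drop self-loops, and round-trip", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("a b", "b a", "c c"), f)
  g <- suppressWarnings(read_edge_list(f))
  expect_equal(n_edges(g), 1)
  expect_equal(n_nodes(g), 2)
  expect_warning(
    network(rbind(c("a", "b"), c("b", "a"), c("c", "c"))),
    "self-loop"
  )

  writeLines(c("1 2", "2 3"), f)
  g <- read_edge_list(f)
  expect_equal(n_edges(g), 2)
  expect_equal(n_nodes(g), 3)

  writeLines(character(0), f)
  g <- read_edge_list(f)
  expect_equal(c(n_nodes(g), n_edges(g)), c(0, 0))

  writeLines(c("a b", "onlyone"), f)
  expect_error(read_edge_list(f), "line 2")

  # round-trip preserves the edge set
  g <- er_fixture(20, 0.3, seed = 5, connected = FALSE)
  write_edge_list(g, f)
  g2 <- read_edge_list(f)
  pair_set <- function(gg) {
    la <- gg$nodes[gg$edges[, 1]]
    lb <- gg$nodes[gg$edges[, 2]]
    paste(pmin(la, lb), pmax(la, lb))
  }
  expect_setequal(pair_set(g), pair_set(g2))
})

test_that("adjacency matrices round-trip through delimited text", {
  g <- er_fixture(12, 0.4, seed = 9, connected = FALSE)
  A <- matrix(0L, 12, 12, dimnames = list(g$nodes, g$nodes))
  A[g$edges] <- 1L
  A[g$edges[, c(2, 1)]] <- 1L
  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(A, f, sep = "\t", row.names = FALSE, quote = FALSE)
  g2 <- read_adjacency(f, sep = "\t")
  expect_identical(g2$edges, g$edges)
})

test_that("binarize_to_density keeps the k strongest pairs", {
  set.seed(1)
  w5 <- matrix(0, 5, 5)
  w5[upper.tri(w5)] <- sample(10)
  w5 <- w5 + t(w5)
  wn <- weighted_network(w5)
  g <- binarize_to_density(wn, 0.3)
  expect_equal(n_edges(g), 3)
  kept <- w5[g$edges]
  expect_setequal(kept, sort(w5[upper.tri(w5)], decreasing = TRUE)[1:3])

  expect_equal(n_edges(binarize_to_density(wn, 1.0)), 10)

  # the standard 164-node, 10%-density case
  set.seed(2)
  w <- matrix(0, 164, 164)
  w[upper.tri(w)] <- runif(choose(164, 2))
  w <- w + t(w)
  g <- binarize_to_density(weighted_network(w), 0.10)
  expect_equal(n_edges(g), 1337)
  expect_error(binarize_to_density(weighted_network(matrix(0, 4, 4)), 0.5),
               "zero")
})

test_that("consensus keeps edges meeting the presence threshold inclusively", {
  g_ab <- network(rbind(c("a", "b")), nodes = c("a", "b", "c"))
  g_abc <- network(rbind(c("a", "b"), c("b", "c")), nodes = c("a", "b", "c"))
  # edge (a,b) in 3/3 -> included at 0.75
  expect_equal(n_edges(consensus_network(list(g_ab, g_ab, g_ab), 0.75)), 1)
  # edge (b,c) in 2/3 = 0.667 < 0.75 -> excluded
  cons <- consensus_network(list(g_abc, g_abc, g_ab), 0.75)
  expect_equal(n_edges(cons), 1)
  # exactly 75 of 100 -> included (>= is inclusive)
  graphs <- c(replicate(75, g_abc, simplify = FALSE),
              replicate(25, g_ab, simplify = FALSE))
  expect_equal(n_edges(consensus_network(graphs, 0.75)), 2)
  expect_error(consensus_network(list()), "empty")
})

test_that("consensus limits: union at threshold -> 0+, intersection at 1", {
  gs <- lapply(1:4, function(i) er_fixture(10, 0.3, seed = 40 + i,
                                           connected = FALSE))
  gs <- lapply(gs, function(g) new_network(as.character(1:10), g$edges))
  uni <- consensus_network(gs, 1e-9)
  inter <- consensus_network(gs, 1)
  all_keys <- sort(unique(unlist(lapply(gs, function(g)
    (g$edges[, 1] - 1) * 10 + g$edges[, 2]))))
  expect_equal((uni$edges[, 1] - 1) * 10 + uni$edges[, 2], all_keys)
  common <- Reduce(intersect, lapply(gs, function(g)
    (g$edges[, 1] - 1) * 10 + g$edges[, 2]))
  expect_setequal((inter$edges[, 1] - 1) * 10 + inter$edges[, 2], common)
})
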