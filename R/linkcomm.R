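#' Similarity of two adjacent edges
#'
#' For edges \eqn{(i,k)} and \eqn{(j,k)} sharing exactly node \eqn{k}, the
#' similarity is the Jaccard index of the inclusive neighborhoods of the
#' non-shared endpoints: \eqn{|n^+(i) \cap n^+(j)| / |n^+(i) \cup n^+(j)|}
#' with \eqn{n^+(x) = \{x\} \cup neighbors(x)}. Non-adjacent edge pairs have
#' similarity 0 by convention and can only join a link community through
#' chains of adjacent merges.
#'
#' @param g a `cn_network`.
#' @param e1,e2 edges as length-2 vectors of node labels.
#' @return similarity in \[0, 1\].
#' @export
edge_similarity <- function(g, e1, e2) {
  i1 <- match(as.character(e1), g$nodes)
  i2 <- match(as.character(e2), g$nodes)
  if (anyNA(c(i1, i2))) stop("unknown node label")
  shared <- intersect(i1, i2)
  if (length(shared) != 1) stop("edges must share exactly one node")
  i <- setdiff(i1, shared)
  j <- setdiff(i2, shared)
  A <- adjacency(g)
  np_i <- c(i, which(A[i, ]))
  np_j <- c(j, which(A[j, ]))
  length(intersect(np_i, np_j)) / length(union(np_i, np_j))
}

#' Overlapping communities by link-community detection
#'
#' Edges are agglomerated by single-linkage clustering on [edge_similarity()]
#' and the dendrogram is cut where the partition density
#' \deqn{D = \frac{2}{m} \sum_c \frac{m_c (m_c - (n_c - 1))}{(n_c - 2)(n_c - 1)}}
#' is maximal (\eqn{m_c} edges and \eqn{n_c} nodes in link community
#' \eqn{c}; communities spanning only 2 nodes contribute 0). Ties between
#' cuts are broken toward fewer communities, and equal-similarity merges are
#' processed as one level in deterministic lexicographic edge order. Each
#' node inherits the labels of its incident edges, so nodes at community
#' borders belong to several communities; single-edge communities are kept
#' and count toward memberships; isolated nodes receive one fresh singleton
#' membership so every node belongs to at least one community.
#'
#' @param g a `cn_network` with at least one edge.
#' @return an object of class `cn_linkcover`: list with `edge_assignment`
#'   (integer label per edge, in `g$edges` row order), `node_memberships`
#'   (named list of label vectors), `partition_density`,
#'   `n_communities` (edge communities plus isolated-node singletons),
#'   `dendrogram` (merge records: similarity, edge ids, level), `network`.
#' @export
link_community_cover <- function(g) {
  if (n_edges(g) < 1) stop("link communities undefined for a graph with no edges")
  res <- lc_cover_cpp(g$edges, n_nodes(g))
  labels <- res$labels
  memb <- vector("list", n_nodes(g))
  for (e in seq_len(n_edges(g))) {
    i <- g$edges[e, 1]; j <- g$edges[e, 2]
    memb[[i]] <- c(memb[[i]], labels[e])
    memb[[j]] <- c(memb[[j]], labels[e])
  }
  memb <- lapply(memb, function(x) sort(unique(x)))
  n_comm <- res$n_communities
  iso <- which(lengths(memb) == 0)
  for (v in iso) {
    n_comm <- n_comm + 1L
    memb[[v]] <- n_comm
  }
  names(memb) <- g$nodes
  structure(list(edge_assignment = labels,
                 node_memberships = memb,
                 partition_density = res$partition_density,
                 n_communities = n_comm,
                 dendrogram = res$merges,
                 network = g),
            class = "cn_linkcover")
}

#' @export
print.cn_linkcover <- function(x, ...) {
  cat("<cn_linkcover> ", x$n_communities, " communities, partition density ",
      signif(x$partition_density, 6), ", overlap score ",
      signif(mean(lengths(x$node_memberships)), 6), "\n", sep = "")
  invisible(x)
}

#' Direct evaluation of partition density
#'
#' @param g a `cn_network`.
#' @param edge_labels integer community label per edge (row order of
#'   `g$edges`).
#' @return the partition density D of that edge partition.
#' @export
partition_density <- function(g, edge_labels) {
  stopifnot(length(edge_labels) == n_edges(g))
  m <- n_edges(g)
  labs <- unique(edge_labels)
  contrib <- vapply(labs, function(cc) {
    rows <- g$edges[edge_labels == cc, , drop = FALSE]
    mc <- nrow(rows)
    nc <- length(unique(c(rows)))
    if (nc <= 2) return(0)
    mc * (mc - (nc - 1)) / ((nc - 2) * (nc - 1))
  }, numeric(1))
  2 * sum(contrib) / m
}

#' Community overlap score
#'
#' The mean number of link communities each node belongs to (at least 1 on
#' graphs without isolated nodes; exactly 1 when the cover has one community
#' per connected component).
#'
#' @param g a `cn_network` or a precomputed `cn_linkcover`.
#' @return the overlap score (mean memberships per node).
#' @export
overlap_score <- function(g) {
  cover <- if (inherits(g, "cn_linkcover")) g else link_community_cover(g)
  mean(lengths(cover$node_memberships))
}

#' Null-normalized overlap score
#'
#' Divides the raw overlap score by the mean overlap score of `n_null`
#' degree-preserving random rewirings, so that 1 means "no more overlap than
#' expected from the degree sequence alone".
#'
#' @param g a `cn_network`.
#' @param n_null number of null networks (10 is the conventional default for
#'   score normalization).
#' @param seed optional integer for reproducible nulls.
#' @param null_spec a [null_spec()] controlling the rewiring (kind is forced
#'   to `"random"`).
#' @param M_ref reference module count for the segregated-structure check;
#'   defaults to the Louvain community count of `g`.
#' @return an object of class `cn_overlap`: list with `overlap_score`,
#'   `normalized_overlap`, `null_mean`, `n_overlapping_communities`,
#'   `maintains_segregation`, `M_ref`.
#' @export
normalized_overlap_score <- function(g, n_null = 10, seed = NULL,
                                     null_spec = NULL, M_ref = NULL) {
  stopifnot(n_null >= 1)
  if (is.null(null_spec)) null_spec <- commarch::null_spec()
  null_spec$kind <- "random"
  cover <- link_community_cover(g)
  raw <- mean(lengths(cover$node_memberships))
  run <- function() {
    nulls <- numeric(n_null)
    for (i in seq_len(n_null)) {
      gn <- randomize_degree_preserving(g, null_spec)
      nulls[i] <- overlap_score(gn)
    }
    nulls
  }
  nulls <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  if (is.null(M_ref)) {
    M_ref <- louvain_partition(g, seed = if (is.null(seed)) NULL else seed + 1L
                               )$n_communities
  }
  structure(list(overlap_score = raw,
                 normalized_overlap = raw / mean(nulls),
                 null_mean = mean(nulls),
                 n_overlapping_communities = cover$n_communities,
                 maintains_segregation =
                   maintains_segregated_structure(cover, M_ref),
                 M_ref = M_ref),
            class = "cn_overlap")
}

#' @export
print.cn_overlap <- function(x, ...) {
  cat("<cn_overlap> raw ", signif(x$overlap_score, 6), ", normalized ",
      signif(x$normalized_overlap, 6), " (null mean ",
      signif(x$null_mean, 6), "), ", x$n_overlapping_communities,
      " communities; maintains segregation (M_ref = ", x$M_ref, "): ",
      x$maintains_segregation, "\n", sep = "")
  invisible(x)
}

#' Does the cover maintain the segregated community structure?
#'
#' TRUE when the number of overlapping communities is at least the reference
#' number of non-overlapping modules (planted module count, or the Louvain
#' community count when no planted truth exists). The comparison is
#' inclusive.
#'
#' @param cover a `cn_linkcover`.
#' @param M_ref reference module count (>= 1).
#' @return logical.
#' @export
maintains_segregated_structure <- function(cover, M_ref) {
  stopifnot(M_ref >= 1)
  n <- if (inherits(cover, "cn_linkcover")) cover$n_communities else cover
  n >= M_ref
}
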