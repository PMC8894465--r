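#' Newman-Girvan modularity of a node partition
#'
#' Direct evaluation of
#' \deqn{Q = \sum_c \left[ \frac{L_c}{m} - \gamma \left(\frac{d_c}{2m}\right)^2 \right]}
#' where \eqn{L_c} is the number of edges inside community \eqn{c},
#' \eqn{d_c} the summed degree of its nodes, \eqn{m} the edge count and
#' \eqn{\gamma} the resolution parameter.
#'
#' @param g a `cn_network` with at least one edge.
#' @param membership community labels, one per roster node (named vectors are
#'   matched by name).
#' @param gamma resolution parameter (1 = classic modularity).
#' @return the modularity Q (dimensionless, at most 1).
#' @export
modularity_q <- function(g, membership, gamma = 1) {
  m <- n_edges(g)
  if (m < 1) stop("modularity undefined for a graph with no edges")
  if (!is.null(names(membership))) {
    if (!all(g$nodes %in% names(membership))) {
      stop("membership is missing nodes: ",
           paste(setdiff(g$nodes, names(membership)), collapse = ", "))
    }
    membership <- membership[g$nodes]
  } else if (length(membership) != n_nodes(g)) {
    stop("membership must assign every node")
  }
  lab <- as.integer(factor(membership))
  deg <- tabulate(c(g$edges), nbins = n_nodes(g))
  within <- lab[g$edges[, 1]] == lab[g$edges[, 2]]
  L_c <- tabulate(lab[g$edges[, 1]][within], nbins = max(lab))
  d_c <- vapply(seq_len(max(lab)), function(cc) sum(deg[lab == cc]), numeric(1))
  sum(L_c / m - gamma * (d_c / (2 * m))^2)
}

#' Louvain partition into non-overlapping communities
#'
#' Greedy two-phase Louvain modularity maximization with seeded restarts; the
#' best-Q partition over `n_runs` runs is returned. Q is re-evaluated with
#' [modularity_q()] so the reported value always matches the direct formula.
#' Isolated nodes become singleton communities.
#'
#' @param g a `cn_network` with at least one edge.
#' @param gamma resolution parameter.
#' @param n_runs number of restarts (the algorithm is stochastic).
#' @param seed optional integer; when given, the result is a deterministic
#'   function of `(seed, n_runs)` and the caller's RNG state is untouched.
#' @return an object of class `cn_partition`: list with `membership` (named
#'   integer vector), `Q`, `gamma`, `n_communities`.
#' @export
louvain_partition <- function(g, gamma = 1, n_runs = 10, seed = NULL) {
  if (n_edges(g) < 1) stop("modularity undefined for a graph with no edges")
  stopifnot(n_runs >= 1)
  run <- function() {
    best <- NULL
    best_q <- -Inf
    ig <- as_igraph(g)
    for (r in seq_len(n_runs)) {
      cl <- igraph::cluster_louvain(ig, resolution = gamma)
      mem <- igraph::membership(cl)
      q <- modularity_q(g, as.integer(mem), gamma)
      if (q > best_q) {
        best_q <- q
        best <- as.integer(mem)
      }
    }
    names(best) <- g$nodes
    structure(list(membership = best, Q = best_q, gamma = gamma,
                   n_communities = length(unique(best))),
              class = "cn_partition")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.cn_partition <- function(x, ...) {
  cat("<cn_partition> Q = ", signif(x$Q, 6), " (gamma = ", x$gamma, "), ",
      x$n_communities, " communities\n", sep = "")
  invisible(x)
}

#' Community segregation score
#'
#' The modularity index Q of the best Louvain partition at resolution
#' `gamma = 1`: how cleanly the network separates into non-overlapping
#' communities.
#'
#' @inheritParams louvain_partition
#' @return the segregation score (modularity Q).
#' @export
segregation_score <- function(g, n_runs = 10, seed = NULL) {
  louvain_partition(g, gamma = 1, n_runs = n_runs, seed = seed)$Q
}
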