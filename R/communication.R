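#' Global efficiency
#'
#' Mean inverse shortest-path length over ordered node pairs (disconnected
#' pairs contribute 0); 1 exactly for a complete graph. A routing-based
#' communication efficiency measure.
#'
#' @param g a `cn_network` with at least 2 nodes.
#' @return efficiency in \[0, 1\].
#' @export
global_efficiency <- function(g) {
  n <- n_nodes(g)
  stopifnot(n >= 2)
  if (n_edges(g) == 0) return(0)
  D <- igraph::distances(as_igraph(g))
  inv <- 1 / D
  diag(inv) <- 0
  inv[is.infinite(D)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Local efficiency
#'
#' Mean over nodes of the global efficiency of the subgraph induced on the
#' node's neighbors; nodes of degree < 2 contribute 0 (Latora-Marchiori
#' convention). A routing-based measure of fault tolerance / local
#' communication.
#'
#' @param g a `cn_network`.
#' @return efficiency in \[0, 1\].
#' @export
local_efficiency <- function(g) {
  n <- n_nodes(g)
  stopifnot(n >= 1)
  A <- adjacency(g)
  vals <- vapply(seq_len(n), function(v) {
    nb <- which(A[v, ])
    if (length(nb) < 2) return(0)
    eff_from_adj(A[nb, nb, drop = FALSE])
  }, numeric(1))
  mean(vals)
}

# global efficiency from a logical adjacency matrix (small graphs; BFS by
# boolean matrix powers)
eff_from_adj <- function(A) {
  k <- nrow(A)
  if (k < 2) return(0)
  D <- matrix(Inf, k, k)
  diag(D) <- 0
  reach <- A
  d <- 1
  repeat {
    newly <- reach & is.infinite(D)
    if (!any(newly)) break
    D[newly] <- d
    d <- d + 1
    reach <- (reach %*% A) > 0
    if (d > k) break
  }
  inv <- 1 / D
  diag(inv) <- 0
  sum(inv) / (k * (k - 1))
}

#' Linear threshold diffusion to a steady state
#'
#' Synchronous monotone diffusion: each active node exerts influence
#' `1/degree(v)` on a neighbor `v` (receiver-degree weighting, so each
#' node's incoming weights sum to 1), and an inactive node activates once
#' the summed influence of its active neighbors reaches `theta`
#' (`>= theta` by default; set `strict_threshold` for `>`). Activation is
#' permanent; rounds repeat until no node changes (the steady state).
#'
#' @param g a `cn_network`.
#' @param seeds non-empty vector of seed node labels.
#' @param theta threshold in \[0, 1\].
#' @param strict_threshold require influence strictly greater than `theta`.
#' @return an object of class `cn_diffusion`: list with `seed_set`,
#'   `threshold`, `activated_final` (labels), `activated_ratio`, `n_rounds`.
#' @export
linear_threshold <- function(g, seeds, theta, strict_threshold = FALSE) {
  stopifnot(theta >= 0, theta <= 1, length(seeds) > 0)
  idx <- match(as.character(seeds), g$nodes)
  if (anyNA(idx)) stop("unknown seed node label")
  n <- n_nodes(g)
  A <- adjacency(g) * 1
  deg <- rowSums(A)
  active <- logical(n)
  active[idx] <- TRUE
  rounds <- 0L
  repeat {
    infl <- as.vector(A %*% active)
    infl <- ifelse(deg > 0, infl / deg, 0)
    hit <- if (strict_threshold) infl > theta else infl >= theta
    newly <- hit & !active
    if (!any(newly)) break
    active[newly] <- TRUE
    rounds <- rounds + 1L
  }
  structure(list(seed_set = g$nodes[idx],
                 threshold = theta,
                 activated_final = g$nodes[active],
                 activated_ratio = mean(active),
                 n_rounds = rounds),
            class = "cn_diffusion")
}

#' Mean activated-node ratio at steady state
#'
#' Diffusion-based communication efficiency: the steady-state activated
#' fraction of [linear_threshold()], averaged over `n_rep` uniformly random
#' seed sets of size `round(seed_fraction * N)`. The conventional settings
#' are `theta = 0.5` with seed fractions between 5% and 50% (32% for
#' trajectory readouts).
#'
#' @param g a `cn_network`.
#' @param seed_fraction fraction of nodes seeded, in (0, 1].
#' @param theta activation threshold.
#' @param n_rep number of random seed-set draws.
#' @param seed optional integer for reproducibility.
#' @param strict_threshold see [linear_threshold()].
#' @return mean activated ratio in \[0, 1\].
#' @export
activated_ratio <- function(g, seed_fraction, theta = 0.5, n_rep = 20,
                            seed = NULL, strict_threshold = FALSE) {
  stopifnot(seed_fraction > 0, seed_fraction <= 1, n_rep >= 1)
  n <- n_nodes(g)
  k <- round_half_up(seed_fraction * n)
  run <- function() {
    mean(vapply(seq_len(n_rep), function(r) {
      s <- sample(g$nodes, k)
      linear_threshold(g, s, theta, strict_threshold)$activated_ratio
    }, numeric(1)))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
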