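#' Planted-partition modular network
#'
#' Equal-size modules; every within-module pair becomes an edge independently
#' with probability `p_in`, every between-module pair with `p_out`. With
#' `p_in = p_out` the model reduces to an Erdos-Renyi graph.
#'
#' @param N node count (divisible by `M`).
#' @param M module count.
#' @param p_in,p_out within-/between-module edge probabilities
#'   (`0 <= p_out <= p_in <= 1`).
#' @param seed optional integer for reproducibility.
#' @return a `cn_network` with an attribute `"planted"` holding the module
#'   assignment.
#' @export
generate_modular <- function(N, M, p_in, p_out, seed = NULL) {
  if (N %% M != 0) stop("N must be divisible by M")
  stopifnot(p_out >= 0, p_in >= p_out, p_in <= 1)
  run <- function() {
    mem <- rep(seq_len(M), each = N / M)
    ut <- which(upper.tri(matrix(0, N, N)), arr.ind = TRUE)
    p <- ifelse(mem[ut[, 1]] == mem[ut[, 2]], p_in, p_out)
    sel <- stats::runif(nrow(ut)) < p
    g <- new_network(as.character(seq_len(N)), ut[sel, , drop = FALSE])
    attr(g, "planted") <- stats::setNames(mem, g$nodes)
    g
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Erdos-Renyi random network with a target mean degree
#'
#' G(N, p) with `p = mean_degree / (N - 1)` and no self-loops; e.g.
#' `N = 164, mean_degree = 16` gives density about 10%.
#'
#' @param N node count.
#' @param mean_degree target average degree in `[0, N - 1]`.
#' @param seed optional integer.
#' @param connected when TRUE, redraw (up to 100 times) until the graph is
#'   connected; useful for seeding evolution models that require
#'   connectivity.
#' @return a `cn_network`.
#' @export
generate_er <- function(N, mean_degree, seed = NULL, connected = FALSE) {
  stopifnot(mean_degree >= 0, mean_degree <= N - 1)
  p <- mean_degree / (N - 1)
  run <- function() {
    for (try in 1:100) {
      ut <- which(upper.tri(matrix(0, N, N)), arr.ind = TRUE)
      sel <- stats::runif(nrow(ut)) < p
      g <- new_network(as.character(seq_len(N)), ut[sel, , drop = FALSE])
      if (!connected || is_connected_net(g)) return(g)
    }
    stop("could not draw a connected graph in 100 attempts")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Segregation-vs-overlap architecture sweep
#'
#' Over a grid of `(p_in, p_out)`, generates planted-partition networks,
#' scores segregation (Louvain modularity) and overlap (mean link-community
#' memberships), and averages over replicates. The classic full grid is
#' `p_in` from 0.7 to 1 in steps of 0.02 and `p_out` from 0.01 to 0.35 in
#' steps of 0.02, over configurations (N, M) = (100, 5), (200, 5), (300, 5),
#' (120, 4), (120, 6), (120, 8), (120, 10); any sub-grid works. Disconnected
#' draws are scored on their largest component (counted in
#' `n_disconnected`).
#'
#' @param N,M network size and module count (N divisible by M).
#' @param p_in_grid,p_out_grid numeric probability grids.
#' @param replicates networks generated per grid point.
#' @param seed optional integer; the whole sweep is reproducible.
#' @param n_runs Louvain restarts per network.
#' @param rescale_overlap also report overlap rescaled over the maximum mean
#'   overlap in the sweep (the per-configuration rescaling used when
#'   comparing configurations).
#' @return a data.frame with one row per grid point: `p_in`, `p_out`,
#'   `segregation`, `overlap`, `n_communities`, `maintains_segregation`
#'   (fraction of replicates with at least M overlapping communities),
#'   `n_disconnected`, and `overlap_rescaled` if requested.
#' @export
sweep_architecture <- function(N, M, p_in_grid, p_out_grid, replicates = 5,
                               seed = NULL, n_runs = 10,
                               rescale_overlap = TRUE) {
  stopifnot(length(p_in_grid) > 0, length(p_out_grid) > 0, replicates >= 1)
  grid <- expand.grid(p_in = p_in_grid, p_out = p_out_grid,
                      KEEP.OUT.ATTRS = FALSE)
  run <- function() {
    out <- lapply(seq_len(nrow(grid)), function(i) {
      seg <- ov <- nc <- numeric(replicates)
      keep <- logical(replicates)
      ndis <- 0L
      for (r in seq_len(replicates)) {
        g <- generate_modular(N, M, grid$p_in[i], grid$p_out[i])
        if (!is_connected_net(g)) {
          ndis <- ndis + 1L
          g <- largest_component(g)
        }
        seg[r] <- segregation_score(g, n_runs = n_runs)
        cover <- link_community_cover(g)
        ov[r] <- overlap_score(cover)
        nc[r] <- cover$n_communities
        keep[r] <- maintains_segregated_structure(cover, M)
      }
      data.frame(p_in = grid$p_in[i], p_out = grid$p_out[i],
                 segregation = mean(seg), overlap = mean(ov),
                 n_communities = mean(nc),
                 maintains_segregation = mean(keep),
                 n_disconnected = ndis)
    })
    do.call(rbind, out)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  if (rescale_overlap) res$overlap_rescaled <- res$overlap / max(res$overlap)
  class(res) <- c("cn_sweep", "data.frame")
  res
}
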