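#' Topological overlap of a node pair
#'
#' The number of common neighbors of `i` and `j` — the neighborhood
#' similarity driving the topological reinforcement rewiring rule.
#'
#' @param g a `cn_network`.
#' @param i,j node labels, `i != j`.
#' @return integer count of common neighbors.
#' @export
topological_overlap <- function(g, i, j) {
  ii <- match(as.character(i), g$nodes)
  jj <- match(as.character(j), g$nodes)
  if (anyNA(c(ii, jj))) stop("unknown node label")
  if (ii == jj) stop("i and j must differ")
  A <- adjacency(g)
  sum(A[ii, ] & A[jj, ])
}

# connectivity of a logical adjacency matrix (all nodes)
adj_connected <- function(A) {
  n <- nrow(A)
  if (n == 0) return(TRUE)
  seen <- logical(n)
  seen[1] <- TRUE
  frontier <- 1L
  while (length(frontier) > 0) {
    nxt <- which(colSums(A[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

#' One topological reinforcement rewiring step
#'
#' Mimics Hebbian-like activity-dependent rewiring: (1) sample `floor(N/2)`
#' nodes that are neither disconnected nor fully connected (degree not in
#' \{0, N-1\}); (2) for each, add one link to the non-neighbor with the
#' highest topological overlap, all proposals scored against the pre-step
#' graph and inserted simultaneously (duplicate proposals collapse, ties
#' broken uniformly at random); (3) delete uniformly at random exactly as
#' many links as were added, resampling any deletion that would disconnect
#' the graph (retry budget 100 per deletion). Node count and link density
#' are exactly conserved.
#'
#' @param g a connected `cn_network`.
#' @param seed optional integer.
#' @return the rewired `cn_network`.
#' @export
tr_step <- function(g, seed = NULL) {
  run <- function() tr_step_impl(g)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

tr_step_impl <- function(g) {
  n <- n_nodes(g)
  A <- adjacency(g)
  deg <- rowSums(A)
  eligible <- which(deg > 0 & deg < n - 1)
  if (length(eligible) == 0) {
    warning("no eligible nodes; network returned unchanged")
    return(g)
  }
  k <- min(floor(n / 2), length(eligible))
  sel <- if (length(eligible) == 1) eligible else sample(eligible, k)
  Tov <- crossprod(A * 1)  # common-neighbor counts on the pre-step graph
  props <- matrix(integer(0), ncol = 2)
  for (u in sel) {
    cand <- which(!A[u, ])
    cand <- cand[cand != u]
    sc <- Tov[u, cand]
    best <- cand[sc == max(sc)]
    v <- if (length(best) == 1) best else sample(best, 1)
    props <- rbind(props, c(min(u, v), max(u, v)))
  }
  props <- unique(props)
  added <- 0L
  for (r in seq_len(nrow(props))) {
    if (!A[props[r, 1], props[r, 2]]) {
      A[props[r, 1], props[r, 2]] <- TRUE
      A[props[r, 2], props[r, 1]] <- TRUE
      added <- added + 1L
    }
  }
  if (added > 0) {
    budget <- 100L * added
    deleted <- 0L
    while (deleted < added) {
      ut <- which(upper.tri(A) & A, arr.ind = TRUE)
      e <- ut[sample.int(nrow(ut), 1), ]
      A[e[1], e[2]] <- FALSE
      A[e[2], e[1]] <- FALSE
      # an edge whose endpoints share a neighbor is never a bridge
      safe <- sum(A[e[1], ] & A[e[2], ]) > 0 || adj_connected(A)
      if (safe) {
        deleted <- deleted + 1L
      } else {
        A[e[1], e[2]] <- TRUE
        A[e[2], e[1]] <- TRUE
        budget <- budget - 1L
        if (budget <= 0) stop("deletion retry budget exhausted")
      }
    }
  }
  network_from_adjacency(A, g$nodes)
}

#' Evolve a network by topological reinforcement
#'
#' Applies [tr_step()] repeatedly (60 steps is the conventional depth for
#' modularity emergence at N = 164, mean degree 16), recording a metric
#' bundle at step 0 and after every step. Density and node count are
#' conserved along the whole trajectory and connectivity is maintained.
#'
#' @param g0 a connected `cn_network`.
#' @param n_steps number of rewiring steps.
#' @param seed optional integer making the trajectory reproducible.
#' @param metrics character subset of `"segregation"`, `"overlap"`,
#'   `"global_eff"`, `"local_eff"`, `"activated_ratio"` to record each step.
#' @param n_runs Louvain restarts for the segregation score.
#' @param lt_seed_fraction,lt_theta,lt_reps linear-threshold settings for the
#'   activated-node ratio (32% seeds, threshold 0.5 by convention).
#' @return an object of class `cn_trajectory`: list with `metrics` (one row
#'   per step: `step`, `n_edges`, `density`, requested metrics), `final`
#'   (the final network), `config`.
#' @export
tr_evolve <- function(g0, n_steps = 60, seed = NULL,
                      metrics = c("segregation", "overlap", "global_eff",
                                  "local_eff", "activated_ratio"),
                      n_runs = 10, lt_seed_fraction = 0.32, lt_theta = 0.5,
                      lt_reps = 20) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  stopifnot(n_steps >= 0)
  measure <- function(g) {
    row <- list(n_edges = n_edges(g), density = edge_density(g))
    if ("segregation" %in% metrics) {
      row$segregation <- segregation_score(g, n_runs = n_runs)
    }
    if ("overlap" %in% metrics) row$overlap <- overlap_score(g)
    if ("global_eff" %in% metrics) row$global_eff <- global_efficiency(g)
    if ("local_eff" %in% metrics) row$local_eff <- local_efficiency(g)
    if ("activated_ratio" %in% metrics) {
      row$activated_ratio <- activated_ratio(g, lt_seed_fraction, lt_theta,
                                             n_rep = lt_reps)
    }
    row
  }
  run <- function() {
    g <- g0
    rows <- vector("list", n_steps + 1)
    rows[[1]] <- c(step = 0, measure(g))
    for (s in seq_len(n_steps)) {
      g <- tr_step_impl(g)
      rows[[s + 1]] <- c(step = s, measure(g))
    }
    list(metrics = do.call(rbind, lapply(rows, as.data.frame)), final = g)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(list(metrics = res$metrics, final = res$final,
                 config = list(n_steps = n_steps, seed = seed,
                               metrics = metrics, n_runs = n_runs,
                               lt_seed_fraction = lt_seed_fraction,
                               lt_theta = lt_theta, lt_reps = lt_reps)),
            class = "cn_trajectory")
}

#' Ensemble of topological reinforcement trajectories
#'
#' Evolves `n_networks` independent Erdos-Renyi starts (50 evolving networks
#' of N = 164, mean degree 16 is the conventional ensemble) and averages the
#' per-step metrics across the ensemble.
#'
#' @param n_networks ensemble size.
#' @param N,mean_degree Erdos-Renyi start parameters (draws are conditioned
#'   on connectivity).
#' @param n_steps rewiring steps per trajectory.
#' @param seed optional integer; sub-seeds for each trajectory are drawn from
#'   it.
#' @param ... passed to [tr_evolve()] (`metrics`, linear-threshold settings,
#'   ...).
#' @return an object of class `cn_trensemble`: list with `mean` (per-step
#'   ensemble-averaged metrics) and `trajectories`.
#' @export
tr_ensemble <- function(n_networks = 50, N = 164, mean_degree = 16,
                        n_steps = 60, seed = NULL, ...) {
  stopifnot(n_networks >= 1)
  seeds <- draw_subseeds(n_networks * 2, seed)
  trajs <- vector("list", n_networks)
  for (i in seq_len(n_networks)) {
    g0 <- generate_er(N, mean_degree, seed = seeds[2 * i - 1],
                      connected = TRUE)
    trajs[[i]] <- tr_evolve(g0, n_steps = n_steps, seed = seeds[2 * i], ...)
  }
  stacked <- do.call(rbind, lapply(trajs, `[[`, "metrics"))
  avg <- stats::aggregate(stacked[setdiff(names(stacked), "step")],
                          by = list(step = stacked$step), FUN = mean)
  structure(list(mean = avg, trajectories = trajs), class = "cn_trensemble")
}

# k reproducible sub-seeds below 2^31
draw_subseeds <- function(k, seed = NULL) {
  f <- function() sample.int(.Machine$integer.max, k)
  if (is.null(seed)) f() else withr::with_seed(seed, f())
}
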