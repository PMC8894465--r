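# Graph fixtures (built in code) and independent oracles used across tests.

bowtie_graph <- function() {
  network(rbind(c("a", "b"), c("a", "c"), c("b", "c"), c("c", "d"),
                c("d", "e"), c("d", "f"), c("e", "f")))
}

complete_graph <- function(n, offset = 0) {
  network(t(utils::combn(n, 2)) + offset,
          nodes = as.character(seq_len(n) + offset))
}

path_graph <- function(n) {
  network(cbind(seq_len(n - 1), 2:n), nodes = as.character(seq_len(n)))
}

cycle_graph <- function(n) {
  network(rbind(cbind(seq_len(n - 1), 2:n), c(n, 1)),
          nodes = as.character(seq_len(n)))
}

star_graph <- function(k) {
  network(cbind(1, 2:(k + 1)), nodes = as.character(seq_len(k + 1)))
}

two_cliques <- function(n) {
  network(rbind(t(utils::combn(n, 2)), t(utils::combn(n, 2)) + n),
          nodes = as.character(seq_len(2 * n)))
}

er_fixture <- function(n, p, seed, connected = TRUE) {
  generate_er(n, p * (n - 1), seed = seed, connected = connected)
}

# --- oracle: exhaustive maximum modularity -----------------------------------
# All set partitions of n elements as restricted-growth membership vectors.
all_partitions <- function(n) {
  out <- list()
  grow <- function(mem) {
    i <- length(mem) + 1
    if (i > n) {
      out[[length(out) + 1]] <<- mem
      return(invisible())
    }
    for (lab in seq_len(max(mem, 0) + 1)) grow(c(mem, lab))
  }
  grow(integer(0))
  out
}

max_modularity_oracle <- function(g, gamma = 1) {
  parts <- all_partitions(n_nodes(g))
  best <- -Inf
  best_part <- NULL
  for (p in parts) {
    q <- modularity_q(g, p, gamma)
    if (q > best) {
      best <- q
      best_part <- p
    }
  }
  list(Q = best, membership = best_part)
}

# --- oracle: max partition density over all dendrogram cuts ------------------
# Rebuilds the similarity-thresholded line graph per level with
# edge_similarity() and igraph components, independent of the C++ path.
all_cuts_max_density <- function(g) {
  m <- n_edges(g)
  if (m == 1) return(0)
  pairs <- NULL
  for (k in seq_len(n_nodes(g))) {
    inc <- which(g$edges[, 1] == k | g$edges[, 2] == k)
    if (length(inc) >= 2) {
      for (xy in utils::combn(inc, 2, simplify = FALSE)) {
        e1 <- g$nodes[g$edges[xy[1], ]]
        e2 <- g$nodes[g$edges[xy[2], ]]
        pairs <- rbind(pairs, data.frame(e1 = xy[1], e2 = xy[2],
                                         sim = edge_similarity(g, e1, e2)))
      }
    }
  }
  if (is.null(pairs)) return(0)
  best <- 0  # all-singleton cut
  for (thr in sort(unique(pairs$sim), decreasing = TRUE)) {
    keep <- pairs[pairs$sim >= thr, , drop = FALSE]
    lg <- igraph::make_empty_graph(n = m, directed = FALSE)
    lg <- igraph::add_edges(lg, t(as.matrix(keep[, c("e1", "e2")])))
    labs <- igraph::components(lg)$membership
    best <- max(best, partition_density(g, labs))
  }
  best
}

# --- oracle: asynchronous linear-threshold fixed point -----------------------
# Updates one random inactive node at a time until no node can activate; the
# process is monotone, so the fixed point must equal the synchronous one.
async_lt_oracle <- function(g, seeds, theta) {
  A <- matrix(FALSE, n_nodes(g), n_nodes(g))
  A[g$edges] <- TRUE
  A[g$edges[, c(2, 1), drop = FALSE]] <- TRUE
  deg <- rowSums(A)
  active <- g$nodes %in% seeds
  repeat {
    inactive <- which(!active)
    if (length(inactive) == 0) break
    cand <- sample(inactive)
    fired <- FALSE
    for (v in cand) {
      if (deg[v] > 0 && sum(A[v, ] & active) / deg[v] >= theta) {
        active[v] <- TRUE
        fired <- TRUE
        break
      }
    }
    if (!fired) break
  }
  sort(g$nodes[active])
}

# --- oracle: Welch t statistic by direct formula -----------------------------
welch_t_oracle <- function(x, y) {
  (mean(x) - mean(y)) / sqrt(var(x) / length(x) + var(y) / length(y))
}

# --- oracle: Pearson r by direct formula -------------------------------------
pearson_oracle <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}
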