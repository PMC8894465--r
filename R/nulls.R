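#' Null-model specification
#'
#' @param kind `"random"` (degree-preserving randomization) or `"lattice"`
#'   (degree-preserving latticization toward a ring ordering).
#' @param swap_iterations_per_edge attempted double-edge swaps per edge
#'   (default 10, the common rewiring depth).
#' @param require_connected reject swaps that disconnect the graph (matches
#'   the connectivity-preserving variants of the standard rewiring
#'   functions).
#' @return a list of class `cn_nullspec`.
#' @export
null_spec <- function(kind = c("random", "lattice"),
                      swap_iterations_per_edge = 10,
                      require_connected = TRUE) {
  kind <- match.arg(kind)
  stopifnot(swap_iterations_per_edge >= 0)  # 0 = identity null
  structure(list(kind = kind,
                 swap_iterations_per_edge = swap_iterations_per_edge,
                 require_connected = require_connected),
            class = "cn_nullspec")
}

rewire_net <- function(g, spec, lattice, seed = NULL) {
  if (n_edges(g) < 2) {
    warning("fewer than 2 edges; returned unchanged")
    return(g)
  }
  attempts <- spec$swap_iterations_per_edge * n_edges(g)
  run <- function() {
    rewire_cpp(g$edges, n_nodes(g), attempts, lattice, spec$require_connected)
  }
  em <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  em <- em[order(em[, 1], em[, 2]), , drop = FALSE]
  new_network(g$nodes, em)
}

#' Degree-preserving randomized null network
#'
#' Double-edge-swap rewiring: `swap_iterations_per_edge * m` attempted swaps,
#' rejecting any swap that would create a self-loop or multi-edge, and (when
#' `require_connected`) any swap that disconnects the graph. The degree
#' sequence of the output is exactly that of the input. With 0 valid swaps
#' (e.g. a star) the input is returned unchanged.
#'
#' @param g a `cn_network` (connected if `spec$require_connected`).
#' @param spec a [null_spec()].
#' @param seed optional integer for reproducibility.
#' @return a rewired `cn_network` on the same roster.
#' @export
randomize_degree_preserving <- function(g, spec = null_spec(), seed = NULL) {
  rewire_net(g, spec, lattice = FALSE, seed = seed)
}

#' Degree-preserving latticized null network
#'
#' As [randomize_degree_preserving()], but a valid swap is additionally
#' accepted only when it does not increase the total ring distance
#' `sum(min(|i - j|, N - |i - j|))` of the swapped edges under the fixed
#' circular ordering of the node roster, pulling edges toward a lattice-like
#' arrangement.
#'
#' @inheritParams randomize_degree_preserving
#' @return a latticized `cn_network` on the same roster.
#' @export
latticize <- function(g, spec = null_spec(kind = "lattice"), seed = NULL) {
  rewire_net(g, spec, lattice = TRUE, seed = seed)
}

# total ring-distance cost of the edge set (latticization objective)
ring_cost <- function(g) {
  n <- n_nodes(g)
  d <- abs(g$edges[, 1] - g$edges[, 2])
  sum(pmin(d, n - d))
}
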