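#' Construct an undirected simple network
#'
#' The basic container used throughout the package: an undirected, unweighted
#' simple graph with an explicit node roster. Self-loops are forbidden,
#' duplicate and reversed-duplicate edges collapse to one, and the roster may
#' contain isolated nodes (nodes that appear in no edge), which matters for
#' overlap scoring where every node must receive at least one community
#' membership.
#'
#' @param edges two-column matrix or data.frame of node labels (or indices
#'   into `nodes`), one edge per row; may have zero rows.
#' @param nodes optional character vector of node labels fixing the roster and
#'   its order; defaults to the labels appearing in `edges`.
#' @return An object of class `cn_network` with elements `nodes` (character)
#'   and `edges` (m x 2 integer matrix of roster indices, each row `i < j`,
#'   rows in lexicographic order).
#' @export
network <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges) || (is.matrix(edges) && nrow(edges) == 0) ||
      (is.data.frame(edges) && nrow(edges) == 0)) {
    edges <- matrix(integer(0), ncol = 2)
    if (is.null(nodes)) nodes <- character(0)
    return(new_network(as.character(nodes), edges))
  }
  edges <- as.matrix(edges)
  if (ncol(edges) < 2) stop("edges must have two columns")
  edges <- edges[, 1:2, drop = FALSE]
  a <- as.character(edges[, 1])
  b <- as.character(edges[, 2])
  keep <- a != b
  if (any(!keep)) warning(sum(!keep), " self-loop(s) dropped")
  a <- a[keep]
  b <- b[keep]
  if (is.null(nodes)) {
    nodes <- unique(c(rbind(a, b)))
  } else {
    nodes <- as.character(nodes)
    if (!all(c(a, b) %in% nodes)) stop("edge endpoint not in node roster")
  }
  ia <- match(a, nodes)
  ib <- match(b, nodes)
  ia2 <- pmin(ia, ib)
  ib2 <- pmax(ia, ib)
  key <- (ia2 - 1) * length(nodes) + ib2
  dup <- duplicated(key)
  new_network(nodes, cbind(ia2[!dup], ib2[!dup]))
}

# canonical form: each row i < j, rows sorted lexicographically
new_network <- function(nodes, edge_idx) {
  storage.mode(edge_idx) <- "integer"
  dimnames(edge_idx) <- NULL
  if (nrow(edge_idx) > 1) {
    edge_idx <- edge_idx[order(edge_idx[, 1], edge_idx[, 2]), , drop = FALSE]
  }
  structure(list(nodes = nodes, edges = edge_idx), class = "cn_network")
}

#' @export
print.cn_network <- function(x, ...) {
  cat("<cn_network> ", n_nodes(x), " nodes, ", n_edges(x),
      " edges, density ", signif(edge_density(x), 4), "\n", sep = "")
  invisible(x)
}

#' Node and edge counts, density, degrees
#'
#' @param g a `cn_network`.
#' @return `n_nodes`/`n_edges` return integers; `edge_density` returns
#'   \eqn{2m / (N(N-1))}; `degrees` a named integer vector over the roster.
#' @export
n_nodes <- function(g) length(g$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(g) nrow(g$edges)

#' @rdname n_nodes
#' @export
edge_density <- function(g) {
  n <- n_nodes(g)
  if (n < 2) return(0)
  2 * n_edges(g) / (n * (n - 1))
}

#' @rdname n_nodes
#' @export
degrees <- function(g) {
  d <- tabulate(c(g$edges), nbins = n_nodes(g))
  names(d) <- g$nodes
  d
}

# logical adjacency matrix (roster order)
adjacency <- function(g) {
  n <- n_nodes(g)
  A <- matrix(FALSE, n, n)
  if (n_edges(g) > 0) {
    A[g$edges] <- TRUE
    A[g$edges[, c(2, 1), drop = FALSE]] <- TRUE
  }
  dimnames(A) <- list(g$nodes, g$nodes)
  A
}

#' Convert to an igraph object
#'
#' @param g a `cn_network`.
#' @return an `igraph` graph with vertex names from the roster (isolated
#'   nodes included).
#' @export
as_igraph <- function(g) {
  ig <- igraph::make_empty_graph(n = n_nodes(g), directed = FALSE)
  ig <- igraph::set_vertex_attr(ig, "name", value = g$nodes)
  if (n_edges(g) > 0) ig <- igraph::add_edges(ig, t(g$edges))
  ig
}

# network from a 0/1 (or logical) adjacency matrix with dimnames
network_from_adjacency <- function(A, nodes = NULL) {
  if (is.null(nodes)) nodes <- rownames(A)
  if (is.null(nodes)) nodes <- as.character(seq_len(nrow(A)))
  idx <- which(upper.tri(A) & A != 0, arr.ind = TRUE)
  new_network(nodes, idx[order(idx[, 1], idx[, 2]), , drop = FALSE])
}

#' Read a network from a plain-text edge list
#'
#' One edge per line as two (or more; extras ignored) whitespace-separated
#' node labels. `#` starts a comment. Duplicate lines and reversed duplicates
#' collapse to a single edge; self-loop lines are dropped with a warning.
#'
#' @param path file path.
#' @return a `cn_network`.
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  keep <- grepl("\\S", lines)
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  lineno <- which(keep)
  bad <- lengths(toks) < 2
  if (any(bad)) {
    stop("malformed edge-list line ", lineno[which(bad)[1]],
         ": expected at least 2 tokens")
  }
  if (length(toks) == 0) return(network())
  em <- t(vapply(toks, function(x) x[1:2], character(2)))
  network(em)
}

#' Write a network as a plain-text edge list
#'
#' @param g a `cn_network`.
#' @param path output file path.
#' @export
write_edge_list <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (n_edges(g) > 0) {
    writeLines(paste(g$nodes[g$edges[, 1]], g$nodes[g$edges[, 2]]), con)
  }
  invisible(path)
}

#' Read a (weighted) network from a square delimited adjacency matrix
#'
#' Expects a header row of node labels and a square numeric body; the matrix
#' must be symmetric with zero diagonal. Nonzero entries become edges
#' (`weighted = FALSE`) or weights (`weighted = TRUE`).
#'
#' @param path file path.
#' @param weighted return a `cn_weighted` instead of a binary `cn_network`.
#' @param sep field separator passed to [utils::read.table()].
#' @return a `cn_network` or `cn_weighted`.
#' @export
read_adjacency <- function(path, weighted = FALSE, sep = "") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE)
  A <- as.matrix(tab)
  if (nrow(A) != ncol(A)) stop("adjacency matrix is not square")
  nodes <- colnames(A)
  rownames(A) <- nodes
  if (max(abs(A - t(A))) > 1e-8) stop("adjacency matrix is not symmetric")
  if (any(diag(A) != 0)) stop("adjacency matrix has nonzero diagonal")
  if (weighted) weighted_network(A, nodes) else network_from_adjacency(A, nodes)
}

#' Construct a weighted network
#'
#' @param w square symmetric non-negative matrix with zero diagonal; a zero
#'   weight means the pair is absent.
#' @param nodes optional node labels (defaults to `rownames(w)`).
#' @return an object of class `cn_weighted` with elements `nodes` and `w`.
#' @export
weighted_network <- function(w, nodes = NULL) {
  w <- as.matrix(w)
  if (nrow(w) != ncol(w)) stop("weight matrix must be square")
  if (is.null(nodes)) nodes <- rownames(w)
  if (is.null(nodes)) nodes <- as.character(seq_len(nrow(w)))
  if (max(abs(w - t(w))) > 1e-10) stop("weights must be symmetric")
  if (any(diag(w) != 0)) stop("diagonal must be zero")
  if (any(w < 0)) stop("weights must be non-negative")
  dimnames(w) <- list(nodes, nodes)
  structure(list(nodes = nodes, w = w), class = "cn_weighted")
}

# round half away from zero (base round() rounds half to even)
round_half_up <- function(x) floor(x + 0.5)

#' Threshold a weighted network to a target link density
#'
#' Keeps the `k` strongest-weight pairs where
#' `k = round(density * N(N-1)/2)` (half away from zero), mirroring the
#' common connectome preprocessing step of binarizing streamline-count
#' matrices at a fixed density (10% by default elsewhere in this package).
#' Ties at the cutoff are broken by lexicographic node-pair order so the
#' result is deterministic.
#'
#' @param w a `cn_weighted`.
#' @param density target link density in (0, 1].
#' @return a `cn_network` on the same roster.
#' @export
binarize_to_density <- function(w, density) {
  stopifnot(inherits(w, "cn_weighted"), density > 0, density <= 1)
  n <- length(w$nodes)
  ut <- which(upper.tri(w$w), arr.ind = TRUE)
  wt <- w$w[ut]
  if (all(wt == 0)) stop("all weights are zero")
  k <- round_half_up(density * n * (n - 1) / 2)
  ord <- order(-wt, ut[, 1], ut[, 2])
  pos <- sum(wt > 0)
  if (k > pos) {
    warning("only ", pos, " positive-weight pairs available; keeping all")
    k <- pos
  }
  sel <- ord[seq_len(k)]
  em <- ut[sel, , drop = FALSE]
  new_network(w$nodes, em[order(em[, 1], em[, 2]), , drop = FALSE])
}

#' Group-consensus network
#'
#' Keeps every edge present in at least `presence_threshold` of the supplied
#' networks (inclusive), e.g. 0.75 reproduces the "present in at least 75% of
#' subjects" rule used for group-averaged connectomes.
#'
#' @param graphs list of `cn_network` objects sharing one node roster.
#' @param presence_threshold required presence fraction in (0, 1].
#' @return a `cn_network` on the shared roster.
#' @export
consensus_network <- function(graphs, presence_threshold = 0.75) {
  if (length(graphs) == 0) stop("empty graph list")
  stopifnot(presence_threshold > 0, presence_threshold <= 1)
  nodes <- graphs[[1]]$nodes
  for (g in graphs) {
    if (!identical(g$nodes, nodes)) stop("graphs must share the node roster")
  }
  n <- length(nodes)
  keys <- unlist(lapply(graphs, function(g) {
    (g$edges[, 1] - 1) * n + g$edges[, 2]
  }))
  cnt <- table(keys)
  keep <- as.numeric(names(cnt))[cnt / length(graphs) >= presence_threshold]
  keep <- sort(keep)
  em <- cbind(floor((keep - 1) / n) + 1, (keep - 1) %% n + 1)
  new_network(nodes, em)
}

#' Largest connected component
#'
#' @param g a `cn_network`.
#' @return the `cn_network` induced on the largest component (ties broken
#'   toward the component containing the earliest roster node).
#' @export
largest_component <- function(g) {
  if (n_nodes(g) == 0) return(g)
  comp <- igraph::components(as_igraph(g))
  big <- which.max(comp$csize)
  keep <- which(comp$membership == big)
  subnetwork(g, keep)
}

# induced subgraph on roster indices `keep`
subnetwork <- function(g, keep) {
  keep <- sort(keep)
  sel <- g$edges[, 1] %in% keep & g$edges[, 2] %in% keep
  em <- g$edges[sel, , drop = FALSE]
  em[, 1] <- match(em[, 1], keep)
  em[, 2] <- match(em[, 2], keep)
  new_network(g$nodes[keep], em)
}

is_connected_net <- function(g) {
  n_nodes(g) > 0 && igraph::is_connected(as_igraph(g))
}
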