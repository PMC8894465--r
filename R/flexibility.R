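#' Multivariate time-series panel
#'
#' @param values nodes x time numeric matrix (no missing values).
#' @param sampling_interval seconds between samples (0.72 s is the typical
#'   resting-state fMRI repetition time emulated here).
#' @return an object of class `cn_panel`.
#' @export
time_series_panel <- function(values, sampling_interval) {
  values <- as.matrix(values)
  stopifnot(nrow(values) >= 2, sampling_interval > 0)
  if (anyNA(values)) stop("panel contains missing values")
  structure(list(values = values, sampling_interval = sampling_interval),
            class = "cn_panel")
}

#' Read a panel from a delimited nodes x time matrix
#'
#' @param path file path (no header; one node per row).
#' @param sampling_interval seconds between samples.
#' @param sep field separator.
#' @return a `cn_panel`.
#' @export
read_panel <- function(path, sampling_interval, sep = "") {
  time_series_panel(as.matrix(utils::read.table(path, header = FALSE,
                                                sep = sep)),
                    sampling_interval)
}

#' Number of sliding windows
#'
#' Start positions such that the window lies fully inside the series:
#' `floor((T - window_samples) / step_samples) + 1`. The canonical
#' resting-state case — 4,800 samples at 0.72 s, a 30-s (42-sample) window
#' shifted one sample — gives 4,759 windows.
#'
#' @param T series length in samples.
#' @param window_samples window length in samples (`<= T`).
#' @param step_samples shift between consecutive windows in samples.
#' @return integer window count.
#' @export
window_count <- function(T, window_samples, step_samples = 1) {
  stopifnot(step_samples >= 1)
  if (window_samples > T) stop("window longer than the series")
  floor((T - window_samples) / step_samples) + 1
}

#' Sliding-window functional connectivity
#'
#' Pearson correlation of every node pair within each window, producing an
#' N x N x W tensor of time-varying connectivity. The window length in
#' samples is `round(window_seconds / sampling_interval)` (30 s at 0.72 s
#' sampling = 42 samples). Zero-variance nodes within a window get
#' correlation 0 (count reported via a message).
#'
#' @param ts a `cn_panel`.
#' @param window_seconds window length in seconds (at least 2 samples).
#' @param step_seconds shift between windows in seconds (defaults to one
#'   sampling interval).
#' @return an object of class `cn_dfc`: list with `tensor` (N x N x W),
#'   `window_samples`, `step_samples`, `starts`.
#' @export
sliding_window_fc <- function(ts, window_seconds = 30,
                              step_seconds = ts$sampling_interval) {
  stopifnot(inherits(ts, "cn_panel"),
            window_seconds >= 2 * ts$sampling_interval)
  w <- round_half_up(window_seconds / ts$sampling_interval)
  s <- max(1, round_half_up(step_seconds / ts$sampling_interval))
  Tn <- ncol(ts$values)
  W <- window_count(Tn, w, s)
  n <- nrow(ts$values)
  tensor <- array(NA_real_, c(n, n, W))
  starts <- seq(1, by = s, length.out = W)
  n_degenerate <- 0L
  for (k in seq_len(W)) {
    seg <- t(ts$values[, starts[k]:(starts[k] + w - 1), drop = FALSE])
    sds <- apply(seg, 2, stats::sd)
    cc <- suppressWarnings(stats::cor(seg))
    if (any(sds == 0)) {
      n_degenerate <- n_degenerate + sum(sds == 0)
      cc[is.na(cc)] <- 0
    }
    diag(cc) <- 1
    tensor[, , k] <- cc
  }
  if (n_degenerate > 0) {
    message(n_degenerate, " zero-variance node-window(s); correlations set to 0")
  }
  structure(list(tensor = tensor, window_samples = w, step_samples = s,
                 starts = starts),
            class = "cn_dfc")
}

#' Per-window community labels tracked across windows
#'
#' Runs weighted Louvain (on the positive part of each correlation slice,
#' gamma = 1 by default) in every window, then aligns labels across
#' consecutive windows by a maximum-overlap one-to-one assignment on the
#' community contingency table, so that a label change reflects a genuine
#' change of module allegiance rather than an arbitrary relabeling.
#' Communities with no match receive fresh labels.
#'
#' @param dc a `cn_dfc` with at least 2 windows.
#' @param gamma resolution parameter for the per-window detection.
#' @param seed optional integer.
#' @return integer matrix N x W of matched community labels.
#' @export
dynamic_communities <- function(dc, gamma = 1, seed = NULL) {
  stopifnot(inherits(dc, "cn_dfc"))
  W <- dim(dc$tensor)[3]
  if (W < 2) stop("need at least 2 windows")
  n <- dim(dc$tensor)[1]
  ut <- upper.tri(matrix(0, n, n))
  # one complete base graph, reweighted per window (edge order = column-major
  # upper triangle, matching R's upper.tri indexing)
  el <- which(ut, arr.ind = TRUE)
  el <- el[order(el[, 2], el[, 1]), , drop = FALSE]
  base <- igraph::graph_from_edgelist(el, directed = FALSE)
  run <- function() {
    labels <- matrix(NA_integer_, n, W)
    next_label <- 0L
    for (k in seq_len(W)) {
      w <- pmax(dc$tensor[, , k][ut], 0)
      if (max(w) <= 0) stop("window ", k, " has no positive correlations")
      mem <- as.integer(igraph::membership(
        igraph::cluster_louvain(base, weights = w, resolution = gamma)))
      if (k == 1) {
        labels[, k] <- mem
        next_label <- max(mem)
      } else {
        matched <- match_labels(labels[, k - 1], mem, next_label)
        labels[, k] <- matched$labels
        next_label <- matched$next_label
      }
    }
    labels
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# Align `cur` community labels to `prev` by maximizing total shared nodes
# under a one-to-one assignment. Exact (brute force over injections of the
# smaller side) when the smaller side has <= 7 communities; greedy otherwise.
# Unmatched current communities get fresh labels starting past `next_label`.
match_labels <- function(prev, cur, next_label) {
  tab <- table(prev, cur)
  pl <- as.integer(rownames(tab))
  cl <- as.integer(colnames(tab))
  nr <- length(pl)
  nc <- length(cl)
  assign_cur <- rep(NA_integer_, nc)  # index into pl
  if (min(nr, nc) <= 7) {
    if (nc <= nr) {
      perms <- perm_injections(nr, nc)
      sc <- apply(perms, 1, function(p) sum(tab[cbind(p, seq_len(nc))]))
      assign_cur <- perms[which.max(sc), ]
    } else {
      perms <- perm_injections(nc, nr)  # rows -> cur columns
      sc <- apply(perms, 1, function(p) sum(tab[cbind(seq_len(nr), p)]))
      best <- perms[which.max(sc), ]
      assign_cur[best] <- seq_len(nr)
    }
  } else {
    ord <- order(-tab)
    used_r <- logical(nr)
    used_c <- logical(nc)
    for (o in ord) {
      r <- (o - 1) %% nr + 1
      cc <- (o - 1) %/% nr + 1
      if (!used_r[r] && !used_c[cc] && tab[r, cc] > 0) {
        assign_cur[cc] <- r
        used_r[r] <- TRUE
        used_c[cc] <- TRUE
      }
    }
  }
  out <- integer(length(cur))
  for (ci in seq_len(nc)) {
    if (is.na(assign_cur[ci])) {
      next_label <- next_label + 1L
      out[cur == cl[ci]] <- next_label
    } else {
      out[cur == cl[ci]] <- pl[assign_cur[ci]]
    }
  }
  list(labels = out, next_label = max(next_label, out))
}

# all injections of k targets into 1..n as a (n!/(n-k)!) x k matrix
perm_injections <- function(n, k) {
  if (k == 0) return(matrix(integer(0), 1, 0))
  out <- matrix(seq_len(n), ncol = 1)
  for (j in seq_len(k - 1)) {
    grown <- lapply(seq_len(nrow(out)), function(r) {
      rest <- setdiff(seq_len(n), out[r, ])
      cbind(matrix(out[r, ], length(rest), j, byrow = TRUE), rest)
    })
    out <- do.call(rbind, grown)
  }
  unname(out)
}

#' Dynamic flexibility from tracked community labels
#'
#' Per node, the fraction of consecutive-window transitions in which its
#' matched community label changes; the mean over nodes is the mean dynamic
#' flexibility (the network's dynamic reconfiguration rate).
#'
#' @param labels N x W integer matrix from [dynamic_communities()] (W >= 2).
#' @return an object of class `cn_flexibility`: list with
#'   `per_node_flexibility` (values in \[0, 1\]) and `mean_flexibility`.
#' @export
flexibility <- function(labels) {
  labels <- as.matrix(labels)
  W <- ncol(labels)
  if (W < 2) stop("need at least 2 windows")
  changes <- labels[, -1, drop = FALSE] != labels[, -W, drop = FALSE]
  per_node <- rowMeans(changes)
  structure(list(per_node_flexibility = per_node,
                 mean_flexibility = mean(per_node)),
            class = "cn_flexibility")
}

#' Mean dynamic flexibility of a panel
#'
#' Convenience wrapper: sliding-window connectivity, per-window community
#' detection with cross-window label matching, then [flexibility()].
#'
#' @param ts a `cn_panel`.
#' @param window_seconds,step_seconds see [sliding_window_fc()].
#' @param gamma,seed see [dynamic_communities()].
#' @return a `cn_flexibility`.
#' @export
panel_flexibility <- function(ts, window_seconds = 30,
                              step_seconds = ts$sampling_interval,
                              gamma = 1, seed = NULL) {
  dc <- sliding_window_fc(ts, window_seconds, step_seconds)
  flexibility(dynamic_communities(dc, gamma = gamma, seed = seed))
}
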