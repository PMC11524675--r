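## Whole-brain binary network: threshold the full coherence matrix, then
## strength (mean degree), clustering coefficient and characteristic path
## length per band.

#' Binarize a coherence matrix into a graph
#'
#' An edge connects two channels when their coherence exceeds `threshold`;
#' the diagonal is forced to zero (no self-loops).
#'
#' @param coherence Symmetric channels x channels matrix with values in
#'   [0, 1].
#' @param threshold Binarization threshold (default 0.6).
#' @param band Optional band tag carried on the graph.
#' @return An object of class `binary_graph`: list with `adjacency` (0/1
#'   matrix), `labels`, `band`, `threshold`.
#' @export
binarize <- function(coherence, threshold = 0.6, band = NA_character_) {
  coherence <- as.matrix(coherence)
  if (nrow(coherence) != ncol(coherence) ||
      max(abs(coherence - t(coherence))) > 1e-9) {
    stop("coherence matrix must be symmetric")
  }
  if (min(coherence) < 0 || max(coherence) > 1 + 1e-12) {
    stop("coherence values must lie in [0, 1]")
  }
  adj <- (coherence > threshold) * 1
  diag(adj) <- 0
  labels <- rownames(coherence) %||% paste0("ch", seq_len(nrow(coherence)))
  dimnames(adj) <- list(labels, labels)
  structure(list(adjacency = adj, labels = labels, band = band,
                 threshold = threshold),
            class = "binary_graph")
}

#' Structural indices of a binary graph
#'
#' Mean strength (on a binary graph, the node degree), mean clustering
#' coefficient (local transitivity, 0 for nodes of degree < 2) and
#' characteristic path length L (mean shortest-path hop count over connected
#' node pairs; `NA` for an edgeless graph). When the graph is disconnected, L
#' averages over reachable pairs only and the unreachable fraction is
#' reported.
#'
#' @param g A `binary_graph`.
#' @return List with `strength`, `cc`, `L` and `unreachable_fraction`.
#' @export
graph_metrics <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  n <- nrow(g$adjacency)
  if (n < 2) stop("graph metrics need at least 2 nodes")
  ig <- igraph::graph_from_adjacency_matrix(g$adjacency, mode = "undirected")
  deg <- igraph::degree(ig)
  strength <- mean(deg)
  cc_local <- igraph::transitivity(ig, type = "local", isolates = "zero")
  cc_local[is.na(cc_local)] <- 0
  cc <- mean(cc_local)
  d <- igraph::distances(ig)
  off <- d[upper.tri(d)]
  finite <- is.finite(off)
  if (!any(finite) || sum(g$adjacency) == 0) {
    L <- NA_real_
    unreach <- 1
  } else {
    L <- mean(off[finite])
    unreach <- mean(!finite)
  }
  list(strength = strength, cc = cc, L = L, unreachable_fraction = unreach)
}

#' Per-band network features from full coherence matrices
#'
#' @param coherence_by_band Named list of symmetric coherence matrices (one
#'   per band, as from [coherence_bands()]).
#' @param threshold Binarization threshold (default 0.6).
#' @return Named numeric vector `net:<band>:strength|CC|L` (3 per band). L of
#'   an edgeless band graph is reported as `NA`.
#' @export
network_features <- function(coherence_by_band, threshold = 0.6) {
  out <- numeric(0)
  for (b in names(coherence_by_band)) {
    m <- graph_metrics(binarize(coherence_by_band[[b]], threshold, band = b))
    v <- c(m$strength, m$cc, m$L)
    names(v) <- paste0("net:", b, ":", c("strength", "CC", "L"))
    out <- c(out, v)
  }
  out
}
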