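#' Read a confidence-weighted protein interaction edge list
#'
#' Tab-separated file with header columns `node_a`, `node_b`,
#' `confidence`.  Edges are undirected: node pairs are stored in canonical
#' (sorted) order.  Self-loops and confidences outside [0, 1] are
#' rejected.
#'
#' @param path Path to a TSV edge list.
#' @return data.frame with columns `node_a`, `node_b`, `confidence`.
#' @export
read_edge_list <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("node_a", "node_b", "confidence")
  if (!all(need %in% names(df))) {
    stop("edge list must have columns ", paste(need, collapse = ", "))
  }
  as_edge_list(df[, need])
}

#' Validate and canonicalise an edge list
#'
#' @param edges data.frame with `node_a`, `node_b`, `confidence`.
#' @return The canonicalised edge list.
#' @export
as_edge_list <- function(edges) {
  if (any(edges$node_a == edges$node_b)) {
    stop("self-loop(s) in edge list: ",
         paste(unique(edges$node_a[edges$node_a == edges$node_b]),
               collapse = ", "))
  }
  if (any(edges$confidence < 0 | edges$confidence > 1)) {
    stop("edge confidences must lie in [0, 1]")
  }
  a <- pmin(edges$node_a, edges$node_b)
  b <- pmax(edges$node_a, edges$node_b)
  out <- data.frame(node_a = a, node_b = b,
                    confidence = edges$confidence,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Filter edges by confidence threshold
#'
#' Retains edges with `confidence >= min_confidence` (inclusive, the
#' STRING convention).  Idempotent; a higher threshold always yields a
#' subset.
#'
#' @param edges Edge list data.frame.
#' @param min_confidence Threshold in [0, 1].
#' @return Filtered edge list.
#' @export
filter_edges <- function(edges, min_confidence) {
  if (min_confidence < 0 || min_confidence > 1) {
    stop("min_confidence must lie in [0, 1]")
  }
  out <- edges[edges$confidence >= min_confidence, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cluster network nodes by spectral embedding plus k-means
#'
#' Embeds the confidence-weighted adjacency via the symmetric normalised
#' graph Laplacian (eigenvectors of the `min(k, n - 1)` smallest
#' eigenvalues, rows normalised to unit length) and partitions the
#' embedding with k-means under a fixed seed.  Optionally drops nodes
#' whose mean incident edge confidence falls below
#' `min_node_confidence` before clustering.  Cluster ids are relabelled
#' by first appearance in node order, so results are deterministic for a
#' given seed.
#'
#' @param edges Edge list data.frame.
#' @param k Number of clusters (1 <= k <= number of nodes).
#' @param seed Integer RNG seed for k-means initialisation.
#' @param min_node_confidence Optional per-node mean-incident-confidence
#'   filter applied before clustering.
#' @return Named integer vector mapping each node to a cluster id in 1..k.
#' @export
cluster_nodes <- function(edges, k, seed = 1L, min_node_confidence = NULL) {
  edges <- as_edge_list(edges)
  nodes <- sort(unique(c(edges$node_a, edges$node_b)))
  if (!is.null(min_node_confidence)) {
    mean_conf <- vapply(nodes, function(v) {
      sel <- edges$node_a == v | edges$node_b == v
      mean(edges$confidence[sel])
    }, numeric(1))
    nodes <- nodes[mean_conf >= min_node_confidence]
    edges <- edges[edges$node_a %in% nodes & edges$node_b %in% nodes, ,
                   drop = FALSE]
  }
  n <- length(nodes)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (k > n) stop("k = ", k, " exceeds the number of nodes (", n, ")")
  if (k == 1L) {
    out <- rep(1L, n); names(out) <- nodes; return(out)
  }
  if (k == n) {
    out <- seq_len(n); names(out) <- nodes; return(out)
  }

  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  ia <- match(edges$node_a, nodes)
  ib <- match(edges$node_b, nodes)
  for (e in seq_along(ia)) {
    W[ia[e], ib[e]] <- W[ia[e], ib[e]] + edges$confidence[e]
    W[ib[e], ia[e]] <- W[ib[e], ia[e]] + edges$confidence[e]
  }
  d <- rowSums(W)
  dinv <- ifelse(d > 0, 1 / sqrt(d), 0)
  L <- diag(n) - (dinv %o% dinv) * W
  dims <- min(k, n - 1L)
  ev <- eigen(L, symmetric = TRUE)
  emb <- ev$vectors[, seq.int(n, n - dims + 1L), drop = FALSE]
  len <- sqrt(rowSums(emb^2))
  emb <- emb / ifelse(len > 0, len, 1)
  set.seed(seed)
  km <- stats::kmeans(emb, centers = k, nstart = 25, iter.max = 100)
  ids <- km$cluster
  relabel <- match(ids, unique(ids))
  out <- as.integer(relabel)
  names(out) <- nodes
  out
}
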