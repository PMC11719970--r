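# Sample clustering: cosine-similarity KNN graph, Louvain community
# detection (weighted modularity, via igraph, with the reported modularity
# recomputed independently), and the K = k_min..k_max stabilization scan.
# Used both on raw beta values at selected CpGs and on the multi-class
# network's global-average-pooling embeddings.

#' Cosine-similarity K-nearest-neighbour graph over samples
#'
#' Each sample is linked to its `K` most cosine-similar other samples; the
#' directed neighbour lists are symmetrized by union. Edges with
#' non-positive similarity are dropped (modularity on negative weights is
#' ill-defined; beta values and ReLU embeddings are non-negative, so this
#' rarely removes anything). Ties are broken by (similarity descending,
#' sample id ascending).
#'
#' @param X Numeric matrix, samples x features, rownames as sample ids.
#' @param K Number of nearest neighbours (`n_samples >= K + 1`).
#' @return An undirected weighted `igraph` graph with a `K` graph attribute.
#' @export
knn_similarity_graph <- function(X, K) {
  X <- as.matrix(X)
  K <- assert_count(K, "K")
  n <- nrow(X)
  if (n < K + 1L) stopf("need at least K + 1 = %d samples, got %d", K + 1L, n)
  ids <- rownames(X)
  if (is.null(ids)) ids <- paste0("S", seq_len(n))
  norms <- sqrt(rowSums(X^2))
  if (any(norms == 0)) {
    stopf("sample '%s' has a zero-norm feature vector; cosine similarity undefined",
          ids[which(norms == 0)[1L]])
  }
  S <- tcrossprod(X / norms)
  S <- pmin(pmax(S, -1), 1)
  from <- integer(0); to <- integer(0)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    ord <- others[order(-S[i, others], ids[others])]
    nb <- ord[seq_len(K)]
    from <- c(from, rep.int(i, K)); to <- c(to, nb)
  }
  # symmetrize by union; canonical (low, high) keys de-duplicate
  lo <- pmin(from, to); hi <- pmax(from, to)
  keep <- !duplicated(cbind(lo, hi))
  lo <- lo[keep]; hi <- hi[keep]
  w <- S[cbind(lo, hi)]
  pos <- w > 0
  g <- igraph::graph_from_data_frame(
    data.frame(from = ids[lo[pos]], to = ids[hi[pos]], weight = w[pos]),
    directed = FALSE, vertices = data.frame(name = ids))
  g <- igraph::set_graph_attr(g, "K", K)
  g
}

#' Louvain community detection on a weighted graph
#'
#' Runs Louvain modularity maximisation (seeded) and reports the partition
#' together with its weighted modularity, recomputed independently of the
#' community-detection backend by [graph_modularity()].
#'
#' @param g Weighted undirected `igraph` graph.
#' @param resolution Modularity resolution parameter (default 1).
#' @param seed Integer seed (fixes the node-visiting randomisation).
#' @return A `community_assignment`: `membership` (named integer vector,
#'   community indices contiguous from 0), `n_communities`, `modularity`,
#'   and a `no_edges` flag when the graph has no edges (every node then
#'   forms its own community).
#' @export
louvain_partition <- function(g, resolution = 1, seed = 1L) {
  n <- igraph::vcount(g)
  if (n == 0L) stopf("empty graph")
  ids <- igraph::V(g)$name
  if (igraph::ecount(g) == 0L) {
    membership <- structure(seq_len(n) - 1L, names = ids)
    return(structure(list(membership = membership,
                          n_communities = as.integer(n),
                          modularity = NA_real_, no_edges = TRUE),
                     class = "community_assignment"))
  }
  cl <- with_seed(seed, igraph::cluster_louvain(g, resolution = resolution))
  memb <- igraph::membership(cl)
  # renumber contiguous from 0 in order of first appearance
  memb <- as.integer(factor(memb, levels = unique(memb))) - 1L
  membership <- structure(memb, names = ids)
  structure(list(membership = membership,
                 n_communities = length(unique(memb)),
                 modularity = graph_modularity(g, membership, resolution),
                 no_edges = FALSE),
            class = "community_assignment")
}

#' Weighted modularity of a partition
#'
#' Independent implementation of Newman's weighted modularity
#' `Q = sum_c (w_in_c / m - gamma * (d_c / 2m)^2)` where `w_in_c` is the
#' total weight inside community `c`, `d_c` its total weighted degree and
#' `m` the total edge weight.
#'
#' @param g Weighted undirected `igraph` graph.
#' @param membership Community labels, one per vertex (vertex order).
#' @param resolution Resolution `gamma` (default 1).
#' @return Numeric modularity.
#' @export
graph_modularity <- function(g, membership, resolution = 1) {
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- igraph::E(g)$weight
  if (is.null(w)) w <- rep(1, nrow(el))
  m <- sum(w)
  if (m == 0) return(NA_real_)
  memb <- as.vector(membership)
  comms <- unique(memb)
  deg <- numeric(igraph::vcount(g))
  for (e in seq_len(nrow(el))) {
    deg[el[e, 1L]] <- deg[el[e, 1L]] + w[e]
    deg[el[e, 2L]] <- deg[el[e, 2L]] + w[e]
  }
  q <- 0
  for (cc in comms) {
    inside <- memb[el[, 1L]] == cc & memb[el[, 2L]] == cc
    w_in <- sum(w[inside])
    d_c <- sum(deg[memb == cc])
    q <- q + w_in / m - resolution * (d_c / (2 * m))^2
  }
  q
}

#' K-stabilization scan of the community count
#'
#' Builds the KNN graph and runs Louvain for every `K` in
#' `k_min..k_max`, recording the community count; the stable `K` is the
#' smallest one whose count stays constant over the following `window`
#' values of `K`. If no such plateau exists the scan is flagged unstable
#' and `k_max` is returned.
#'
#' @param X Numeric matrix, samples x features.
#' @param k_min,k_max Scan range (default 1..50; `k_max < n_samples`).
#' @param window Plateau length required for stability (default 4).
#' @param resolution Louvain resolution.
#' @param seed Integer seed.
#' @return A `k_scan_result`: `k`, `n_communities` (per K), `stable_k`,
#'   `stable_count`, `stable` flag, and the `community_assignment` at
#'   `stable_k`.
#' @export
k_scan <- function(X, k_min = 1L, k_max = 50L, window = 4L, resolution = 1,
                   seed = 1L) {
  k_min <- assert_count(k_min, "k_min")
  k_max <- assert_count(k_max, "k_max", min = k_min)
  if (k_max >= nrow(X)) stopf("k_max must be below the sample count")
  ks <- k_min:k_max
  counts <- integer(length(ks))
  parts <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    g <- knn_similarity_graph(X, ks[i])
    parts[[i]] <- louvain_partition(g, resolution = resolution,
                                    seed = derive_seed(seed, paste0("k", ks[i])))
    counts[i] <- parts[[i]]$n_communities
  }
  stable_i <- NA_integer_
  for (i in seq_along(ks)) {
    j <- i + window
    if (j > length(ks)) break
    if (all(counts[i:j] == counts[i])) { stable_i <- i; break }
  }
  stable <- !is.na(stable_i)
  if (!stable) stable_i <- length(ks)
  structure(list(k = ks, n_communities = counts, stable_k = ks[stable_i],
                 stable_count = counts[stable_i], stable = stable,
                 window = as.integer(window),
                 assignment = parts[[stable_i]]),
            class = "k_scan_result")
}

#' @export
print.k_scan_result <- function(x, ...) {
  cat(sprintf("k_scan_result: K = %d..%d, %s at K = %d with %d communities\n",
              min(x$k), max(x$k),
              if (x$stable) "stabilized" else "UNSTABLE; fell back to",
              x$stable_k, x$stable_count))
  invisible(x)
}

#' @export
print.community_assignment <- function(x, ...) {
  cat(sprintf("community_assignment: %d communities over %d samples, modularity %.4f\n",
              x$n_communities, length(x$membership), x$modularity))
  invisible(x)
}
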