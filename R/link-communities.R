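# Link clustering: communities of edges rather than nodes. Edges are
# agglomerated by single linkage on the Jaccard similarity of the inclusive
# neighbourhoods of their non-shared endpoints, and the dendrogram is cut
# where the partition density is maximal. Nodes may belong to several
# communities; edges belong to exactly one.

canonical_edges <- function(edges) {
  a <- as.character(edges[[1]]); b <- as.character(edges[[2]])
  if (any(a == b)) stop("self-loops are not allowed")
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  e <- unique(data.frame(a = a, b = b, stringsAsFactors = FALSE))
  e <- e[order(e$a, e$b), ]
  rownames(e) <- NULL
  e
}

inclusive_neighbourhoods <- function(edges) {
  nodes <- sort(unique(c(edges$a, edges$b)))
  nb <- lapply(stats::setNames(nodes, nodes), function(v) {
    sort(unique(c(v, edges$b[edges$a == v], edges$a[edges$b == v])))
  })
  nb
}

#' Similarity of two adjacent edges
#'
#' Two edges sharing exactly one endpoint are compared through the Jaccard
#' similarity of the inclusive neighbourhoods of their non-shared endpoints:
#' `S = |n+(i) on n+(j)| / |n+(i) u n+(j)|` with `n+(x) = {x} u neighbours(x)`.
#' This is the unweighted edge similarity used by link clustering of
#' undirected graphs.
#'
#' @param edges Two-column data.frame of graph edges (the whole graph; the
#'   neighbourhoods are computed from it).
#' @param e1,e2 Length-2 character vectors naming the endpoints of the two
#'   edges to compare.
#' @return Similarity in `[0, 1]`. Errors if the edges are identical or do
#'   not share exactly one endpoint.
#' @examples
#' tri <- data.frame(a = c("a", "a", "b"), b = c("b", "c", "c"))
#' edge_similarity(tri, c("a", "b"), c("a", "c"))  # 1
#' @export
edge_similarity <- function(edges, e1, e2) {
  edges <- canonical_edges(edges)
  e1 <- sort(as.character(e1)); e2 <- sort(as.character(e2))
  if (identical(e1, e2)) stop("cannot compare an edge with itself")
  shared <- intersect(e1, e2)
  if (length(shared) != 1L) stop("edges must share exactly one endpoint")
  i <- setdiff(e1, shared); j <- setdiff(e2, shared)
  nb <- inclusive_neighbourhoods(edges)
  length(intersect(nb[[i]], nb[[j]])) / length(union(nb[[i]], nb[[j]]))
}

#' Partition density of an edge partition
#'
#' For communities `c` with `m_c` edges over `n_c` nodes,
#' `D = (2/M) * sum_c m_c * (m_c - n_c + 1) / ((n_c - 2) * (n_c - 1))`.
#' A community that is a single edge (`n_c = 2`) contributes 0 by
#' convention; a clique contributes its maximal term. `D = 1` iff every
#' community with at least 3 nodes is a clique.
#'
#' @param membership Integer vector assigning each edge to a community.
#' @param edges Canonical two-column data.frame of the same edges (row i is
#'   the edge `membership[i]` refers to).
#' @return The partition density.
#' @export
partition_density <- function(membership, edges) {
  M <- nrow(edges)
  stopifnot(length(membership) == M, M > 0)
  terms <- vapply(split(seq_len(M), membership), function(idx) {
    m <- length(idx)
    n <- length(unique(c(edges$a[idx], edges$b[idx])))
    if (n <= 2) 0 else m * (m - n + 1) / ((n - 2) * (n - 1))
  }, 0)
  (2 / M) * sum(terms)
}

edge_distance_matrix <- function(edges) {
  M <- nrow(edges)
  nb <- inclusive_neighbourhoods(edges)
  nodes <- names(nb)
  d <- matrix(1, M, M)
  # incident edge lists per node; adjacent edge pairs get 1 - Jaccard
  incident <- lapply(nodes, function(v) which(edges$a == v | edges$b == v))
  names(incident) <- nodes
  for (v in nodes) {
    idx <- incident[[v]]
    if (length(idx) < 2) next
    for (p in seq_len(length(idx) - 1L)) {
      for (q in seq((p + 1L), length(idx))) {
        ei <- idx[p]; ej <- idx[q]
        i <- setdiff(c(edges$a[ei], edges$b[ei]), v)
        j <- setdiff(c(edges$a[ej], edges$b[ej]), v)
        if (i == j) next  # multi-edge cannot occur after canonicalisation
        s <- length(intersect(nb[[i]], nb[[j]])) / length(union(nb[[i]], nb[[j]]))
        if (1 - s < d[ei, ej]) d[ei, ej] <- d[ej, ei] <- 1 - s
      }
    }
  }
  diag(d) <- 0
  d
}

#' Link communities at the partition-density maximum
#'
#' Clusters the edges of an undirected graph by single-linkage agglomeration
#' on [edge_similarity()] (non-adjacent edges have similarity 0 and merge
#' only at height 1) and cuts the resulting dendrogram at the height
#' maximising the [partition_density()]. Candidate cuts are the distinct
#' merge heights below 1 plus the all-singletons cut at 0; at equal density
#' the larger height (fewer, larger communities) wins. The procedure is
#' deterministic: single-linkage partitions at a height are the connected
#' components of the similarity-thresholded edge graph, independent of merge
#' order.
#'
#' @param edges Two-column data.frame of edges (extra columns ignored);
#'   duplicate and reversed edges collapse.
#' @param min_nodes Communities with fewer nodes than this are flagged
#'   `small = TRUE` in the summary (default 3); nothing is deleted.
#' @return Object of class `"link_community_set"`: list with
#'   `communities` (list of `list(edges, nodes)`), `membership` (community id
#'   per edge), `edges` (canonical edge table), `summary` (data.frame
#'   community/n_nodes/n_edges/small), `cut_height`, `partition_density`,
#'   and `dendrogram` (an hclust over edges, `NULL` for a single-edge graph).
#' @export
cluster_links <- function(edges, min_nodes = 3) {
  e <- canonical_edges(edges)
  M <- nrow(e)
  if (M == 0L) stop("empty graph: no edges to cluster")
  edge_key <- paste(e$a, e$b, sep = "|")
  if (M == 1L) {
    membership <- 1L
    hc <- NULL
    best_h <- 0
  } else {
    d <- edge_distance_matrix(e)
    dimnames(d) <- list(edge_key, edge_key)
    hc <- stats::hclust(stats::as.dist(d), method = "single")
    heights <- sort(unique(c(0, hc$height[hc$height < 1 - 1e-12])))
    dens <- vapply(heights, function(h) {
      partition_density(stats::cutree(hc, h = h), e)
    }, 0)
    best_h <- heights[max(which(dens == max(dens)))]  # ties -> larger height
    membership <- stats::cutree(hc, h = best_h)
  }
  membership <- as.integer(factor(membership, levels = unique(membership)))
  comms <- lapply(split(seq_len(M), membership), function(idx) {
    list(edges = e[idx, , drop = FALSE],
         nodes = sort(unique(c(e$a[idx], e$b[idx]))))
  })
  summary <- data.frame(
    community = seq_along(comms),
    n_nodes = vapply(comms, function(cm) length(cm$nodes), 0L),
    n_edges = vapply(comms, function(cm) nrow(cm$edges), 0L)
  )
  summary$small <- summary$n_nodes < min_nodes
  structure(
    list(communities = comms, membership = membership, edges = e,
         summary = summary, cut_height = best_h,
         partition_density = partition_density(membership, e),
         dendrogram = hc),
    class = "link_community_set"
  )
}

#' @export
print.link_community_set <- function(x, ...) {
  cat(sprintf(
    "<link_community_set> %d communities over %d edges; cut height %.4f, partition density %.4f\n",
    length(x$communities), nrow(x$edges), x$cut_height, x$partition_density))
  invisible(x)
}
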