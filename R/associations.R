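#' Project a bipartite layer onto co-occurrence associations
#'
#' Given annotation pairs linking middle-layer nodes (diseases) to
#' target-layer nodes (phenotypes or genes), scores every unordered pair of
#' target nodes that share at least one middle-layer neighbour with the
#' hypergeometric index. The null universe is the number of middle-layer
#' nodes in the analysed graph; pairs with zero shared neighbours are never
#' emitted. Pairs are reported once, with lexicographically sorted ids, so
#' the output is independent of edge insertion order.
#'
#' @param pairs data.frame whose first column is the middle-layer node id and
#'   whose second column is the target-layer node id.
#' @param universe Middle-layer size for the null; defaults to the number of
#'   distinct middle-layer nodes in `pairs`.
#' @return data.frame with columns `item_a`, `item_b`, `shared`, `deg_a`,
#'   `deg_b`, `universe`, `hyi`, sorted by (`item_a`, `item_b`).
#' @export
project_associations <- function(pairs, universe = NULL) {
  if (nrow(pairs) == 0L) stop("empty graph: no annotation pairs")
  mid <- as.character(pairs[[1]]); tgt <- as.character(pairs[[2]])
  mids <- sort(unique(mid)); tgts <- sort(unique(tgt))
  if (is.null(universe)) universe <- length(mids)
  inc <- Matrix::sparseMatrix(
    i = match(mid, mids), j = match(tgt, tgts),
    x = 1, dims = c(length(mids), length(tgts))
  )
  inc@x[] <- 1  # duplicates collapse to presence
  co <- Matrix::crossprod(inc)      # target x target shared-disease counts
  deg <- Matrix::colSums(inc)
  co <- methods::as(Matrix::triu(co, k = 1), "TsparseMatrix")
  keep <- co@x > 0
  ia <- co@i[keep] + 1L; ib <- co@j[keep] + 1L
  if (length(ia) == 0L) {
    return(data.frame(item_a = character(0), item_b = character(0),
                      shared = integer(0), deg_a = integer(0),
                      deg_b = integer(0), universe = integer(0),
                      hyi = numeric(0), stringsAsFactors = FALSE))
  }
  res <- data.frame(
    item_a = tgts[ia], item_b = tgts[ib],
    shared = as.integer(co@x[keep]),
    deg_a = as.integer(deg[ia]), deg_b = as.integer(deg[ib]),
    universe = as.integer(universe),
    stringsAsFactors = FALSE
  )
  res$hyi <- hypergeometric_index(res$shared, res$deg_a, res$deg_b, universe)
  res <- res[order(res$item_a, res$item_b), ]
  rownames(res) <- NULL
  res
}

#' Cross-layer phenotype-gene associations from a tripartite network
#'
#' Treats the corpus's diseases as the shared middle layer of a
#' phenotype-disease-gene tripartite network and scores every phenotype-gene
#' pair by the number of diseases annotated with both, under the same
#' hypergeometric-index null as [project_associations()] (universe = number
#' of diseases with complete information).
#'
#' @param corpus An `"annotation_corpus"`.
#' @return data.frame with columns `phenotype_id`, `gene`, `shared`,
#'   `deg_phenotype`, `deg_gene`, `universe`, `hyi`.
#' @export
phenotype_gene_associations <- function(corpus) {
  stopifnot(inherits(corpus, "annotation_corpus"))
  dis <- corpus$diseases$disease_id
  phen <- corpus$phenotype_universe
  gene <- corpus$gene_universe
  P <- Matrix::sparseMatrix(
    i = match(corpus$phenotype_pairs$disease_id, dis),
    j = match(corpus$phenotype_pairs$phenotype_id, phen),
    x = 1, dims = c(length(dis), length(phen)))
  G <- Matrix::sparseMatrix(
    i = match(corpus$gene_pairs$disease_id, dis),
    j = match(corpus$gene_pairs$gene, gene),
    x = 1, dims = c(length(dis), length(gene)))
  co <- methods::as(Matrix::crossprod(P, G), "TsparseMatrix")  # phen x gene
  keep <- co@x > 0
  ip <- co@i[keep] + 1L; ig <- co@j[keep] + 1L
  res <- data.frame(
    phenotype_id = phen[ip], gene = gene[ig],
    shared = as.integer(co@x[keep]),
    deg_phenotype = as.integer(Matrix::colSums(P))[ip],
    deg_gene = as.integer(Matrix::colSums(G))[ig],
    universe = length(dis),
    stringsAsFactors = FALSE
  )
  res$hyi <- if (nrow(res)) {
    hypergeometric_index(res$shared, res$deg_phenotype, res$deg_gene, length(dis))
  } else numeric(0)
  res <- res[order(res$phenotype_id, res$gene), ]
  rownames(res) <- NULL
  res
}

#' Keep associations at or above a hypergeometric-index threshold
#'
#' @param scores data.frame with an `hyi` column (either association layout).
#' @param threshold Minimum HyI; default 2 (one-sided p <= 0.01).
#' @return The significant rows, stable-sorted by descending `hyi` then by
#'   the pair ids.
#' @export
significant_pairs <- function(scores, threshold = 2.0) {
  res <- scores[scores$hyi >= threshold, ]
  id_cols <- intersect(c("item_a", "item_b", "phenotype_id", "gene"), names(res))
  res <- res[order(-res$hyi, res[[id_cols[1]]], res[[id_cols[2]]]), ]
  rownames(res) <- NULL
  res
}

#' Restrict phenotype pairs to class-typical phenotypes
#'
#' @param pairs data.frame with `item_a`, `item_b` columns.
#' @param typical Character vector of typical phenotype ids.
#' @param mode `"both"` keeps pairs with both endpoints typical (the
#'   default: a pair of class phenotypes); `"either"` keeps pairs with at
#'   least one typical endpoint.
#' @return The retained rows.
#' @export
restrict_to_typical <- function(pairs, typical, mode = c("both", "either")) {
  mode <- match.arg(mode)
  a_in <- pairs$item_a %in% typical
  b_in <- pairs$item_b %in% typical
  res <- pairs[if (mode == "both") a_in & b_in else a_in | b_in, ]
  rownames(res) <- NULL
  res
}
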