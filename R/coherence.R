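#' Functionally coherent phenotype clusters
#'
#' A phenotype community is functionally coherent when at least a threshold
#' fraction (default 70%) of its member phenotypes share the same
#' significantly enriched function term. Coverage of a term is the fraction
#' of community phenotypes for which that term appears in the enrichment
#' table; the denominator is all phenotypes in the community, including any
#' with no enriched term at all. Namespaces are pooled: any single term from
#' any annotation resource can certify a cluster.
#'
#' @param communities A `"link_community_set"` from [cluster_links()].
#' @param enrichment data.frame of phenotype-function pairs
#'   ([phenotype_function_pairs()] output: needs `phenotype_id`, `term_id`,
#'   optionally `namespace`).
#' @param threshold Minimum coverage fraction in `(0, 1]`; default 0.7
#'   (0.5 is the usual sensitivity setting).
#' @return List of coherent clusters, each a list with `community` (id in
#'   `communities`), `phenotypes`, `shared_terms` (data.frame term_id /
#'   namespace / coverage / covering phenotypes, sorted by descending
#'   coverage then term id), and `coverage` (the best fraction). Communities
#'   failing the threshold are absent.
#' @export
coherent_clusters <- function(communities, enrichment, threshold = 0.7) {
  stopifnot(inherits(communities, "link_community_set"),
            threshold > 0, threshold <= 1)
  ns <- if ("namespace" %in% names(enrichment)) enrichment$namespace else "custom"
  enr <- unique(data.frame(phenotype_id = enrichment$phenotype_id,
                           term_id = enrichment$term_id,
                           namespace = ns, stringsAsFactors = FALSE))
  out <- list()
  for (ci in seq_along(communities$communities)) {
    phen <- communities$communities[[ci]]$nodes
    sub <- enr[enr$phenotype_id %in% phen, ]
    if (nrow(sub) == 0L) next
    cov_list <- split(sub$phenotype_id, sub$term_id)
    coverage <- vapply(cov_list, function(p) length(unique(p)), 0L) / length(phen)
    pass <- coverage >= threshold
    if (!any(pass)) next
    terms <- names(cov_list)[pass]
    shared <- data.frame(
      term_id = terms,
      namespace = vapply(terms, function(t) sub$namespace[sub$term_id == t][1], ""),
      coverage = unname(coverage[pass]),
      phenotypes = vapply(terms, function(t)
        paste(sort(unique(cov_list[[t]])), collapse = ","), ""),
      stringsAsFactors = FALSE
    )
    shared <- shared[order(-shared$coverage, shared$term_id), ]
    rownames(shared) <- NULL
    out[[length(out) + 1L]] <- list(
      community = ci,
      phenotypes = phen,
      shared_terms = shared,
      coverage = max(shared$coverage)
    )
  }
  out
}

#' Gene support for a coherent cluster
#'
#' Lists the genes associated (by the HyI-filtered phenotype-gene pairs) with
#' any member phenotype of a cluster, annotated with the fraction of member
#' phenotypes each gene supports. A gene appearing in several clusters with
#' different shared functions is the signature of pleiotropy.
#'
#' @param cluster One element of the [coherent_clusters()] result (or any
#'   list with a `phenotypes` field).
#' @param phen_gene data.frame with `phenotype_id`, `gene` columns.
#' @return data.frame `gene` / `n_phenotypes` / `coverage`, sorted by
#'   descending coverage then gene.
#' @export
cluster_gene_support <- function(cluster, phen_gene) {
  phen <- cluster$phenotypes
  sub <- unique(phen_gene[phen_gene$phenotype_id %in% phen,
                          c("phenotype_id", "gene")])
  if (nrow(sub) == 0L) {
    return(data.frame(gene = character(0), n_phenotypes = integer(0),
                      coverage = numeric(0), stringsAsFactors = FALSE))
  }
  n <- vapply(split(sub$phenotype_id, sub$gene), function(p) length(unique(p)), 0L)
  res <- data.frame(gene = names(n), n_phenotypes = as.integer(n),
                    coverage = as.numeric(n) / length(phen),
                    stringsAsFactors = FALSE)
  res <- res[order(-res$coverage, res$gene), ]
  rownames(res) <- NULL
  res
}
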