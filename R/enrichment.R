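#' Over-representation analysis of a gene list
#'
#' Hypergeometric enrichment of a query gene list against term-annotated gene
#' sets, with Benjamini-Hochberg adjustment across the tested terms. Defaults
#' follow the common ORA parameterisation: `p_cutoff = 0.05` on the adjusted
#' p, `q_cutoff = 0.2`, term sizes restricted to `[min_gs_size, max_gs_size]`
#' after intersecting each gene set with the universe. The q-value reported
#' here is the BH-based estimate with pi0 = 1, i.e. numerically the BH
#' adjusted p; tools that refine pi0 by spline fitting will differ slightly.
#'
#' @param query Character vector of query genes. Genes outside the universe
#'   are dropped with a warning.
#' @param annotation data.frame with columns `term_id`, `gene`, or a named
#'   list of gene-id vectors.
#' @param universe Character vector of background genes. Default: all genes
#'   annotated to at least one term in `annotation`.
#' @param min_gs_size,max_gs_size Term-size bounds (default 10 and 500).
#' @param p_cutoff Threshold on the BH-adjusted p (default 0.05).
#' @param q_cutoff Threshold on the q-value (default 0.2).
#' @param namespace Optional label copied into the output rows.
#' @return data.frame with columns `term_id`, `k` (overlap), `K` (term size
#'   in universe), `n` (query size in universe), `N` (universe size), `p`,
#'   `p_adjust`, `q`, `namespace`; only rows passing both cut-offs, sorted by
#'   ascending `p` then term id.
#' @export
ora <- function(query, annotation, universe = NULL,
                min_gs_size = 10, max_gs_size = 500,
                p_cutoff = 0.05, q_cutoff = 0.2, namespace = "custom") {
  sets <- if (is.data.frame(annotation)) {
    split(annotation$gene, annotation$term_id)
  } else annotation
  sets <- lapply(sets, unique)
  if (is.null(universe)) universe <- unique(unlist(sets, use.names = FALSE))
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty gene universe")
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(sprintf("%d query gene(s) outside the universe dropped", length(outside)))
    query <- intersect(query, universe)
  }
  empty <- data.frame(term_id = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0),
                      p_adjust = numeric(0), q = numeric(0),
                      namespace = character(0), stringsAsFactors = FALSE)
  if (length(query) == 0L) return(empty)
  sets <- lapply(sets, intersect, universe)
  K <- lengths(sets)
  sets <- sets[K >= min_gs_size & K <= max_gs_size]
  if (length(sets) == 0L) return(empty)
  k <- vapply(sets, function(s) length(intersect(s, query)), 0L)
  K <- lengths(sets)
  n <- length(query); N <- length(universe)
  p <- hyper_tail(k, K, n, N)
  res <- data.frame(term_id = names(sets), k = k, K = K, n = n, N = N,
                    p = p, stringsAsFactors = FALSE)
  res$p_adjust <- bh_adjust(res$p)
  res$q <- res$p_adjust  # BH-based q with pi0 = 1
  res$namespace <- namespace
  res <- res[res$p_adjust <= p_cutoff & res$q <= q_cutoff & res$k > 0, ]
  res <- res[order(res$p, res$term_id), ]
  rownames(res) <- NULL
  res
}

#' Phenotype-function pairs by per-phenotype enrichment
#'
#' For every phenotype in a (HyI-filtered) phenotype-gene association table,
#' runs [ora()] on the phenotype's associated gene list. The multiple-testing
#' family is the set of terms tested for one phenotype's gene list — matching
#' per-gene-list enrichment tools — not the global phenotype x term grid.
#' Phenotypes with no significant term are absent from the result.
#'
#' @param phen_gene data.frame with columns `phenotype_id`, `gene`
#'   (typically [significant_pairs()] applied to
#'   [phenotype_gene_associations()]).
#' @param annotation,universe,... Passed to [ora()].
#' @return data.frame: `phenotype_id` plus the [ora()] columns.
#' @export
phenotype_function_pairs <- function(phen_gene, annotation, universe = NULL, ...) {
  by_phen <- split(phen_gene$gene, phen_gene$phenotype_id)
  out <- lapply(names(by_phen), function(ph) {
    tab <- suppressWarnings(ora(by_phen[[ph]], annotation, universe = universe, ...))
    if (nrow(tab) == 0L) return(NULL)
    cbind(data.frame(phenotype_id = ph, stringsAsFactors = FALSE), tab)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(phenotype_id = character(0), term_id = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p = numeric(0), p_adjust = numeric(0),
                      q = numeric(0), namespace = character(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
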