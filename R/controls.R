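# Validation machinery: literature co-mention tests over term -> document
# indices, prevalence-matched random phenotype sets, degree-preserving pair
# shuffles, empirical real-vs-random comparisons, and the tissue-expression
# contrast.

#' Search queries for a term's textual descriptions
#'
#' A term is looked for in abstracts under its primary name and every
#' synonym, lower-cased and deduplicated. The statistics only ever consume a
#' term -> document index, so any retrieval backend (or a file) can stand
#' behind these queries.
#'
#' @param ontology An `"ontology"` object.
#' @param id Term id.
#' @return Character vector of lower-case query strings.
#' @export
build_term_queries <- function(ontology, id) {
  id <- resolve_term(ontology, id)
  term <- ontology$terms[[id]]
  if (is.null(term) || is.na(term$name)) stop("term has no name to query")
  unique(tolower(c(term$name, term$synonyms)))
}

#' Read a term -> document index from TSV
#'
#' @param path Two-column TSV (`term_id`, `pmid`) with `#` comments.
#' @param corpus_size Total number of documents in the searched corpus.
#' @return A `"term_corpus_index"`: list with `docs` (named list of document
#'   id sets) and `corpus_size`.
#' @export
read_term_index <- function(path, corpus_size) {
  pairs <- parse_annotations(path, dialect = "pair_tsv", kind = "term_pmids")
  term_corpus_index(split(pairs$pmid, pairs$term_id), corpus_size)
}

#' Construct a term -> document index
#'
#' @param docs Named list: term id -> character/integer vector of document
#'   ids.
#' @param corpus_size Total corpus size; must be at least the size of any
#'   union of document sets used downstream.
#' @return A `"term_corpus_index"` object.
#' @export
term_corpus_index <- function(docs, corpus_size) {
  docs <- lapply(docs, function(d) unique(as.character(d)))
  structure(list(docs = docs, corpus_size = as.integer(corpus_size)),
            class = "term_corpus_index")
}

#' Co-mention test of two terms in a document corpus
#'
#' Builds the 2x2 table (mentions A x mentions B) by set algebra over the two
#' PMID lists against the corpus size, and tests enrichment of joint mention
#' with the one-tailed Fisher exact test.
#'
#' @param docs_a,docs_b Vectors of document ids mentioning each term.
#' @param corpus_size Total number of documents searched.
#' @return List with `both`, `a_only`, `b_only`, `neither`, `p`.
#' @export
comention_test <- function(docs_a, docs_b, corpus_size) {
  docs_a <- unique(as.character(docs_a)); docs_b <- unique(as.character(docs_b))
  u <- length(union(docs_a, docs_b))
  if (corpus_size < u) stop("corpus_size smaller than the union of document sets")
  both <- length(intersect(docs_a, docs_b))
  a_only <- length(docs_a) - both
  b_only <- length(docs_b) - both
  neither <- corpus_size - u
  list(both = both, a_only = a_only, b_only = b_only, neither = neither,
       p = fisher_one_tail(both, a_only, b_only, neither))
}

#' Co-mention tests for a list of term pairs
#'
#' @param pairs Two-column data.frame of term ids.
#' @param index A `"term_corpus_index"`.
#' @return `pairs` with `both` and `p` columns appended; terms absent from
#'   the index have empty document sets.
#' @export
comention_pairs <- function(pairs, index) {
  stopifnot(inherits(index, "term_corpus_index"))
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    ct <- comention_test(index$docs[[pairs[[1]][i]]] %||% character(0),
                         index$docs[[pairs[[2]][i]]] %||% character(0),
                         index$corpus_size)
    c(both = ct$both, p = ct$p)
  })
  res <- do.call(rbind, res)
  pairs$both <- as.integer(res[, "both"])
  pairs$p <- res[, "p"]
  pairs
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Prevalence-matched random phenotype sets
#'
#' Draws random phenotype sets mimicking the disease-count (prevalence)
#' distribution of a target set: candidates are binned into deciles of the
#' candidate prevalence distribution (or into exact-value bins when at most
#' `n_bins` distinct counts occur) and, for each target phenotype, one
#' candidate is drawn without replacement (within a replicate) from the
#' target's bin. An exhausted bin is widened to its neighbours with a
#' warning; the targets are never resampled.
#'
#' @param candidates Named numeric vector: candidate phenotype -> disease
#'   count.
#' @param targets Named numeric vector: target phenotype -> disease count.
#' @param n_reps Number of replicate sets (100 for the standard contrast).
#' @param n_bins Number of quantile bins over the candidate counts
#'   (default 10).
#' @param seed Optional integer seed.
#' @return List of `n_reps` character vectors, each of length
#'   `length(targets)`.
#' @export
prevalence_matched_sample <- function(candidates, targets, n_reps = 100,
                                      n_bins = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  values <- sort(unique(candidates))
  if (length(values) <= n_bins) {
    # few distinct prevalence values: every value is its own bin, so a
    # target is always matched by an equally prevalent candidate
    bin_of <- function(x) findInterval(x, c(values, Inf))
  } else {
    breaks <- unique(stats::quantile(candidates, probs = seq(0, 1, length.out = n_bins + 1)))
    bin_of <- function(x) findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  }
  cand_bin <- bin_of(candidates)
  tgt_bin <- bin_of(targets)
  n_bins_eff <- max(cand_bin)
  lapply(seq_len(n_reps), function(rep) {
    taken <- character(0)
    out <- character(length(targets))
    for (i in seq_along(targets)) {
      width <- 0L
      repeat {
        ok <- names(candidates)[abs(cand_bin - tgt_bin[i]) <= width]
        ok <- setdiff(ok, taken)
        if (length(ok)) break
        width <- width + 1L
        if (width > n_bins_eff) stop("candidate pool exhausted")
        warning(sprintf("prevalence bin %d exhausted; widened by %d", tgt_bin[i], width))
      }
      out[i] <- ok[sample.int(length(ok), 1L)]
      taken <- c(taken, out[i])
    }
    out
  })
}

#' Degree-preserving shuffle of a bipartite pair list
#'
#' Randomises which left item pairs with which right item by repeated double
#' edge swaps — pick two pairs, exchange their right-hand members, reject the
#' swap if it would duplicate an existing pair — until a mixing target of
#' successful swaps (default `10 * nrow(pairs)`). Left and right degree
#' sequences are exactly preserved and no duplicate pairs are created.
#' Graphs admitting no legal swap (e.g. a star) come back unchanged.
#'
#' @param pairs Two-column data.frame.
#' @param n_swaps Successful-swap mixing target.
#' @param seed Optional integer seed.
#' @return data.frame with the same columns, degrees preserved.
#' @export
degree_preserving_shuffle <- function(pairs, n_swaps = 10 * nrow(pairs),
                                      seed = NULL) {
  if (nrow(pairs) == 0L) stop("pair list must be non-empty")
  if (!is.null(seed)) set.seed(seed)
  left <- as.character(pairs[[1]]); right <- as.character(pairs[[2]])
  m <- length(left)
  if (m < 2L) return(pairs)
  key <- function(l, r) paste(l, r, sep = "\r")
  existing <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(m)) assign(key(left[i], right[i]), TRUE, envir = existing)
  done <- 0L; attempts <- 0L; max_attempts <- 100L * n_swaps
  while (done < n_swaps && attempts < max_attempts) {
    attempts <- attempts + 1L
    ij <- sample.int(m, 2L)
    i <- ij[1]; j <- ij[2]
    if (right[i] == right[j] || left[i] == left[j]) next
    k1 <- key(left[i], right[j]); k2 <- key(left[j], right[i])
    if (exists(k1, envir = existing, inherits = FALSE) ||
        exists(k2, envir = existing, inherits = FALSE)) next
    rm(list = c(key(left[i], right[i]), key(left[j], right[j])), envir = existing)
    tmp <- right[i]; right[i] <- right[j]; right[j] <- tmp
    assign(k1, TRUE, envir = existing); assign(k2, TRUE, envir = existing)
    done <- done + 1L
  }
  out <- pairs
  out[[1]] <- left; out[[2]] <- right
  out
}

#' Empirical comparison of an observed count against null replicates
#'
#' Summarises a real-vs-random contrast: the mean and SD of the null counts
#' and the add-one empirical p-value
#' `(1 + #\{null >= observed\}) / (1 + n_reps)`, the probability of finding
#' at least as extreme a count in the randomised data.
#'
#' @param observed Observed count on the real data.
#' @param null_counts Numeric vector of counts from null replicates.
#' @return List with `observed`, `mean`, `sd`, `empirical_p`, `n_reps`.
#' @export
empirical_comparison <- function(observed, null_counts) {
  if (length(null_counts) == 0L) stop("need at least one null replicate")
  list(observed = observed,
       mean = mean(null_counts),
       sd = stats::sd(null_counts),
       empirical_p = (1 + sum(null_counts >= observed)) / (1 + length(null_counts)),
       n_reps = length(null_counts))
}

#' Read a normal-tissue expression table
#'
#' Expects the Human Protein Atlas `normal_tissue.tsv` column layout:
#' `Gene`, `Gene name`, `Tissue`, `Cell type`, `Level`, `Reliability`
#' (tab-separated, with header).
#'
#' @param path File path.
#' @return data.frame with columns `gene`, `tissue`, `cell_type`, `level`.
#' @export
read_hpa_expression <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  names(tab) <- tolower(gsub("[ .]", "_", names(tab)))
  gene_col <- if ("gene_name" %in% names(tab)) "gene_name" else "gene"
  data.frame(gene = tab[[gene_col]], tissue = tab$tissue,
             cell_type = tab$cell_type, level = tab$level,
             stringsAsFactors = FALSE)
}

#' Default neuronal/muscular tissue panel
#' @return Character vector of tissue names.
#' @export
neuromuscular_tissues <- function() {
  c("cerebellum", "cerebral cortex", "hippocampus", "caudate",
    "skeletal muscle", "heart muscle")
}

#' Tissue-expression contrast between two gene sets
#'
#' A gene counts as expressed when any expression row matches one of the
#' listed tissues at one of the accepted levels (default Medium or High).
#' The proportions expressed in the two sets are compared by the one-tailed
#' Fisher exact test (enrichment of expression in `genes_a`). Genes absent
#' from the table count as not expressed and are tallied in a warning.
#'
#' @param genes_a,genes_b Character vectors of gene symbols.
#' @param expression data.frame as from [read_hpa_expression()].
#' @param tissues Tissue names to count (substring-free exact match,
#'   case-insensitive); default [neuromuscular_tissues()].
#' @param levels Accepted expression levels; default `c("Medium", "High")`.
#' @return List with `prop_a`, `prop_b`, `table` (the 2x2 as a matrix) and
#'   `p`.
#' @export
tissue_expression_test <- function(genes_a, genes_b, expression,
                                   tissues = neuromuscular_tissues(),
                                   levels = c("Medium", "High")) {
  genes_a <- unique(genes_a); genes_b <- unique(genes_b)
  hit <- expression[tolower(expression$tissue) %in% tolower(tissues) &
                      expression$level %in% levels, ]
  expressed <- unique(hit$gene)
  absent <- setdiff(c(genes_a, genes_b), unique(expression$gene))
  if (length(absent)) {
    warning(sprintf("%d gene(s) absent from the expression table counted not-expressed",
                    length(absent)))
  }
  a <- sum(genes_a %in% expressed); b <- length(genes_a) - a
  cc <- sum(genes_b %in% expressed); d <- length(genes_b) - cc
  list(prop_a = if (length(genes_a)) a / length(genes_a) else NaN,
       prop_b = if (length(genes_b)) cc / length(genes_b) else NaN,
       table = matrix(c(a, cc, b, d), 2, 2,
                      dimnames = list(c("set_a", "set_b"),
                                      c("expressed", "not_expressed"))),
       p = fisher_one_tail(a, b, cc, d))
}
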