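#' Default neuromuscular-disorder keyword list
#'
#' The fourteen search phrases used to pull neuromuscular disorders out of a
#' title-indexed disease catalogue: muscular dystrophy, myopathy, myasthenic,
#' myasthenia, neuropathy, amyotrophic lateral sclerosis, spinal muscular
#' atrophy, spinal and bulbar muscular atrophy, myotonia, periodic paralysis,
#' myotonic dystrophy, mitochondrial cytopathy, necrotizing
#' encephalomyelopathy, mitochondrial DNA depletion.
#'
#' @return Character vector of lower-case keyword phrases.
#' @export
nmd_keywords <- function() {
  c("muscular dystrophy", "myopathy", "myasthenic", "myasthenia",
    "neuropathy", "amyotrophic lateral sclerosis", "spinal muscular atrophy",
    "spinal and bulbar muscular atrophy", "myotonia", "periodic paralysis",
    "myotonic dystrophy", "mitochondrial cytopathy",
    "necrotizing encephalomyelopathy", "mitochondrial dna depletion")
}

#' Label diseases by keyword match on their titles
#'
#' A disease is `IN_CLASS` iff any keyword is a case-insensitive substring of
#' its title or one of its alternative titles. This is a reproducible proxy
#' for a free-text database search.
#'
#' @param titles Named character vector: disease id -> title.
#' @param keywords Character vector of phrases; defaults to [nmd_keywords()].
#' @param alt_titles Optional named list: disease id -> character vector of
#'   alternative titles.
#' @return Named character vector of labels (`"IN_CLASS"` / `"OUT_CLASS"`),
#'   one per disease.
#' @export
classify_by_keywords <- function(titles, keywords = nmd_keywords(),
                                 alt_titles = NULL) {
  if (length(keywords) == 0L) stop("keyword list must be non-empty")
  kw <- tolower(keywords)
  hit <- vapply(seq_along(titles), function(i) {
    texts <- tolower(c(titles[[i]], alt_titles[[names(titles)[i]]]))
    any(vapply(kw, function(k) any(grepl(k, texts, fixed = TRUE)), TRUE))
  }, TRUE)
  stats::setNames(ifelse(hit, "IN_CLASS", "OUT_CLASS"), names(titles))
}

#' Label diseases by descent from an ontology class root
#'
#' A disease is `IN_CLASS` iff its classification term reaches `root` by
#' following `is_a` links upward (the root's own term included). Diseases
#' with no classification term are labelled `OUT_CLASS` with a warning.
#'
#' @param disease_terms Named character vector: disease id -> classification
#'   term id.
#' @param classification An `"ontology"` object (e.g. a parsed disease
#'   ontology).
#' @param root Term id of the class root.
#' @param disease_ids Optional full set of disease ids to label; ids absent
#'   from `disease_terms` get `OUT_CLASS`.
#' @return Named character vector of labels.
#' @export
classify_by_descendants <- function(disease_terms, classification, root,
                                    disease_ids = names(disease_terms)) {
  in_class <- term_descends_from(classification, unname(disease_terms), root)
  labels <- stats::setNames(rep("OUT_CLASS", length(disease_ids)), disease_ids)
  labels[names(disease_terms)[in_class]] <- "IN_CLASS"
  missing <- setdiff(disease_ids, names(disease_terms))
  if (length(missing)) {
    warning(sprintf("%d disease(s) have no classification term; labelled OUT_CLASS",
                    length(missing)))
  }
  labels
}

#' Build the filtered annotation corpus
#'
#' Combines disease-phenotype pairs, disease-gene pairs and class labels into
#' a corpus retaining only diseases with complete information, i.e. at least
#' one phenotype AND at least one gene. Counting downstream is always per
#' disease (presence/absence), so duplicated annotation rows cannot inflate
#' anything.
#'
#' @param phenotype_pairs data.frame with columns `disease_id`,
#'   `phenotype_id` (as from [parse_annotations()]).
#' @param gene_pairs data.frame with columns `disease_id`, `gene`.
#' @param labels Named character vector of `"IN_CLASS"`/`"OUT_CLASS"` labels.
#'   Unlabelled diseases are treated as `OUT_CLASS`.
#' @param titles Optional named character vector of disease titles.
#' @return An object of class `"annotation_corpus"`: list with `diseases`
#'   (data.frame id/title/label), `phenotype_pairs`, `gene_pairs` (filtered
#'   to retained diseases), the derived `phenotype_universe` and
#'   `gene_universe`, and `counts` (summary of the filtering).
#' @export
build_corpus <- function(phenotype_pairs, gene_pairs, labels, titles = NULL) {
  stopifnot(all(c("disease_id", "phenotype_id") %in% names(phenotype_pairs)),
            all(c("disease_id", "gene") %in% names(gene_pairs)))
  phenotype_pairs <- unique(phenotype_pairs[c("disease_id", "phenotype_id")])
  gene_pairs <- unique(gene_pairs[c("disease_id", "gene")])
  all_ids <- sort(unique(c(phenotype_pairs$disease_id, gene_pairs$disease_id,
                           names(labels))))
  keep <- intersect(unique(phenotype_pairs$disease_id),
                    unique(gene_pairs$disease_id))
  if (length(keep) == 0L) {
    stop(sprintf(paste0("empty corpus after filtering: %d disease(s) with ",
                        "phenotypes, %d with genes, 0 with both"),
                 length(unique(phenotype_pairs$disease_id)),
                 length(unique(gene_pairs$disease_id))))
  }
  keep <- sort(keep)
  lab <- stats::setNames(rep("OUT_CLASS", length(keep)), keep)
  lab[intersect(keep, names(labels))] <- labels[intersect(keep, names(labels))]
  pp <- phenotype_pairs[phenotype_pairs$disease_id %in% keep, ]
  gp <- gene_pairs[gene_pairs$disease_id %in% keep, ]
  pp <- pp[order(pp$disease_id, pp$phenotype_id), ]
  gp <- gp[order(gp$disease_id, gp$gene), ]
  rownames(pp) <- rownames(gp) <- NULL
  diseases <- data.frame(
    disease_id = keep,
    title = if (is.null(titles)) NA_character_ else unname(titles[keep]),
    label = unname(lab),
    stringsAsFactors = FALSE
  )
  counts <- c(
    total = length(all_ids),
    all_in_class = sum(labels == "IN_CLASS", na.rm = TRUE),
    all_out_class = length(all_ids) - sum(labels == "IN_CLASS", na.rm = TRUE),
    complete = length(keep),
    in_class = sum(lab == "IN_CLASS"),
    out_class = sum(lab == "OUT_CLASS"),
    phenotypes = length(unique(pp$phenotype_id)),
    genes = length(unique(gp$gene))
  )
  structure(
    list(diseases = diseases, phenotype_pairs = pp, gene_pairs = gp,
         phenotype_universe = sort(unique(pp$phenotype_id)),
         gene_universe = sort(unique(gp$gene)),
         counts = counts),
    class = "annotation_corpus"
  )
}

#' @export
print.annotation_corpus <- function(x, ...) {
  cat("<annotation_corpus>\n")
  cat(sprintf("  diseases with complete information: %d (%d in-class, %d out-of-class)\n",
              x$counts[["complete"]], x$counts[["in_class"]], x$counts[["out_class"]]))
  cat(sprintf("  phenotype universe: %d  gene universe: %d\n",
              x$counts[["phenotypes"]], x$counts[["genes"]]))
  invisible(x)
}

#' Phenotypes typical of the in-class diseases
#'
#' For every phenotype in the corpus, counts the diseases annotated with it
#' in each class and tests enrichment among in-class diseases with a
#' one-tailed Fisher exact test on the 2x2 table (class membership x has
#' phenotype). Phenotypes with p below the threshold, sorted by ascending p,
#' are the class-typical phenotypes.
#'
#' @param corpus An `"annotation_corpus"`.
#' @param alpha Significance threshold on the (by default raw) p-value;
#'   default 0.05.
#' @param adjust If `TRUE`, threshold the BH-adjusted p instead of the raw p.
#'   The raw-p default matches the typical-phenotype extraction convention.
#' @return data.frame with columns `phenotype_id`, `n_in`, `n_out`, `p`
#'   (and `p_adjust` when `adjust = TRUE`), rows sorted by ascending `p` then
#'   id, restricted to phenotypes passing the threshold.
#' @export
typical_phenotypes <- function(corpus, alpha = 0.05, adjust = FALSE) {
  stopifnot(inherits(corpus, "annotation_corpus"))
  lab <- stats::setNames(corpus$diseases$label, corpus$diseases$disease_id)
  n_in_total <- sum(lab == "IN_CLASS")
  n_out_total <- sum(lab == "OUT_CLASS")
  if (n_in_total == 0L || n_out_total == 0L) {
    stop("typical_phenotypes needs at least one disease in each class")
  }
  pp <- corpus$phenotype_pairs
  is_in <- lab[pp$disease_id] == "IN_CLASS"
  n_in <- table(factor(pp$phenotype_id[is_in], levels = corpus$phenotype_universe))
  n_out <- table(factor(pp$phenotype_id[!is_in], levels = corpus$phenotype_universe))
  a <- as.integer(n_in); cc <- as.integer(n_out)
  p <- hyper_tail(a, a + (n_in_total - a), a + cc, n_in_total + n_out_total)
  res <- data.frame(
    phenotype_id = corpus$phenotype_universe,
    n_in = a, n_out = cc, p = p,
    stringsAsFactors = FALSE
  )
  if (adjust) {
    res$p_adjust <- bh_adjust(res$p)
    res <- res[res$p_adjust <= alpha, ]
  } else {
    res <- res[res$p <= alpha, ]
  }
  res <- res[order(res$p, res$phenotype_id), ]
  rownames(res) <- NULL
  res
}
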