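# Synthetic annotation corpora with planted structure. The generator states
# a small world with the statistical features the pipeline assumes: a
# minority disease class whose diseases co-annotate module phenotypes and
# module genes tied to a function term, on top of unstructured background
# annotation shared by all diseases. Everything is seeded and byte-stable.

#' Parameters of the synthetic corpus generator
#'
#' Defaults state the standard simulation world: 200 in-class and 800
#' out-of-class diseases; 10 planted phenotype modules of 6 phenotypes, each
#' tied to one function term annotating a 12-gene set; in-class diseases
#' draw their module's phenotypes with probability 0.9 and its genes with
#' probability 0.7; every disease draws each of 300 background phenotypes
#' with probability 0.02 and each of 200 background genes with probability
#' 0.01. The literature corpus holds 10000 documents, mentions any term in a
#' document with probability 0.03, and gives planted pairs a 10x joint lift.
#'
#' @param n_diseases_in,n_diseases_out Class sizes.
#' @param n_phen_modules Number of planted phenotype modules (0 gives a
#'   structure-free corpus for type-I checks).
#' @param module_size Phenotypes per module.
#' @param within_module_annotation_prob Probability an in-class disease is
#'   annotated with each phenotype of its module.
#' @param background_annotation_prob Per-disease probability of each
#'   background phenotype.
#' @param n_background_phenotypes,n_background_genes Background vocabulary
#'   sizes.
#' @param n_genes_per_function Genes in each module's function term.
#' @param gene_disease_prob Probability an in-class disease is annotated
#'   with each gene of its module.
#' @param background_gene_prob Per-disease probability of each background
#'   gene.
#' @param n_background_functions,background_function_size Decoy function
#'   terms over the background genes.
#' @param corpus_size,base_mention_rate,comention_lift Literature-index
#'   parameters.
#' @return A list of class `"sim_params"`.
#' @export
sim_params <- function(n_diseases_in = 200, n_diseases_out = 800,
                       n_phen_modules = 10, module_size = 6,
                       within_module_annotation_prob = 0.9,
                       background_annotation_prob = 0.02,
                       n_background_phenotypes = 300,
                       n_background_genes = 200,
                       n_genes_per_function = 12,
                       gene_disease_prob = 0.7,
                       background_gene_prob = 0.01,
                       n_background_functions = 20,
                       background_function_size = 15,
                       corpus_size = 10000,
                       base_mention_rate = 0.03,
                       comention_lift = 10) {
  p <- as.list(environment())
  probs <- c(p$within_module_annotation_prob, p$background_annotation_prob,
             p$gene_disease_prob, p$background_gene_prob, p$base_mention_rate)
  stopifnot(all(probs >= 0 & probs <= 1))
  structure(p, class = "sim_params")
}

#' Derive a child seed from a run seed
#'
#' One global seed fans out to per-stage child seeds by a counter scheme so
#' stages can be re-run independently yet reproducibly. The result stays
#' below 2^31.
#'
#' @param seed Integer run seed.
#' @param stage Integer stage counter.
#' @return Integer child seed.
#' @export
child_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 10007 + stage * 97) %% 2147483629)
}

pad_id <- function(prefix, i, width = 3) sprintf("%s%0*d", prefix, width, i)

#' Generate a synthetic annotation corpus with planted modules
#'
#' In-class diseases are assigned round-robin to phenotype modules and draw
#' their module's phenotypes and genes at the stated probabilities; all
#' diseases draw background phenotypes and genes at background rates. Every
#' module's gene set is annotated to one function term; background genes are
#' spread over decoy function terms. Diseases are forced to keep at least
#' one phenotype and one gene so the complete-information filter does not
#' empty the class. Titles embed a class keyword ("myopathy") for in-class
#' diseases so keyword labelling is exercised end to end.
#'
#' @param params A [sim_params()] object.
#' @param seed Integer seed.
#' @return List with `corpus` (an `"annotation_corpus"`), `annotation`
#'   (function term -> gene data.frame), `truth` (planted structure:
#'   per-module phenotypes/genes/function/diseases, all planted
#'   phenotype-phenotype and phenotype-function pairs), and `labels`.
#' @export
generate_corpus <- function(params = sim_params(), seed = 1) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(child_seed(seed, 1L))
  p <- params
  d_in <- pad_id("D:IN", seq_len(p$n_diseases_in))
  d_out <- pad_id("D:OUT", seq_len(p$n_diseases_out))
  bg_phen <- pad_id("HP:BG", seq_len(p$n_background_phenotypes))
  bg_gene <- pad_id("GBG", seq_len(p$n_background_genes))

  modules <- list()
  if (p$n_phen_modules > 0) {
    for (m in seq_len(p$n_phen_modules)) {
      modules[[m]] <- list(
        id = m,
        phenotypes = sprintf("HP:M%02d.%d", m, seq_len(p$module_size)),
        genes = sprintf("GM%02d.%d", m, seq_len(p$n_genes_per_function)),
        func = sprintf("F:M%02d", m),
        diseases = d_in[(seq_along(d_in) - 1L) %% p$n_phen_modules + 1L == m]
      )
    }
  }
  module_of <- if (p$n_phen_modules > 0) {
    (seq_along(d_in) - 1L) %% p$n_phen_modules + 1L
  } else rep(NA_integer_, length(d_in))

  draw <- function(pool, prob) pool[stats::runif(length(pool)) < prob]
  pp <- list(); gp <- list()
  for (i in seq_along(d_in)) {
    m <- module_of[i]
    phen <- draw(bg_phen, p$background_annotation_prob)
    gene <- draw(bg_gene, p$background_gene_prob)
    if (!is.na(m)) {
      phen <- c(draw(modules[[m]]$phenotypes, p$within_module_annotation_prob), phen)
      gene <- c(draw(modules[[m]]$genes, p$gene_disease_prob), gene)
      if (length(phen) == 0L) phen <- modules[[m]]$phenotypes[1]
      if (length(gene) == 0L) gene <- modules[[m]]$genes[1]
    }
    if (length(phen) == 0L) phen <- sample(bg_phen, 1L)
    if (length(gene) == 0L) gene <- sample(bg_gene, 1L)
    pp[[i]] <- data.frame(disease_id = d_in[i], phenotype_id = phen,
                          stringsAsFactors = FALSE)
    gp[[i]] <- data.frame(disease_id = d_in[i], gene = gene,
                          stringsAsFactors = FALSE)
  }
  for (i in seq_along(d_out)) {
    phen <- draw(bg_phen, p$background_annotation_prob)
    gene <- draw(bg_gene, p$background_gene_prob)
    if (length(phen) == 0L) phen <- sample(bg_phen, 1L)
    if (length(gene) == 0L) gene <- sample(bg_gene, 1L)
    pp[[length(d_in) + i]] <- data.frame(disease_id = d_out[i], phenotype_id = phen,
                                         stringsAsFactors = FALSE)
    gp[[length(d_in) + i]] <- data.frame(disease_id = d_out[i], gene = gene,
                                         stringsAsFactors = FALSE)
  }
  phenotype_pairs <- do.call(rbind, pp)
  gene_pairs <- do.call(rbind, gp)

  labels <- stats::setNames(c(rep("IN_CLASS", length(d_in)),
                              rep("OUT_CLASS", length(d_out))),
                            c(d_in, d_out))
  titles <- stats::setNames(
    c(sprintf("Synthetic myopathy, type %d", seq_along(d_in)),
      sprintf("Synthetic disorder %d", seq_along(d_out))),
    c(d_in, d_out))

  # function annotation: one term per module plus decoy terms covering every
  # background gene (so the default ORA universe includes them)
  ann <- list()
  for (m in modules) {
    ann[[length(ann) + 1L]] <- data.frame(term_id = m$func, gene = m$genes,
                                          stringsAsFactors = FALSE)
  }
  if (p$n_background_functions > 0 && p$n_background_genes > 0) {
    base_assign <- (seq_along(bg_gene) - 1L) %% p$n_background_functions + 1L
    ann[[length(ann) + 1L]] <- data.frame(
      term_id = sprintf("F:BG%02d", base_assign), gene = bg_gene,
      stringsAsFactors = FALSE)
    for (f in seq_len(p$n_background_functions)) {
      extra <- sample(bg_gene, min(p$background_function_size, length(bg_gene)))
      ann[[length(ann) + 1L]] <- data.frame(term_id = sprintf("F:BG%02d", f),
                                            gene = extra, stringsAsFactors = FALSE)
    }
  }
  annotation <- unique(do.call(rbind, ann))
  rownames(annotation) <- NULL

  planted_phen_pairs <- do.call(rbind, lapply(modules, function(m) {
    if (length(m$phenotypes) < 2) return(NULL)
    cmb <- utils::combn(sort(m$phenotypes), 2)
    data.frame(item_a = cmb[1, ], item_b = cmb[2, ], module = m$id,
               stringsAsFactors = FALSE)
  }))
  planted_phen_func <- do.call(rbind, lapply(modules, function(m) {
    data.frame(phenotype_id = m$phenotypes, term_id = m$func, module = m$id,
               stringsAsFactors = FALSE)
  }))

  corpus <- build_corpus(phenotype_pairs, gene_pairs, labels, titles)
  list(corpus = corpus, annotation = annotation,
       truth = list(modules = modules,
                    phenotype_pairs = planted_phen_pairs,
                    phenotype_function_pairs = planted_phen_func,
                    background_phenotypes = bg_phen,
                    background_genes = bg_gene),
       labels = labels, titles = titles)
}

#' Generate a synthetic literature co-mention index
#'
#' Every term (planted module phenotypes and function terms) is mentioned in
#' each document independently at the base rate; planted within-module pairs
#' (phenotype-phenotype and phenotype-function) additionally receive joint
#' mentions so their co-mention probability is lifted by `comention_lift`
#' over the product of marginals. All other pairs co-mention independently,
#' so their Fisher tests are significant at about the nominal rate.
#'
#' @param truth The `truth` element of [generate_corpus()].
#' @param params A [sim_params()] object.
#' @param seed Integer seed.
#' @return A `"term_corpus_index"`.
#' @export
generate_literature_index <- function(truth, params = sim_params(), seed = 1) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(child_seed(seed, 2L))
  p <- params
  terms <- unique(c(unlist(lapply(truth$modules, `[[`, "phenotypes")),
                    vapply(truth$modules, `[[`, "", "func")))
  doc_ids <- as.character(seq_len(p$corpus_size))
  docs <- lapply(stats::setNames(terms, terms), function(t) {
    doc_ids[stats::runif(p$corpus_size) < p$base_mention_rate]
  })
  planted <- rbind(
    stats::setNames(truth$phenotype_pairs[c("item_a", "item_b")], c("a", "b")),
    stats::setNames(truth$phenotype_function_pairs[c("phenotype_id", "term_id")],
                    c("a", "b")))
  extra_rate <- (p$comention_lift - 1) * p$base_mention_rate^2
  for (i in seq_len(nrow(planted))) {
    n_extra <- stats::rbinom(1, p$corpus_size, extra_rate)
    if (n_extra > 0) {
      joint <- sample(doc_ids, n_extra)
      docs[[planted$a[i]]] <- unique(c(docs[[planted$a[i]]], joint))
      docs[[planted$b[i]]] <- unique(c(docs[[planted$b[i]]], joint))
    }
  }
  term_corpus_index(docs, p$corpus_size)
}
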