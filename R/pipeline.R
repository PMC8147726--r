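# End-to-end orchestration: typical phenotypes -> co-occurrence network ->
# phenotype-gene associations -> per-phenotype enrichment -> link communities
# -> coherent clusters, with artifacts written as deterministic TSV/JSON and
# a thin HTML report that only re-prints artifact content.

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10, pretty = TRUE)
}

#' Run the full phenotype-clustering pipeline
#'
#' Executes every stage on an annotation corpus and writes the artifact
#' directory: `typical_phenotypes.tsv`, `pairs_significant.tsv` (typical
#' co-occurring phenotype pairs), `phen_gene.tsv` (significant
#' phenotype-gene associations), `enrichment.tsv` (phenotype-function
#' pairs), `communities.tsv` + `communities_summary.tsv`,
#' `coherent_clusters.json`, optionally `controls_summary.tsv`
#' (prevalence-matched null contrast), `run_metadata.json` and
#' `report.html`. Reruns with the same inputs and seed produce byte-identical
#' artifacts.
#'
#' @param corpus An `"annotation_corpus"`.
#' @param annotation Function-term annotation data.frame (`term_id`, `gene`).
#' @param out_dir Output directory (created if missing).
#' @param alpha Typical-phenotype significance threshold (default 0.05).
#' @param hyi_threshold Hypergeometric-index cut-off (default 2).
#' @param coherence_threshold Shared-function coverage fraction (default 0.7).
#' @param min_gs_size,max_gs_size ORA term-size bounds.
#' @param controls If `TRUE`, run the prevalence-matched null contrast on the
#'   significant-pair count.
#' @param n_control_reps Null replicates for the contrast (default 20; the
#'   full-scale contrast uses 100).
#' @param seed Integer seed (used by the control resampling).
#' @return Invisibly, a list with every stage result and `out_dir`.
#' @export
run_pipeline <- function(corpus, annotation, out_dir,
                         alpha = 0.05, hyi_threshold = 2.0,
                         coherence_threshold = 0.7,
                         min_gs_size = 10, max_gs_size = 500,
                         controls = TRUE, n_control_reps = 20, seed = 1) {
  stopifnot(inherits(corpus, "annotation_corpus"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  typical <- typical_phenotypes(corpus, alpha = alpha)
  assoc <- project_associations(corpus$phenotype_pairs)
  sig <- significant_pairs(assoc, hyi_threshold)
  typ_pairs <- restrict_to_typical(sig, typical$phenotype_id)

  pg <- phenotype_gene_associations(corpus)
  pg_sig <- significant_pairs(pg, hyi_threshold)
  pg_typ <- pg_sig[pg_sig$phenotype_id %in% typical$phenotype_id, ]
  enrich <- phenotype_function_pairs(pg_typ, annotation,
                                     min_gs_size = min_gs_size,
                                     max_gs_size = max_gs_size)

  if (nrow(typ_pairs) > 0) {
    communities <- cluster_links(typ_pairs[, c("item_a", "item_b")])
    clusters <- coherent_clusters(communities, enrich, coherence_threshold)
  } else {
    communities <- NULL
    clusters <- list()
  }

  cluster_json <- lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    genes <- cluster_gene_support(cl, pg_typ)
    list(cluster_id = i, community = cl$community,
         phenotypes = as.list(cl$phenotypes),
         coverage = cl$coverage,
         shared_terms = lapply(seq_len(nrow(cl$shared_terms)), function(j)
           as.list(cl$shared_terms[j, ])),
         supporting_genes = lapply(seq_len(nrow(genes)), function(j)
           as.list(genes[j, ])))
  })

  controls_summary <- NULL
  if (controls && nrow(typical) > 0) {
    prevalence <- table(corpus$phenotype_pairs$phenotype_id)
    cand_ids <- setdiff(names(prevalence), typical$phenotype_id)
    tgt <- stats::setNames(as.numeric(prevalence[typical$phenotype_id]),
                           typical$phenotype_id)
    cand <- stats::setNames(as.numeric(prevalence[cand_ids]), cand_ids)
    if (length(cand) >= length(tgt)) {
      sets <- suppressWarnings(prevalence_matched_sample(
        cand, tgt, n_reps = n_control_reps, seed = child_seed(seed, 3L)))
      null_counts <- vapply(sets, function(s)
        sum(sig$item_a %in% s & sig$item_b %in% s), 0L)
      cmp <- empirical_comparison(nrow(typ_pairs), null_counts)
      controls_summary <- data.frame(
        contrast = "significant_in_class_pairs_vs_prevalence_matched",
        observed = cmp$observed, null_mean = cmp$mean, null_sd = cmp$sd,
        empirical_p = cmp$empirical_p, n_reps = cmp$n_reps)
    }
  }

  write_tsv(typical, file.path(out_dir, "typical_phenotypes.tsv"))
  write_tsv(typ_pairs, file.path(out_dir, "pairs_significant.tsv"))
  write_tsv(pg_sig, file.path(out_dir, "phen_gene.tsv"))
  write_tsv(enrich, file.path(out_dir, "enrichment.tsv"))
  if (!is.null(communities)) {
    memb <- data.frame(
      community = rep(communities$summary$community,
                      communities$summary$n_nodes),
      node = unlist(lapply(communities$communities, `[[`, "nodes")))
    write_tsv(memb, file.path(out_dir, "communities.tsv"))
    write_tsv(communities$summary, file.path(out_dir, "communities_summary.tsv"))
  } else {
    write_tsv(data.frame(community = integer(0), node = character(0)),
              file.path(out_dir, "communities.tsv"))
    write_tsv(data.frame(community = integer(0), n_nodes = integer(0),
                         n_edges = integer(0), small = logical(0)),
              file.path(out_dir, "communities_summary.tsv"))
  }
  write_json_file(cluster_json, file.path(out_dir, "coherent_clusters.json"))
  if (!is.null(controls_summary)) {
    write_tsv(controls_summary, file.path(out_dir, "controls_summary.tsv"))
  }
  write_json_file(
    list(package = "phenolink",
         version = as.character(utils::packageVersion("phenolink")),
         seed = seed,
         thresholds = list(alpha = alpha, hyi = hyi_threshold,
                           coherence = coherence_threshold,
                           min_gs_size = min_gs_size,
                           max_gs_size = max_gs_size),
         counts = as.list(corpus$counts),
         partition_density = if (is.null(communities)) NA else
           communities$partition_density,
         cut_height = if (is.null(communities)) NA else communities$cut_height,
         n_communities = if (is.null(communities)) 0L else
           length(communities$communities),
         n_coherent_clusters = length(clusters)),
    file.path(out_dir, "run_metadata.json"))
  render_report(out_dir)

  invisible(list(out_dir = out_dir, typical = typical, associations = assoc,
                 significant = sig, typical_pairs = typ_pairs,
                 phen_gene = pg_sig, enrichment = enrich,
                 communities = communities, clusters = clusters,
                 controls = controls_summary))
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

html_table <- function(df) {
  if (nrow(df) == 0L) return("<p><em>empty</em></p>")
  hdr <- paste0("<tr>", paste0("<th>", html_escape(names(df)), "</th>",
                               collapse = ""), "</tr>")
  rows <- apply(df, 1, function(r)
    paste0("<tr>", paste0("<td>", html_escape(as.character(r)), "</td>",
                          collapse = ""), "</tr>"))
  paste0("<table border='1' cellspacing='0' cellpadding='3'>", hdr,
         paste(rows, collapse = "\n"), "</table>")
}

#' Render the HTML report from an artifact directory
#'
#' A pure renderer: every number shown is read back from the TSV/JSON
#' artifacts written by [run_pipeline()]; nothing is recomputed. Coherent
#' clusters come first, each with its phenotypes, shared function terms
#' (with coverage) and supporting genes.
#'
#' @param out_dir Artifact directory.
#' @return Invisibly, the report path.
#' @export
render_report <- function(out_dir) {
  read_tsv <- function(f) {
    path <- file.path(out_dir, f)
    if (!file.exists(path)) return(NULL)
    utils::read.delim(path, stringsAsFactors = FALSE)
  }
  meta <- jsonlite::read_json(file.path(out_dir, "run_metadata.json"))
  clusters <- jsonlite::read_json(file.path(out_dir, "coherent_clusters.json"))
  parts <- c(
    "<html><head><meta charset='utf-8'><title>phenotype cluster report</title></head><body>",
    "<h1>Phenotype co-occurrence cluster report</h1>",
    sprintf("<p>phenolink %s; seed %s; HyI &ge; %s; coherence &ge; %s; alpha %s</p>",
            meta$version, meta$seed, meta$thresholds$hyi,
            meta$thresholds$coherence, meta$thresholds$alpha),
    sprintf("<p>%s communities; %s functionally coherent clusters; partition density %s at cut height %s</p>",
            meta$n_communities, meta$n_coherent_clusters,
            meta$partition_density, meta$cut_height),
    "<h2>Functionally coherent clusters</h2>")
  for (cl in clusters) {
    parts <- c(parts,
      sprintf("<h3>Cluster %s (community %s, coverage %s)</h3>",
              cl$cluster_id, cl$community, cl$coverage),
      sprintf("<p>Phenotypes: %s</p>",
              html_escape(paste(unlist(cl$phenotypes), collapse = ", "))),
      "<h4>Shared function terms</h4>",
      html_table(do.call(rbind, lapply(cl$shared_terms, as.data.frame))),
      "<h4>Supporting genes</h4>",
      html_table(do.call(rbind, lapply(cl$supporting_genes, as.data.frame))))
  }
  if (length(clusters) == 0L) parts <- c(parts, "<p><em>none</em></p>")
  summaries <- list(
    "Community summary" = read_tsv("communities_summary.tsv"),
    "Typical phenotypes" = read_tsv("typical_phenotypes.tsv"),
    "Null-model contrast" = read_tsv("controls_summary.tsv"))
  for (nm in names(summaries)) {
    if (is.null(summaries[[nm]])) next
    parts <- c(parts, sprintf("<h2>%s</h2>", nm), html_table(summaries[[nm]]))
  }
  parts <- c(parts, "</body></html>")
  path <- file.path(out_dir, "report.html")
  writeLines(parts, path)
  invisible(path)
}
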