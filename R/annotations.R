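#' Read an annotation pair table
#'
#' Two dialects are supported:
#' \describe{
#'   \item{`pair_tsv`}{generic two-column tab-separated file: `id_a<TAB>id_b`,
#'     `#` comment lines, no header. Column meaning is set by `kind`.}
#'   \item{`hpoa`}{phenotype.hpoa-style layout: tab-separated with a header
#'     whose columns include `database_id`, `qualifier` and `hpo_id` (the
#'     2019-era positional layout `DatabaseID Disease_Name Qualifier HPO_ID ...`
#'     is also accepted when no header is present). Rows whose qualifier is
#'     `NOT` are negative annotations and are dropped.}
#' }
#' Duplicate pairs are collapsed.
#'
#' @param path File path or character vector of lines.
#' @param dialect `"pair_tsv"` or `"hpoa"`.
#' @param kind What the pair relates; sets the output column names. One of
#'   `"disease_phenotype"`, `"disease_gene"`, `"gene_function"`,
#'   `"term_pmids"`.
#' @return A two-column character data.frame of unique pairs.
#' @export
parse_annotations <- function(path,
                              dialect = c("pair_tsv", "hpoa"),
                              kind = c("disease_phenotype", "disease_gene",
                                       "gene_function", "term_pmids")) {
  dialect <- match.arg(dialect)
  kind <- match.arg(kind)
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path, warn = FALSE) else path
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  cols <- switch(kind,
    disease_phenotype = c("disease_id", "phenotype_id"),
    disease_gene      = c("disease_id", "gene"),
    gene_function     = c("term_id", "gene"),
    term_pmids        = c("term_id", "pmid")
  )
  if (length(lines) == 0L) {
    out <- data.frame(a = character(0), b = character(0), stringsAsFactors = FALSE)
    names(out) <- cols
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (dialect == "pair_tsv") {
    bad <- which(lengths(fields) != 2L)
    if (length(bad)) {
      stop(sprintf("row %d: expected 2 tab-separated columns, found %d",
                   bad[1], length(fields[[bad[1]]])))
    }
    a <- vapply(fields, `[`, "", 1L)
    b <- vapply(fields, `[`, "", 2L)
  } else {
    header <- tolower(fields[[1]])
    if (any(grepl("database", header)) && any(grepl("hpo", header))) {
      i_db <- grep("database", header)[1]
      i_q <- grep("qualifier", header)[1]
      i_hpo <- grep("hpo", header)[1]
      fields <- fields[-1]
    } else {
      # positional fallback: DatabaseID, DiseaseName, Qualifier, HPO_ID, ...
      i_db <- 1L; i_q <- 3L; i_hpo <- 4L
    }
    need <- max(i_db, i_q, i_hpo, na.rm = TRUE)
    bad <- which(lengths(fields) < need)
    if (length(bad)) {
      stop(sprintf("row %d: hpoa record has %d columns, needs at least %d",
                   bad[1], length(fields[[bad[1]]]), need))
    }
    qual <- if (is.na(i_q)) rep("", length(fields)) else vapply(fields, `[`, "", i_q)
    keep <- toupper(qual) != "NOT"
    a <- vapply(fields, `[`, "", i_db)[keep]
    b <- vapply(fields, `[`, "", i_hpo)[keep]
  }
  out <- unique(data.frame(a = a, b = b, stringsAsFactors = FALSE))
  names(out) <- cols
  rownames(out) <- NULL
  out
}
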