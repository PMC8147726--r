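#' Parse an OBO ontology file
#'
#' Minimal reader for the OBO flat-file format as used by the Human Phenotype
#' Ontology and disease-classification ontologies: it collects `[Term]`
#' stanzas with their `id`, `name`, `synonym`, `alt_id` and `is_a` tags.
#' Obsolete terms (`is_obsolete: true`) are dropped; their ids do not resolve.
#' `alt_id`s resolve to their primary id via [resolve_term()]. Parent links
#' referencing unknown terms are kept and recorded in `dangling` rather than
#' treated as fatal.
#'
#' @param path Path to an OBO file, or a character vector of OBO lines.
#' @return An object of class `"ontology"`: a list with
#'   \describe{
#'     \item{terms}{named list, id -> list(id, name, synonyms, parents)}
#'     \item{alt}{named character vector mapping alt ids to primary ids}
#'     \item{roots}{ids with no parents}
#'     \item{dangling}{parent ids referenced but never defined}
#'   }
#' @export
parse_obo <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path, warn = FALSE) else path
  lines <- sub("\\s+$", "", lines)
  # split into stanzas; only [Term] stanzas carry ontology terms
  stanza_start <- grep("^\\[", lines)
  if (length(stanza_start) == 0L) stop("no stanzas found: not an OBO file?")
  bounds <- c(stanza_start, length(lines) + 1L)
  terms <- list()
  alt <- character(0)
  for (i in seq_along(stanza_start)) {
    head_line <- lines[stanza_start[i]]
    if (head_line != "[Term]") next
    body <- lines[seq(stanza_start[i] + 1L, bounds[i + 1L] - 1L)]
    body <- body[nzchar(body)]
    tag_split <- regmatches(body, regexpr(": ", body), invert = TRUE)
    bad <- which(lengths(tag_split) != 2L)
    if (length(bad)) {
      stop(sprintf("malformed OBO tag line %d: '%s'",
                   stanza_start[i] + bad[1], body[bad[1]]))
    }
    tags <- vapply(tag_split, `[`, "", 1L)
    vals <- vapply(tag_split, `[`, "", 2L)
    if (any(tags == "is_obsolete" & vals == "true")) next
    id <- vals[tags == "id"][1]
    if (is.na(id)) stop(sprintf("[Term] stanza at line %d has no id", stanza_start[i]))
    syn <- vals[tags == "synonym"]
    # synonym values are quoted strings with trailing scope/xrefs
    syn <- sub('^"(.*)".*$', "\\1", syn)
    parents <- vals[tags == "is_a"]
    parents <- sub("\\s*!.*$", "", parents)  # strip trailing '! name' comments
    terms[[id]] <- list(
      id = id,
      name = if (any(tags == "name")) vals[tags == "name"][1] else NA_character_,
      synonyms = unname(syn),
      parents = unname(parents)
    )
    for (a in vals[tags == "alt_id"]) alt[[a]] <- id
  }
  all_parents <- unique(unlist(lapply(terms, `[[`, "parents")))
  onto <- structure(
    list(
      terms = terms,
      alt = alt,
      roots = names(terms)[vapply(terms, function(t) length(t$parents) == 0L, TRUE)],
      dangling = setdiff(all_parents, names(terms))
    ),
    class = "ontology"
  )
  onto
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("<ontology> %d terms, %d roots, %d alt ids, %d dangling parents\n",
              length(x$terms), length(x$roots), length(x$alt), length(x$dangling)))
  invisible(x)
}

#' Resolve a term id (following alt_id redirects)
#'
#' @param ontology An `"ontology"` object.
#' @param id Character vector of term ids (primary or alternative).
#' @return Character vector of primary ids; `NA` where the id is unknown or
#'   obsolete.
#' @export
resolve_term <- function(ontology, id) {
  out <- ifelse(id %in% names(ontology$terms), id,
                unname(ontology$alt[id]))
  out[!out %in% names(ontology$terms)] <- NA_character_
  out
}

#' Test descent from a root term
#'
#' A term "reaches" the root if the root is on some `is_a` path upward from
#' it; a term reaches itself (reflexive). Used to label diseases whose
#' classification term lies under a class root such as the neuromuscular
#' branch of a disease ontology.
#'
#' @param ontology An `"ontology"` object.
#' @param ids Character vector of term ids to test.
#' @param root Root term id.
#' @return Logical vector, one entry per element of `ids`.
#' @export
term_descends_from <- function(ontology, ids, root) {
  if (!root %in% names(ontology$terms)) stop(sprintf("root term '%s' not in ontology", root))
  desc <- ontology_descendants(ontology, root)
  resolve_term(ontology, ids) %in% desc
}

#' All descendants of a term (including the term itself)
#'
#' @param ontology An `"ontology"` object.
#' @param root Term id.
#' @return Character vector of term ids in the `is_a` closure below `root`.
#' @export
ontology_descendants <- function(ontology, root) {
  children <- split(
    rep(names(ontology$terms), vapply(ontology$terms, function(t) length(t$parents), 0L)),
    unlist(lapply(ontology$terms, `[[`, "parents"))
  )
  seen <- character(0)
  frontier <- root
  while (length(frontier)) {
    seen <- c(seen, frontier)
    frontier <- setdiff(unique(unlist(children[frontier], use.names = FALSE)), seen)
  }
  seen
}
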