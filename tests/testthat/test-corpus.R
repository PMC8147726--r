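test_that("OBO parsing handles is_a, alt_id, synonyms and obsolete terms", {
  ont <- parse_obo(minimal_obo())
  expect_length(ont$terms, 4)                       # obsolete term dropped
  expect_false("T:005" %in% names(ont$terms))
  expect_equal(resolve_term(ont, "T:902"), "T:002") # alt id resolves
  expect_equal(ont$terms[["T:002"]]$parents, "T:001")
  expect_equal(ont$terms[["T:002"]]$synonyms, "child synonym")
  expect_setequal(ont$roots, c("T:001", "T:004"))
  expect_error(parse_obo(c("[Term]", "id: X:1", "no-colon-line")), "malformed")
})

test_that("descendant queries follow is_a transitively and reflexively", {
  ont <- parse_obo(minimal_obo())
  expect_true(term_descends_from(ont, "T:001", "T:001"))   # reflexive
  expect_true(term_descends_from(ont, "T:003", "T:001"))   # two hops
  expect_false(term_descends_from(ont, "T:004", "T:001"))  # disjoint branch
})

test_that("pair_tsv annotation parsing collapses duplicates and comments", {
  lines <- c("# comment", "d1\tHP:1", "d1\tHP:1", "d2\tHP:2")
  tab <- parse_annotations(lines, "pair_tsv", "disease_phenotype")
  expect_equal(nrow(tab), 2)
  expect_named(tab, c("disease_id", "phenotype_id"))
  expect_equal(nrow(parse_annotations("# only a comment", "pair_tsv",
                                      "disease_phenotype")), 0)
  expect_error(parse_annotations("a\tb\tc", "pair_tsv", "disease_gene"),
               "row 1")
})

test_that("hpoa dialect drops NOT-qualified rows", {
  lines <- c(
    "database_id\tdisease_name\tqualifier\thpo_id",
    "OMIM:1\tfoo\t\tHP:0000001",
    "OMIM:1\tfoo\tNOT\tHP:0000002",
    "OMIM:2\tbar\t\tHP:0000001")
  tab <- parse_annotations(lines, "hpoa", "disease_phenotype")
  expect_equal(nrow(tab), 2)
  expect_false("HP:0000002" %in% tab$phenotype_id)
  # positional layout without a header
  tab2 <- parse_annotations(c("OMIM:3\tbaz\t\tHP:0000009\textra"), "hpoa",
                            "disease_phenotype")
  expect_equal(tab2$phenotype_id, "HP:0000009")
})

test_that("keyword labelling is a case-insensitive substring match on titles", {
  titles <- c(d1 = "Muscular dystrophy, Duchenne type",
              d2 = "Cystic fibrosis",
              d3 = "MYOPATHY, DISTAL, 1")
  lab <- classify_by_keywords(titles)
  expect_equal(unname(lab), c("IN_CLASS", "OUT_CLASS", "IN_CLASS"))
  # alternative titles count too
  lab2 <- classify_by_keywords(c(d4 = "Some disease"),
                               alt_titles = list(d4 = "congenital myasthenia"))
  expect_equal(unname(lab2), "IN_CLASS")
  expect_length(nmd_keywords(), 14)
})

test_that("descendant labelling uses the classification ontology", {
  ont <- parse_obo(minimal_obo())
  dt <- c(d1 = "T:001", d2 = "T:003", d3 = "T:004")
  lab <- classify_by_descendants(dt, ont, "T:001")
  expect_equal(unname(lab[c("d1", "d2", "d3")]),
               c("IN_CLASS", "IN_CLASS", "OUT_CLASS"))
  expect_warning(
    lab2 <- classify_by_descendants(dt, ont, "T:001",
                                    disease_ids = c(names(dt), "d4")),
    "no classification term")
  expect_equal(unname(lab2["d4"]), "OUT_CLASS")
})

test_that("corpus filtering keeps only diseases with phenotypes and genes", {
  pp <- data.frame(disease_id = c("d1", "d2", "d3", "d4", "d5"),
                   phenotype_id = paste0("P", 1:5))
  gp <- data.frame(disease_id = c("d1", "d2", "d3"), gene = c("G1", "G2", "G3"))
  labels <- setNames(rep("OUT_CLASS", 5), paste0("d", 1:5))
  corpus <- build_corpus(pp, gp, labels)
  expect_equal(corpus$counts[["complete"]], 3)       # 2 of 5 lack genes
  expect_setequal(corpus$diseases$disease_id, c("d1", "d2", "d3"))
  # idempotence: rebuilding from the filtered pairs changes nothing
  corpus2 <- build_corpus(corpus$phenotype_pairs, corpus$gene_pairs, labels)
  expect_identical(corpus$diseases, corpus2$diseases)
  expect_identical(corpus$phenotype_pairs, corpus2$phenotype_pairs)
  expect_error(build_corpus(pp[1, ], gp[2, ], labels), "empty corpus")
})

test_that("typical phenotypes are one-tail enriched in the in-class diseases", {
  corpus <- toy_corpus()
  typ <- typical_phenotypes(corpus, alpha = 0.05)
  # P1, P2 in 5/5 in-class, 0/5 out-of-class: p = 1/252
  expect_setequal(typ$phenotype_id, c("P1", "P2"))
  expect_equal(typ$p, rep(1 / 252, 2), tolerance = 1e-12)
  # P3 absent from in-class diseases: p = 1, never typical
  all_p <- typical_phenotypes(corpus, alpha = 1)
  expect_equal(all_p$p[all_p$phenotype_id == "P3"], 1)
  # 3/5 vs 1/5 example
  pp <- data.frame(
    disease_id = c(paste0("i", 1:5), paste0("o", 1:5), "i1", "i2", "i3", "o1"),
    phenotype_id = c(rep("X", 10), rep("Q", 4)))
  gp <- data.frame(disease_id = c(paste0("i", 1:5), paste0("o", 1:5)),
                   gene = "G")
  labels <- setNames(rep(c("IN_CLASS", "OUT_CLASS"), each = 5),
                     c(paste0("i", 1:5), paste0("o", 1:5)))
  res <- typical_phenotypes(build_corpus(pp, gp, labels), alpha = 1)
  expect_equal(res$p[res$phenotype_id == "Q"], 66 / 252, tolerance = 1e-12)
  expect_false("Q" %in% typical_phenotypes(build_corpus(pp, gp, labels))$phenotype_id)
})

test_that("inverting the class labels yields a disjoint typical set", {
  corpus <- toy_corpus()
  flipped <- corpus
  flipped$diseases$label <- ifelse(corpus$diseases$label == "IN_CLASS",
                                   "OUT_CLASS", "IN_CLASS")
  t1 <- typical_phenotypes(corpus)
  t2 <- typical_phenotypes(flipped)
  expect_length(intersect(t1$phenotype_id, t2$phenotype_id), 0)
})
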