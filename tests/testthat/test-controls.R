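test_that("term queries collect name and synonyms, lower-cased and deduplicated", {
  ont <- parse_obo(c("[Term]", "id: T:1", "name: Muscle weakness",
                     'synonym: "muscular weakness" EXACT []',
                     'synonym: "Muscle Weakness" EXACT []'))
  q <- build_term_queries(ont, "T:1")
  expect_setequal(q, c("muscle weakness", "muscular weakness"))
  ont2 <- parse_obo(c("[Term]", "id: T:2"))
  expect_error(build_term_queries(ont2, "T:2"), "no name")
})

test_that("co-mention test builds the 2x2 by set algebra", {
  # both=3, a_only=2, b_only=2, neither=3 -> p = 0.5
  r <- comention_test(c(1:5), c(1:3, 6:7), 10)
  expect_equal(unlist(r[c("both", "a_only", "b_only", "neither")]),
               c(both = 3, a_only = 2, b_only = 2, neither = 3))
  expect_equal(r$p, 0.5, tolerance = 1e-12)
  # disjoint sets: P(X >= 0) = 1
  expect_equal(comention_test(1:3, 4:6, 10)$p, 1.0)
  # identical 5-document sets in a 10-document corpus: p = 1/252
  expect_equal(comention_test(1:5, 1:5, 10)$p, 1 / 252, tolerance = 1e-12)
  expect_error(comention_test(1:8, 9:12, 10), "corpus_size")
  # delegation: equals the one-tailed Fisher test on the identical table
  expect_equal(comention_test(1:6, 4:12, 40)$p,
               fisher_one_tail(3, 3, 6, 28), tolerance = 1e-12)
})

test_that("prevalence-matched sampling reproduces the target histogram", {
  set.seed(61)
  candidates <- setNames(c(rep(5, 30), rep(10, 30), rep(50, 30)),
                         paste0("c", 1:90))
  targets <- setNames(c(5, 10), c("t1", "t2"))
  sets <- prevalence_matched_sample(candidates, targets, n_reps = 100, seed = 9)
  expect_length(sets, 100)
  for (s in sets[1:20]) {
    expect_length(s, 2)
    expect_setequal(sort(unname(candidates[s])), c(5, 10))
  }
  # seeded: identical across runs
  again <- prevalence_matched_sample(candidates, targets, n_reps = 100, seed = 9)
  expect_identical(sets, again)
  # bin-for-bin histogram match on a richer case
  cand2 <- setNames(sample(1:100, 500, replace = TRUE), paste0("c", 1:500))
  tgt2 <- setNames(sample(1:100, 40, replace = TRUE), paste0("t", 1:40))
  breaks <- unique(quantile(cand2, probs = seq(0, 1, 0.1)))
  bin <- function(x) findInterval(x, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE)
  reps <- prevalence_matched_sample(cand2, tgt2, n_reps = 5, seed = 10)
  for (s in reps) {
    expect_equal(table(factor(bin(unname(cand2[s])), levels = 1:10)),
                 table(factor(bin(unname(tgt2)), levels = 1:10)))
  }
})

test_that("degree-preserving shuffle keeps degree multisets byte-identical", {
  # two pairs: identity or the one legal swap, degrees always 1
  p2 <- data.frame(l = c("p1", "p2"), r = c("f1", "f2"))
  s2 <- degree_preserving_shuffle(p2, seed = 1)
  expect_true(setequal(paste(s2$l, s2$r), c("p1 f1", "p2 f2")) ||
                setequal(paste(s2$l, s2$r), c("p1 f2", "p2 f1")))
  # single pair and stars admit no legal swap
  expect_identical(degree_preserving_shuffle(p2[1, ], seed = 1), p2[1, ])
  star <- data.frame(l = rep("hub", 4), r = paste0("f", 1:4))
  expect_identical(degree_preserving_shuffle(star, seed = 1)$r, star$r)
  set.seed(62)
  for (rep in 1:200) {
    pairs <- unique(data.frame(l = paste0("L", sample(8, 25, TRUE)),
                               r = paste0("R", sample(10, 25, TRUE))))
    sh <- degree_preserving_shuffle(pairs)
    expect_identical(sort(table(pairs$l)), sort(table(sh$l)))
    expect_identical(as.vector(table(pairs$l)[sort(unique(pairs$l))]),
                     as.vector(table(sh$l)[sort(unique(sh$l))]))
    expect_identical(as.vector(table(pairs$r)[sort(unique(pairs$r))]),
                     as.vector(table(sh$r)[sort(unique(sh$r))]))
    expect_equal(nrow(unique(sh)), nrow(pairs))  # no duplicate pairs
  }
})

test_that("empirical comparison uses the add-one estimator", {
  r <- empirical_comparison(100, rep(50, 100))
  expect_equal(r$empirical_p, 1 / 101, tolerance = 1e-12)
  r2 <- empirical_comparison(10, rep(60, 100))
  expect_equal(r2$empirical_p, 1.0)
  r3 <- empirical_comparison(2, c(1, 2, 3))
  expect_equal(r3$empirical_p, 0.75)
  expect_equal(r3$mean, 2)
  expect_error(empirical_comparison(5, numeric(0)), "replicate")
})

test_that("tissue expression contrast counts medium/high rows in listed tissues", {
  expr <- data.frame(
    gene = c(paste0("A", 1:4), "A5", "B1", paste0("B", 2:5)),
    tissue = c(rep("skeletal muscle", 4), "liver", "cerebellum", rep("liver", 4)),
    cell_type = "myocytes",
    level = c(rep("High", 4), "High", "Medium", rep("High", 4)))
  r <- tissue_expression_test(paste0("A", 1:5), paste0("B", 1:5), expr)
  expect_equal(r$prop_a, 0.8)  # A1..A4 expressed, A5 only in liver
  expect_equal(r$prop_b, 0.2)  # only B1 (cerebellum Medium)
  expect_equal(r$p, 26 / 252, tolerance = 1e-12)
  expect_equal(r$p, stats::fisher.test(r$table,
                                       alternative = "greater")$p.value,
               tolerance = 1e-12)
  # identical sets: equal proportions, p well above significance
  same <- tissue_expression_test(paste0("A", 1:5), paste0("A", 1:5), expr)
  expect_equal(same$prop_a, same$prop_b)
  expect_gte(same$p, 0.5)
  # empty tissue list: nothing expressed, p = 1
  none <- suppressWarnings(
    tissue_expression_test(paste0("A", 1:5), paste0("B", 1:5), expr,
                           tissues = character(0)))
  expect_equal(none$prop_a, 0)
  expect_equal(none$p, 1)
  # unknown genes tallied in a warning
  expect_warning(tissue_expression_test(c("A1", "ZZ"), "B1", expr), "absent")
})

test_that("HPA-layout expression tables round-trip through the reader", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("Gene\tGene name\tTissue\tCell type\tLevel\tReliability",
               "ENSG1\tDMD\tskeletal muscle\tmyocytes\tHigh\tEnhanced",
               "ENSG2\tTTN\theart muscle\tcardiomyocytes\tMedium\tApproved"),
             tmp)
  tab <- read_hpa_expression(tmp)
  expect_equal(tab$gene, c("DMD", "TTN"))
  expect_equal(tab$level, c("High", "Medium"))
  r <- tissue_expression_test("DMD", "TTN", tab,
                              tissues = "skeletal muscle")
  expect_equal(r$prop_a, 1)
  expect_equal(r$prop_b, 0)
})
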