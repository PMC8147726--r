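# Independent oracles, deliberately naive: enumeration and hand-rolled
# formulas that never share code with the implementation they check.

# P(X >= x) by enumerating every C(N, n) draw of n items from a universe of
# N items whose first K are marked.
oracle_hyper_tail <- function(x, K, n, N) {
  if (n == 0) return(as.numeric(x <= 0))
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # items 1..K are the marked ones
  sum(hits >= x) / ncol(draws)
}

# Textbook BH step-up: sort ascending, p_(i) * m / i, cumulative min from the
# largest rank down, cap at 1, back to input order.
oracle_bh <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  pmin(adj, 1)[order(o)]
}

# Quadratic count of (pair, disease) co-incidences straight from the pair
# list: for every disease, every unordered phenotype pair it carries.
oracle_coincidence_total <- function(pairs) {
  per_disease <- split(pairs[[2]], pairs[[1]])
  sum(vapply(per_disease, function(ph) {
    k <- length(unique(ph)); k * (k - 1) / 2
  }, 0))
}

# Independent link-clustering pieces: inclusive-neighbourhood Jaccard for
# adjacent edges, partition density from scratch, and the best density over
# all similarity-threshold cuts (single-linkage partitions at height 1 - s
# are the components of the "similarity >= s" graph over edges).
oracle_edge_sim <- function(edges, i, j) {
  ends_i <- c(edges$a[i], edges$b[i]); ends_j <- c(edges$a[j], edges$b[j])
  shared <- intersect(ends_i, ends_j)
  if (length(shared) != 1) return(NA_real_)
  u <- setdiff(ends_i, shared); v <- setdiff(ends_j, shared)
  nbr <- function(x) unique(c(x, edges$b[edges$a == x], edges$a[edges$b == x]))
  length(intersect(nbr(u), nbr(v))) / length(union(nbr(u), nbr(v)))
}

oracle_density <- function(membership, edges) {
  M <- nrow(edges)
  total <- 0
  for (cid in unique(membership)) {
    idx <- which(membership == cid)
    m <- length(idx)
    n <- length(unique(c(edges$a[idx], edges$b[idx])))
    if (n > 2) total <- total + m * (m - n + 1) / ((n - 2) * (n - 1))
  }
  2 * total / M
}

# components of an undirected graph given an M x M logical adjacency
oracle_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cid <- 0
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1
    frontier <- s
    while (length(frontier)) {
      comp[frontier] <- cid
      frontier <- setdiff(which(rowSums(adj[, frontier, drop = FALSE]) > 0 &
                                  is.na(comp)), frontier)
    }
  }
  comp
}

oracle_best_cut_density <- function(edges) {
  M <- nrow(edges)
  if (M == 1) return(0)
  sim <- matrix(0, M, M)
  for (i in 1:(M - 1)) for (j in (i + 1):M) {
    s <- oracle_edge_sim(edges, i, j)
    if (!is.na(s)) sim[i, j] <- sim[j, i] <- s
  }
  thresholds <- sort(unique(c(sim[sim > 0], 1)))
  best <- -Inf
  for (s in thresholds) {
    adj <- sim >= s
    diag(adj) <- TRUE
    d <- oracle_density(oracle_components(adj), edges)
    if (d > best) best <- d
  }
  best
}

# small random simple graph as a canonical edge data.frame
random_edges <- function(n_nodes, n_edges) {
  all_pairs <- t(utils::combn(n_nodes, 2))
  pick <- all_pairs[sample.int(nrow(all_pairs), min(n_edges, nrow(all_pairs))), ,
                    drop = FALSE]
  data.frame(a = paste0("v", pick[, 1]), b = paste0("v", pick[, 2]),
             stringsAsFactors = FALSE)
}

# tiny hand-built corpus: 5 in-class diseases share phenotypes P1/P2 and gene
# G1; 5 out-of-class diseases carry P3 and G2; P4 is mixed background.
toy_corpus <- function() {
  pp <- data.frame(
    disease_id = c(rep(paste0("din", 1:5), each = 2), paste0("dout", 1:5),
                   "din1", "dout1"),
    phenotype_id = c(rep(c("P1", "P2"), 5), rep("P3", 5), "P4", "P4"),
    stringsAsFactors = FALSE)
  gp <- data.frame(
    disease_id = c(paste0("din", 1:5), paste0("dout", 1:5)),
    gene = c(rep("G1", 5), rep("G2", 5)),
    stringsAsFactors = FALSE)
  labels <- setNames(c(rep("IN_CLASS", 5), rep("OUT_CLASS", 5)),
                     c(paste0("din", 1:5), paste0("dout", 1:5)))
  build_corpus(pp, gp, labels)
}

minimal_obo <- function() c(
  "format-version: 1.2",
  "",
  "[Term]",
  "id: T:001",
  "name: root term",
  "",
  "[Term]",
  "id: T:002",
  "name: child term",
  "alt_id: T:902",
  'synonym: "child synonym" EXACT []',
  "is_a: T:001 ! root term",
  "",
  "[Term]",
  "id: T:003",
  "name: grandchild",
  "is_a: T:002",
  "",
  "[Term]",
  "id: T:004",
  "name: other branch",
  "",
  "[Term]",
  "id: T:005",
  "name: gone",
  "is_obsolete: true"
)
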