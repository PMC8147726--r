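#' Exact upper tail of the hypergeometric distribution
#'
#' Computes `P(X >= x)` for `X ~ Hypergeometric(N, K, n)`: the probability of
#' drawing at least `x` marked items when `n` items are drawn without
#' replacement from a universe of `N` items of which `K` are marked. This is
#' the exact kernel behind the one-tailed Fisher test and the hypergeometric
#' index; it is evaluated in log space via [stats::phyper()] so that very
#' small tails do not underflow.
#'
#' @param x Observed overlap (number of marked items drawn).
#' @param K Number of marked items in the universe.
#' @param n Number of items drawn.
#' @param N Universe size.
#' @return The tail probability, a value in `(0, 1]` whenever `x` is an
#'   attainable overlap (`max(0, n + K - N) <= x <= min(n, K)`).
#' @examples
#' hyper_tail(5, 5, 5, 10)   # 1/252
#' hyper_tail(0, 5, 5, 10)   # 1: the tail from the minimum overlap
#' @export
hyper_tail <- function(x, K, n, N) {
  stopifnot(length(x) == length(K) || length(K) == 1L || length(x) == 1L)
  if (any(N < 0) || any(K < 0) || any(n < 0) || any(K > N) || any(n > N)) {
    stop("inconsistent hypergeometric margins: need 0 <= K, n <= N")
  }
  if (any(x < pmax(0, n + K - N)) || any(x > pmin(n, K))) {
    stop("overlap x outside the attainable range [max(0, n+K-N), min(n, K)]")
  }
  # P(X >= x) = P(X > x - 1); phyper's white/black parametrisation
  stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
}

#' One-tailed Fisher exact test for enrichment of the joint cell
#'
#' Given the 2x2 contingency table
#' \preformatted{          in set   not in set
#'   positive     a          b
#'   negative     c          d}
#' returns the exact upper-tail p-value for enrichment of the `a` cell, i.e.
#' `P(X >= a)` for `X ~ Hypergeometric(N = a+b+c+d, K = a+b, n = a+c)`. This
#' is the one-sided alternative `fisher.test(..., alternative = "greater")`
#' computes, without the two-sided mass re-allocation.
#'
#' @param a,b,c,d Non-negative integer cell counts; `a` is the joint-positive
#'   cell whose enrichment is tested.
#' @return Exact p-value in `(0, 1]`.
#' @examples
#' fisher_one_tail(3, 2, 1, 4)  # 66/252
#' fisher_one_tail(3, 2, 2, 3)  # 0.5
#' @export
fisher_one_tail <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("contingency cells must be non-negative integers")
  }
  N <- a + b + c + d
  if (N == 0) stop("empty contingency table")
  hyper_tail(a, a + b, a + c, N)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper over [stats::p.adjust()] with `method = "BH"`, kept as a
#' named operation so every module adjusts p-values the same way. Returns
#' adjusted values in the original input order.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Hypergeometric index of an observed co-occurrence
#'
#' The hypergeometric index (HyI) of two nodes that share `shared` of their
#' middle-layer neighbours is `-log10 P(X >= shared)` under the hypergeometric
#' null in which the two neighbourhoods (sizes `deg_a`, `deg_b`) are drawn
#' independently from a universe of `universe` middle-layer nodes. HyI >= 2
#' therefore corresponds to a one-sided enrichment p <= 0.01, the default
#' significance cut-off for co-occurrence associations.
#'
#' @param shared Number of common middle-layer neighbours.
#' @param deg_a,deg_b Neighbourhood sizes of the two nodes.
#' @param universe Number of middle-layer nodes.
#' @return Non-negative numeric HyI value (0 when the tail is 1). Vectorised
#'   over its arguments.
#' @examples
#' hypergeometric_index(5, 5, 5, 10)   # ~2.40: passes the HyI >= 2 cut-off
#' hypergeometric_index(4, 5, 4, 10)   # ~1.62: fails it
#' @export
hypergeometric_index <- function(shared, deg_a, deg_b, universe) {
  if (any(universe <= 0)) stop("universe must be a positive count")
  # symmetric in (deg_a, deg_b); use log-scale tail to survive tiny p
  lp <- stats::phyper(shared - 1, deg_a, universe - deg_a, deg_b,
                      lower.tail = FALSE, log.p = TRUE)
  if (any(shared < pmax(0, deg_a + deg_b - universe)) ||
      any(shared > pmin(deg_a, deg_b))) {
    stop("shared count outside the attainable overlap range")
  }
  pmax(0, -lp / log(10))
}
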