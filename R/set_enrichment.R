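## Candidate-list intersection and overlap significance.  Identifier
## harmonization is an input contract: lists are compared exactly and
## case-sensitively.

#' Intersect two harmonized identifier lists
#'
#' @param a,b Character vectors of gene/protein identifiers (duplicates are
#'   collapsed; set semantics).
#' @return The sorted common identifiers.
#' @export
intersect_ids <- function(a, b) {
  sort(intersect(unique(a), unique(b)))
}

#' Upper tail of the hypergeometric overlap distribution
#'
#' `P[X >= k]` for `X ~ Hypergeometric(N, K, n)`: the probability of seeing
#' at least `k` common identifiers when a list of size `n` is drawn from a
#' universe of `N` identifiers of which `K` are in the other list.
#' Equivalent to a one-sided Fisher exact test on the 2x2 overlap table.
#'
#' @param k Observed intersection size.
#' @param K Size of list A.
#' @param n Size of list B.
#' @param N Universe size.  Always explicit: overlap significance is
#'   meaningless without a stated universe.
#' @return The upper-tail probability in (0, 1].
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(K, n))
    stop("require 0 <= k <= min(K, n) <= N")
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Overlap two identifier lists and test the intersection size
#'
#' @param ids_a,ids_b Character vectors of harmonized identifiers.
#' @param universe_size Total number of identifiers both lists were drawn
#'   from (explicit; never defaulted).
#' @return A one-row `data.frame` with `k` (intersection), `K`, `n`, `N`
#'   and the hypergeometric upper-tail `p`.
#' @export
overlap_test <- function(ids_a, ids_b, universe_size) {
  a <- unique(ids_a); b <- unique(ids_b)
  k <- length(intersect_ids(a, b))
  data.frame(k = k, K = length(a), n = length(b), N = universe_size,
             p = hypergeom_upper_tail(k, length(a), length(b), universe_size))
}

#' Read a one-identifier-per-line list
#'
#' Blank lines are skipped; duplicates are collapsed.
#'
#' @param path Path to the text file.
#' @return Character vector of identifiers.
#' @export
read_id_list <- function(path) {
  ids <- trimws(readLines(path, warn = FALSE))
  unique(ids[nzchar(ids)])
}
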