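## Exact 2x2 machinery shared by enrichment and concordance analyses.
## Implemented directly on the hypergeometric density so the package's
## numbers can be checked against stats::fisher.test as an independent
## oracle rather than being that call.

#' One-sided hypergeometric tail probability of an overlap
#'
#' P(X >= overlap) where X ~ Hypergeometric(set size `k_set`, universe size
#' `n_universe`, draws `n_query`): the overrepresentation p-value.
#'
#' @param overlap observed overlap count.
#' @param n_query query size.
#' @param k_set gene-set size within the universe.
#' @param n_universe universe size.
#' @return p-value in [0, 1].
#' @export
hypergeom_tail_p <- function(overlap, n_query, k_set, n_universe) {
  stopifnot(overlap >= 0, overlap <= min(n_query, k_set),
            k_set <= n_universe, n_query <= n_universe)
  stats::phyper(overlap - 1, k_set, n_universe - k_set, n_query,
                lower.tail = FALSE)
}

#' Two-sided Fisher exact p for a 2x2 table
#'
#' Exhaustive enumeration: conditioning on the margins, the p-value is the
#' sum of hypergeometric point masses not exceeding that of the observed
#' table (with the conventional 1 + 1e-7 relative tolerance).
#'
#' @param n11,n12,n21,n22 cell counts.
#' @return Two-sided p-value.
#' @export
fisher_exact_p <- function(n11, n12, n21, n22) {
  stopifnot(n11 >= 0, n12 >= 0, n21 >= 0, n22 >= 0)
  m <- n11 + n12          # row 1 margin
  n <- n21 + n22          # row 2 margin
  k <- n11 + n21          # column 1 margin
  lo <- max(0, k - n)
  hi <- min(k, m)
  support <- lo:hi
  dens <- stats::dhyper(support, m, n, k)
  obs <- stats::dhyper(n11, m, n, k)
  sum(dens[dens <= obs * (1 + 1e-7)])
}

#' Odds ratio of a 2x2 table with Haldane-Anscombe correction
#'
#' `(n11 * n22) / (n12 * n21)`; when any cell is zero, 0.5 is added to every
#' cell first so the ratio stays finite.
#'
#' @param n11,n12,n21,n22 cell counts.
#' @return List: `odds_ratio`, `corrected` (logical), `log_or_se` (delta
#'   method SE of the log odds ratio, on the corrected table when applied).
#' @export
odds_ratio_2x2 <- function(n11, n12, n21, n22) {
  cells <- c(n11, n12, n21, n22)
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  list(odds_ratio = or, corrected = corrected,
       log_or_se = sqrt(sum(1 / cells)))
}

#' Benjamini-Hochberg adjustment
#'
#' Thin wrapper kept for symmetry with the exported statistics.
#'
#' @param p raw p-values.
#' @return Adjusted p-values (same order as input).
#' @keywords internal
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")
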