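#' Reference leave-one-out ranks for the eleven ALS-linked RBPs
#'
#' The published leave-one-out cross-validation ranks of the eleven
#' RNA-binding proteins with known ALS-causing mutations, each ranked
#' against the 1467 other literature-mentioned RBPs after being removed
#' from the seed set. These ranks are the worked-example input for the
#' evaluation statistics: counting them at thresholds 15 and 118 (top 8%
#' of 1478) gives 5 and 10; the one-sided Wilcoxon rank-sum normal
#' approximation with continuity correction gives p about 3.17e-7; the
#' pooled trapezoid-rule AUC is about 0.935.
#'
#' @return named integer vector of ranks (names are HGNC symbols), with
#'   attribute `n_candidates` = 1467.
#' @examples
#' r <- alsLooRanks()
#' topThresholdCounts(r, c(15, 118))
#' aucFromRanks(r, attr(r, "n_candidates"))
#' @export
alsLooRanks <- function() {
  r <- c(TARDBP = 1L, FUS = 5L, SETX = 11L, MATR3 = 12L, TAF15 = 13L,
         ATXN2 = 21L, HNRNPA2B1 = 60L, ARHGEF28 = 61L, HNRNPA1 = 106L,
         GLE1 = 107L, ANG = 713L)
  attr(r, "n_candidates") <- 1467L
  r
}
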