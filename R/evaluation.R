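#' Leave-one-out cross-validation of a seed-based ranking
#'
#' Each known gene in turn is removed from the seed set and ranked as a
#' candidate: the diffusion is re-run with the remaining seeds over the
#' SAME similarity matrix (the matrix is not rebuilt per fold), and the
#' held-out gene's 1-based rank among the candidates plus itself is
#' recorded. A held-out gene whose profile ties or beats every candidate
#' ranks 1; a fully dissimilar one ranks `nCandidates + 1`.
#'
#' @param sim a [SimilarityMatrix-class] covering knowns and candidates.
#' @param knowns seed gene ids, at least 2.
#' @param candidates candidate gene ids, disjoint from `knowns`.
#' @param alpha,tol,maxIter diffusion parameters, see [graphDiffusion()].
#' @return data.frame with columns `gene` (held-out known) and `rank`.
#' @seealso [looReport()] for the full summary statistics.
#' @export
looCrossValidation <- function(sim, knowns, candidates, alpha = 0.7,
                               tol = 1e-9, maxIter = 1000L) {
  knowns <- sort(as.character(knowns))
  candidates <- sort(as.character(candidates))
  if (length(knowns) < 2) stop("need at least 2 known genes", call. = FALSE)
  if (length(intersect(knowns, candidates)) > 0)
    stop("known and candidate sets overlap", call. = FALSE)
  P <- transitionMatrix(sim)
  ranks <- vapply(knowns, function(k) {
    seeds <- setdiff(knowns, k)
    s <- tryCatch(
      graphDiffusion(P, seeds, alpha = alpha, tol = tol, maxIter = maxIter),
      error = function(e) stop("fold for held-out gene ", k, ": ",
                               conditionMessage(e), call. = FALSE))
    pool <- c(candidates, k)
    sc <- s[pool]
    ord <- order(-sc, pool, method = "radix")
    match(k, pool[ord])
  }, integer(1))
  data.frame(gene = knowns, rank = as.integer(ranks),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pooled trapezoid-rule AUC from held-out ranks
#'
#' Builds the pooled ROC step curve over all leave-one-out folds, reading
#' the held-out ranks as positions of the `n1` positives in one combined
#' ranking over positives and negatives: the i-th best positive, at rank
#' `r_i`, has `r_i - i` negatives above it and therefore outranks
#' `nCandidates - (r_i - i)` of them. The trapezoid-rule area under the
#' resulting step curve is the fraction of concordant positive-negative
#' pairs (the Mann-Whitney statistic scaled to [0, 1]):
#' `AUC = sum_i (nCandidates - (r_i - i)) / (n1 * nCandidates)`.
#' Pooled ranks from independent folds can tie, in which case the count of
#' negatives above is clamped to `[0, nCandidates]`.
#'
#' @param ranks integer vector of held-out ranks, or the data.frame from
#'   [looCrossValidation()].
#' @param nCandidates number of candidates each held-out gene competed with.
#' @return AUC in [0, 1].
#' @examples
#' aucFromRanks(c(1, 3), 2)   # 3 of the 4 pairs concordant: 0.75
#' aucFromRanks(1:3, 3)       # all positives first: 1
#' @export
aucFromRanks <- function(ranks, nCandidates) {
  ranks <- rankVector(ranks)
  if (length(ranks) == 0) stop("empty rank list", call. = FALSE)
  if (any(ranks < 1) || any(ranks > nCandidates + 1))
    stop("ranks must lie in 1..nCandidates+1", call. = FALSE)
  rs <- sort(ranks)
  negAbove <- pmin(pmax(rs - seq_along(rs), 0), nCandidates)
  mean((nCandidates - negAbove) / nCandidates)
}

rankVector <- function(ranks) {
  if (is.data.frame(ranks)) ranks <- ranks$rank
  as.numeric(ranks)
}

#' One-sided Wilcoxon rank-sum p from held-out ranks
#'
#' Tests whether the known genes' diffusion scores are greater than the
#' candidates' (equivalently, their pooled ranks smaller). `W` is the sum
#' of the known genes' ranks among `N = n1 + n2` pooled observations.
#' The normal approximation uses a continuity correction:
#' `z = (W + 0.5 - n1 (N + 1) / 2) / sqrt(n1 n2 (N + 1) / 12)` with the
#' lower-tail normal probability. The exact method enumerates all
#' `choose(N, n1)` placements of the known ranks and is restricted to
#' `N <= 25`.
#'
#' @param ranks held-out ranks (vector or [looCrossValidation()] output).
#' @param nCandidates number of candidates (`n2`).
#' @param method "normal-cc" (default) or "exact".
#' @return one-sided p value.
#' @export
wilcoxonOneSided <- function(ranks, nCandidates, method = c("normal-cc", "exact")) {
  method <- match.arg(method)
  ranks <- rankVector(ranks)
  n1 <- length(ranks)
  if (n1 < 1) stop("need at least one rank", call. = FALSE)
  n2 <- nCandidates
  N <- n1 + n2
  W <- sum(ranks)
  if (method == "normal-cc") {
    z <- (W + 0.5 - n1 * (N + 1) / 2) / sqrt(n1 * n2 * (N + 1) / 12)
    stats::pnorm(z)
  } else {
    if (N > 25)
      stop("exact method restricted to N <= 25 (got N = ", N, ")", call. = FALSE)
    placements <- utils::combn(N, n1)
    mean(colSums(placements) <= W)
  }
}

#' One-sided (upper-tail) Fisher exact p for a 2x2 table
#'
#' Probability of at least `a` successes in the top cell under the
#' hypergeometric null: `P(X >= a)` for `X ~ Hypergeometric(N = a+b+c+d,
#' K = a+c, n = a+b)`. Computed by summing hypergeometric point masses in
#' log space (via `lchoose`) for numerical safety at extreme tails.
#'
#' @param tab 2x2 matrix or length-4 vector `(a, b, c, d)`: rows
#'   selected/not-selected, columns true/not-true.
#' @return upper-tail p value; an all-zero table returns 1.
#' @examples
#' fisherExactGreater(buildTopKTable(1467, 73, 10, 8))  # 1.07e-9
#' @export
fisherExactGreater <- function(tab) {
  if (is.matrix(tab)) {
    if (!all(dim(tab) == c(2, 2))) stop("table must be 2x2", call. = FALSE)
    cells <- as.integer(c(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]))
  } else {
    cells <- as.integer(tab)
  }
  if (length(cells) != 4 || any(is.na(cells)) || any(cells < 0))
    stop("need a 2x2 table of non-negative counts", call. = FALSE)
  a <- cells[1]; b <- cells[2]; cc <- cells[3]; d <- cells[4]
  N <- a + b + cc + d
  if (N == 0) return(1.0)
  K <- a + cc
  n <- a + b
  support <- max(0, n - (N - K)):min(n, K)
  logp <- lchoose(K, support) + lchoose(N - K, n - support) - lchoose(N, n)
  upper <- logp[support >= a]
  if (length(upper) == 0) return(0.0)
  m <- max(upper)
  min(1, exp(m + log(sum(exp(upper - m)))))
}

#' Build the top-k enrichment contingency table
#'
#' The 2x2 table for "did the top-k of the ranking capture more assumed-true
#' genes than chance": `[[hits, k - hits], [trueRemaining, otherRemaining]]`
#' out of `nCandidates` genes of which `nAssumedTrue` are assumed true.
#'
#' @param nCandidates total genes ranked.
#' @param nAssumedTrue genes assumed true among them.
#' @param k size of the top list.
#' @param hits assumed-true genes observed in the top k.
#' @return 2x2 integer matrix.
#' @examples
#' buildTopKTable(1467, 73, 10, 8)
#' @export
buildTopKTable <- function(nCandidates, nAssumedTrue, k, hits) {
  if (hits > min(k, nAssumedTrue))
    stop("hits cannot exceed min(k, nAssumedTrue)", call. = FALSE)
  if (k > nCandidates) stop("k cannot exceed nCandidates", call. = FALSE)
  cells <- c(hits, k - hits, nAssumedTrue - hits,
             nCandidates - k - (nAssumedTrue - hits))
  if (any(cells < 0))
    stop("derived cell count is negative; check the margins", call. = FALSE)
  matrix(as.integer(cells), nrow = 2, byrow = TRUE,
         dimnames = list(c("selected", "not_selected"), c("true", "not_true")))
}

#' Count held-out ranks at or below each threshold
#'
#' @param ranks held-out ranks (vector or [looCrossValidation()] output).
#' @param thresholds positive integer thresholds.
#' @return named integer vector, one count per threshold.
#' @examples
#' topThresholdCounts(c(1, 5, 11, 12, 13, 21, 60, 61, 106, 107, 713), c(15, 118))
#' @export
topThresholdCounts <- function(ranks, thresholds) {
  if (any(thresholds < 1)) stop("thresholds must be positive", call. = FALSE)
  ranks <- rankVector(ranks)
  stats::setNames(vapply(thresholds, function(t) sum(ranks <= t), numeric(1)) |>
                    as.integer(),
                  as.character(thresholds))
}

#' Median of rank-threshold Fisher exact p values
#'
#' At each distinct held-out rank `r`, tests whether the knowns are
#' enriched above that rank threshold: with `a` = number of held-out ranks
#' `<= r`, the table is `[[a, nKnown - a], [r - a, nCandidates - (r - a)]]`,
#' scored by [fisherExactGreater()]. Returns the median of the per-threshold
#' p values (mean of the middle two for an even count).
#'
#' @param ranks held-out ranks (vector or [looCrossValidation()] output).
#' @param nKnown number of known genes (= number of ranks).
#' @param nCandidates number of candidates.
#' @return median p value.
#' @export
thresholdFisherMedian <- function(ranks, nKnown, nCandidates) {
  ranks <- rankVector(ranks)
  stopifnot(nKnown == length(ranks))
  ps <- vapply(sort(unique(ranks)), function(r) {
    a <- sum(ranks <= r)
    # each fold ranks independently, so pooled ranks can tie and more than
    # r knowns may sit at rank <= r; the candidate cell is clamped at zero
    b <- max(r - a, 0)
    fisherExactGreater(matrix(c(a, nKnown - a, b, nCandidates - b),
                              nrow = 2, byrow = TRUE))
  }, numeric(1))
  stats::median(ps)
}

#' Full leave-one-out validation report
#'
#' Runs [looCrossValidation()] and summarizes it into a [LOOReport-class]:
#' pooled trapezoid-rule AUC, one-sided Wilcoxon rank-sum p (normal
#' approximation with continuity correction), the median rank-threshold
#' Fisher p, and counts of held-out ranks within each requested threshold.
#'
#' @inheritParams looCrossValidation
#' @param thresholds integer thresholds for the top-count summary.
#' @return a [LOOReport-class].
#' @export
looReport <- function(sim, knowns, candidates, alpha = 0.7, tol = 1e-9,
                      maxIter = 1000L, thresholds = integer()) {
  lr <- looCrossValidation(sim, knowns, candidates, alpha = alpha, tol = tol,
                           maxIter = maxIter)
  nC <- length(setdiff(candidates, knowns))
  new("LOOReport",
      looRanks = lr,
      nCandidates = as.integer(nC),
      auc = aucFromRanks(lr, nC),
      wilcoxonP = wilcoxonOneSided(lr, nC),
      thresholdFisherMedianP = thresholdFisherMedian(lr, nrow(lr), nC),
      topCounts = if (length(thresholds)) topThresholdCounts(lr, thresholds)
                  else stats::setNames(integer(), character()))
}
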