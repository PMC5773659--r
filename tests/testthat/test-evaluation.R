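# brute-force AUC: place the positives at their pooled ranks, fill the
# remaining positions with negatives, and count concordant pairs explicitly
pairCountAuc <- function(ranks, nCand) {
  N <- length(ranks) + nCand
  negPos <- setdiff(seq_len(N), ranks)[seq_len(nCand)]
  wins <- sum(outer(ranks, negPos, "<"))
  wins / (length(ranks) * nCand)
}

test_that("AUC from held-out ranks matches hand examples", {
  expect_equal(aucFromRanks(1:4, 100), 1)          # all positives first
  expect_equal(aucFromRanks(c(1, 2, 3), 3), 1)
  expect_equal(aucFromRanks(c(1, 3), 2), 0.75)     # brute-force: 3 of 4 pairs
  expect_equal(aucFromRanks(11, 10), 0)            # dead last, single fold
  expect_error(aucFromRanks(integer(), 10), "empty")
  expect_error(aucFromRanks(12, 10), "1..nCandidates")
})

test_that("AUC equals brute-force pair counting on random rank sets", {
  set.seed(101)
  for (trial in 1:50) {
    nCand <- sample(5:50, 1)
    n1 <- sample(1:5, 1)
    ranks <- sort(sample(nCand + 1, n1))
    expect_equal(aucFromRanks(ranks, nCand), pairCountAuc(ranks, nCand),
                 tolerance = 1e-12)
  }
})

test_that("exact Wilcoxon enumeration matches closed cases", {
  expect_equal(wilcoxonOneSided(c(1, 2), 3, method = "exact"), 0.1)  # 1/C(5,2)
  expect_error(wilcoxonOneSided(c(1, 2), 30, method = "exact"), "N <= 25")
  # W at its null mean gives p near one half under the normal approximation
  n1 <- 4; n2 <- 46; N <- n1 + n2
  ranks <- c(10, 20, 30, 42)  # sums to n1 (N + 1) / 2 = 102
  expect_equal(sum(ranks), n1 * (N + 1) / 2)
  expect_lt(abs(wilcoxonOneSided(ranks, n2) - 0.5), 0.01)
})

test_that("normal-cc and exact Wilcoxon agree within 0.02 for small N", {
  # the approximation claim needs at least two knowns and N >= 10; with a
  # single known the exact null has only N support points and the normal
  # approximation is off by up to ~0.06
  set.seed(55)
  for (trial in 1:40) {
    n1 <- sample(2:5, 1)
    n2 <- sample((10 - n1):(25 - n1), 1)
    ranks <- sort(sample(n1 + n2, n1))
    pN <- wilcoxonOneSided(ranks, n2, method = "normal-cc")
    pE <- wilcoxonOneSided(ranks, n2, method = "exact")
    expect_lt(abs(pN - pE), 0.02)
  }
})

test_that("Wilcoxon p is super-uniform under the uniform-rank null", {
  set.seed(77)
  n1 <- 8; n2 <- 120
  rejections <- mean(replicate(2000, {
    ranks <- sample(n1 + n2, n1)
    wilcoxonOneSided(ranks, n2) < 0.05
  }))
  expect_lte(rejections, 0.06)
})

test_that("upper-tail Fisher matches enumeration and the stats oracle", {
  expect_equal(fisherExactGreater(matrix(c(2, 1, 1, 2), 2, byrow = TRUE)), 0.5,
               tolerance = 1e-12)
  expect_equal(fisherExactGreater(c(0, 0, 0, 0)), 1)
  set.seed(91)
  for (trial in 1:60) {
    cells <- as.integer(rmultinom(1, sample(4:60, 1), rep(0.25, 4)))
    tab <- matrix(cells, 2, byrow = TRUE)
    expect_equal(fisherExactGreater(tab),
                 stats::fisher.test(t(tab), alternative = "greater")$p.value,
                 tolerance = 1e-9)
  }
})

test_that("top-k contingency tables are assembled correctly", {
  expect_equal(unname(buildTopKTable(1467, 73, 10, 8)),
               matrix(c(8L, 2L, 65L, 1392L), 2, byrow = TRUE))
  expect_equal(unname(buildTopKTable(1467, 293, 10, 8)),
               matrix(c(8L, 2L, 285L, 1172L), 2, byrow = TRUE))
  expect_equal(unname(buildTopKTable(100, 10, 5, 0)),
               matrix(c(0L, 5L, 10L, 85L), 2, byrow = TRUE))
  expect_error(buildTopKTable(100, 3, 5, 4), "hits")
  expect_error(buildTopKTable(10, 9, 5, 0), "negative")
})

test_that("threshold counts follow the rank distribution", {
  ranks <- c(2, 2, 7, 30)
  expect_equal(topThresholdCounts(ranks, c(1, 2, 10, 100)),
               c("1" = 0L, "2" = 2L, "10" = 3L, "100" = 4L))
  expect_equal(topThresholdCounts(integer(), c(5, 10)),
               c("5" = 0L, "10" = 0L))
  expect_error(topThresholdCounts(ranks, 0), "positive")
})

test_that("median rank-threshold Fisher p behaves at the extremes", {
  # single known at rank 1: table [[1,0],[0,n]], p = 1/(n+1)
  nC <- 25
  expect_equal(thresholdFisherMedian(1, 1, nC), 1 / (nC + 1), tolerance = 1e-12)
  # all knowns at the bottom: no enrichment, median p near 1
  expect_gt(thresholdFisherMedian(c(19, 20), 2, 18), 0.99)
  # {1,2} vs direct hypergeometric enumeration of the two threshold tables
  p1 <- fisherExactGreater(matrix(c(1, 1, 0, 8), 2, byrow = TRUE))
  p2 <- fisherExactGreater(matrix(c(2, 0, 0, 8), 2, byrow = TRUE))
  expect_equal(thresholdFisherMedian(c(1, 2), 2, 8), stats::median(c(p1, p2)),
               tolerance = 1e-12)
})

test_that("improving one rank never hurts AUC or the Wilcoxon p", {
  set.seed(33)
  for (trial in 1:25) {
    nCand <- sample(20:60, 1)
    ranks <- sort(sample(nCand + 1, 5))
    i <- sample(5, 1)
    if (ranks[i] == 1) next
    better <- ranks; better[i] <- better[i] - 1
    expect_gte(aucFromRanks(better, nCand), aucFromRanks(ranks, nCand))
    expect_lte(wilcoxonOneSided(better, nCand), wilcoxonOneSided(ranks, nCand))
  }
})

test_that("LOO returns one record per known and respects identical profiles", {
  # held-out known identical in similarity to a remaining seed ranks first
  nodes <- c("K1", "K2", "C1", "C2")
  s <- matrix(0.1, 4, 4, dimnames = list(nodes, nodes)); diag(s) <- 0
  s["K1", "K2"] <- s["K2", "K1"] <- 0.9
  lr <- looCrossValidation(new("SimilarityMatrix", sim = s),
                           c("K1", "K2"), c("C1", "C2"))
  expect_equal(nrow(lr), 2L)
  expect_equal(lr$rank[lr$gene == "K1"], 1L)
  expect_equal(lr$rank[lr$gene == "K2"], 1L)
  expect_error(looCrossValidation(new("SimilarityMatrix", sim = s),
                                  "K1", c("C1", "C2")), "at least 2")
})

test_that("looReport bundles consistent summary statistics", {
  set.seed(12)
  sim <- randomSim(12)
  knowns <- c("N01", "N02", "N03")
  cands <- setdiff(rownames(as.matrix(sim)), knowns)
  rep <- looReport(sim, knowns, cands, thresholds = c(2, 9))
  lr <- looRanks(rep)
  expect_equal(nrow(lr), 3L)
  st <- reportStats(rep)
  expect_equal(st$auc, aucFromRanks(lr, 9))
  expect_equal(st$wilcoxon_p, wilcoxonOneSided(lr, 9))
  expect_equal(st$top_counts$`9`, sum(lr$rank <= 9))
})
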