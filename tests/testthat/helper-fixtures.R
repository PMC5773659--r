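# Small builders shared across test files. All fixtures are constructed in
# code; nothing is read from disk except files the tests write themselves.

makeCorpus <- function(texts, dates = NULL, titles = NULL, ids = NULL) {
  n <- length(texts)
  Corpus(data.frame(
    doc_id = if (is.null(ids)) sprintf("d%03d", seq_len(n)) else ids,
    date = if (is.null(dates)) rep("2010-01-01", n) else dates,
    title = if (is.null(titles)) rep("", n) else titles,
    text = texts, stringsAsFactors = FALSE))
}

# valid random similarity matrix over n named nodes
randomSim <- function(n, nodeNames = sprintf("N%02d", seq_len(n))) {
  s <- matrix(runif(n * n), n, n)
  s <- (s + t(s)) / 2
  diag(s) <- 0
  dimnames(s) <- list(nodeNames, nodeNames)
  new("SimilarityMatrix", sim = s)
}

# direct dense closed-form RWR solve: s = (1-a) (I - a M)^-1 p0, where M is
# P with dangling columns replaced by the seed distribution
rwrClosedForm <- function(P, seeds, alpha) {
  nodes <- rownames(P)
  dangling <- attr(P, "dangling")
  p0 <- setNames(numeric(length(nodes)), nodes)
  p0[seeds] <- 1 / length(seeds)
  M <- P
  if (any(dangling))
    M[, dangling] <- matrix(p0, nrow = length(nodes), ncol = sum(dangling))
  setNames(as.vector((1 - alpha) * solve(diag(length(nodes)) - alpha * M, p0)),
           nodes)
}

# end-to-end synthetic pipeline: corpus -> annotation -> profiles -> sim
syntheticSim <- function(params) {
  out <- simulateCorpus(params)
  ann <- annotateCorpus(out$corpus, out$dictionary)
  prof <- suppressWarnings(buildProfiles(ann, dictionaryGenes(out$dictionary)))
  list(sim = similarityMatrix(prof), truth = out$truth,
       genes = dictionaryGenes(out$dictionary), corpus = out$corpus,
       dictionary = out$dictionary, annotated = ann)
}

syntheticLooAuc <- function(params) {
  run <- syntheticSim(params)
  pos <- run$truth$positive_genes
  cands <- setdiff(run$genes, pos)
  aucFromRanks(looCrossValidation(run$sim, pos, cands), length(cands))
}
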