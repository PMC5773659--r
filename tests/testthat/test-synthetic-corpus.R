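smallParams <- function(...) {
  defaults <- list(nGenes = 30, nPositives = 6, vocabBackground = 400,
                   vocabTopic = 60, docsPerGeneMean = 4, docLength = 40,
                   seed = 5)
  do.call(syntheticParams, utils::modifyList(defaults, list(...)))
}

test_that("identical parameters and seed give byte-identical output", {
  a <- simulateCorpus(smallParams())
  b <- simulateCorpus(smallParams())
  expect_identical(documents(a$corpus), documents(b$corpus))
  expect_identical(dictionaryEntries(a$dictionary), dictionaryEntries(b$dictionary))
  expect_identical(a$truth, b$truth)
  # and a different seed changes the corpus
  c <- simulateCorpus(smallParams(seed = 6))
  expect_false(identical(documents(a$corpus), documents(c$corpus)))
})

test_that("planted positive count and date range match the parameters", {
  out <- simulateCorpus(smallParams(nPositives = 25, nGenes = 60))
  expect_length(out$truth$positive_genes, 25L)
  d <- documents(out$corpus)
  rng <- parseDate(c("2000-01-01", "2015-12-31"))
  expect_true(all(d$date >= rng[1] & d$date <= rng[2]))
})

test_that("invalid parameters are rejected with the field named", {
  expect_error(smallParams(nPositives = 31), "nPositives")
  expect_error(smallParams(signalDelta = 1.2), "signalDelta")
  expect_error(smallParams(docLength = 0), "docLength")
  expect_error(syntheticParams(dateRange = c("2015-01-01", "2000-01-01")),
               "dateRange")
})

test_that("every document literally contains a surface form of its gene", {
  out <- simulateCorpus(smallParams())
  ann <- annotateCorpus(out$corpus, out$dictionary)
  docsWithMention <- unique(mentions(ann)$doc_id)
  expect_setequal(docsWithMention, documents(out$corpus)$doc_id)
})

test_that("injected synonym collisions surface as ambiguous forms", {
  out <- simulateCorpus(smallParams(ambiguityPairs = 2))
  amb <- out$truth$injected_ambiguities
  expect_equal(nrow(amb), 2L)
  expect_true(all(amb$synonym %in% ambiguousForms(out$dictionary)))
  # under the strict policy an ambiguous-only mention attributes to no gene
  ann <- annotateCorpus(out$corpus, out$dictionary, policy = "strict")
  m <- mentions(ann)
  expect_true(all(is.na(m$gene[m$surface %in% amb$synonym])))
})

test_that("late positives carry no topic terms before their discovery date", {
  out <- simulateCorpus(smallParams(discoveryFraction = 0.5, docsPerGeneMean = 8))
  late <- names(out$truth$discovery_date)
  expect_gte(length(late), 1L)
  d <- documents(out$corpus)
  topic <- out$truth$topic_terms
  owner <- out$truth$doc_gene
  for (g in late) {
    own <- names(owner)[owner == g]
    pre <- own[d$date[match(own, d$doc_id)] < out$truth$discovery_date[[g]]]
    toks <- unlist(tokenize(d$text[match(pre, d$doc_id)]))
    expect_length(intersect(toks, topic), 0L)
    # after discovery the gene's own documents are topic-enriched
    post <- setdiff(own, pre)
    if (length(post) > 0) {
      postToks <- unlist(tokenize(d$text[match(post, d$doc_id)]))
      expect_gt(length(intersect(postToks, topic)), 0L)
    }
  }
})

test_that("positive profiles cluster above background at high signal", {
  # stated conditions: 200 genes, 20 positives, delta 0.8, ~10 docs of 80
  # tokens; the within-positive mean cosine must beat positive-vs-background
  # in at least 9 of the seeds 1..10
  wins <- vapply(1:10, function(sd) {
    run <- syntheticSim(syntheticParams(seed = sd))
    s <- as.matrix(run$sim)
    pos <- run$truth$positive_genes
    bg <- setdiff(rownames(s), pos)
    within <- mean(s[pos, pos][upper.tri(s[pos, pos])])
    between <- mean(s[pos, bg])
    within > between
  }, logical(1))
  expect_gte(sum(wins), 9L)
})

test_that("within-positive similarity is non-decreasing in the topic weight", {
  deltas <- c(0, 0.4, 0.8)
  meanWithin <- vapply(deltas, function(delta) {
    mean(vapply(1:10, function(sd) {
      run <- syntheticSim(smallParams(signalDelta = delta, seed = sd))
      s <- as.matrix(run$sim)
      pos <- run$truth$positive_genes
      mean(s[pos, pos][upper.tri(s[pos, pos])])
    }, numeric(1)))
  }, numeric(1))
  expect_false(is.unsorted(meanWithin))
})
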