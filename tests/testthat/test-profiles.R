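# build an AnnotatedCorpus where each gene's documents have fully controlled
# token content (the gene symbol itself is removed from its own profile)
annotatedFromTexts <- function(geneTexts, dates = NULL) {
  genes <- names(geneTexts)
  texts <- unlist(geneTexts, use.names = FALSE)
  owner <- rep(genes, lengths(geneTexts))
  co <- makeCorpus(paste(owner, texts),
                   dates = if (is.null(dates)) NULL else dates)
  annotateCorpus(co, geneDictionary(setNames(rep(list(character()),
                                                 length(genes)), genes)))
}

test_that("raw-mode cosine matches the hand computation", {
  # A: xx twice, yy once; B: xx once, zz once -> cos = 2 / sqrt(10)
  ann <- annotatedFromTexts(list(GENEA = "xx xx yy", GENEB = "xx zz"))
  prof <- buildProfiles(ann, c("GENEA", "GENEB"), weighting = "raw")
  w <- as.matrix(profileMatrix(prof))
  expect_equal(w["GENEA", c("xx", "yy")], c(xx = 2, yy = 1))
  expect_equal(w["GENEB", c("xx", "zz")], c(xx = 1, zz = 1))
  sim <- similarityMatrix(prof)
  expect_equal(as.matrix(sim)["GENEA", "GENEB"], 2 / sqrt(10), tolerance = 1e-12)
})

test_that("a term present in every entity gets TF-IDF weight zero", {
  ann <- annotatedFromTexts(list(GENEA = "common aa", GENEB = "common bb",
                                 GENEC = "common cc", GENED = "common dd"))
  prof <- buildProfiles(ann, paste0("GENE", LETTERS[1:4]), weighting = "tfidf")
  w <- as.matrix(profileMatrix(prof))
  expect_true(all(w[, "common"] == 0))
  expect_true(all(w[cbind(1:4, match(c("aa", "bb", "cc", "dd"), colnames(w)))] > 0))
})

test_that("stopwords, short tokens and own surface forms are removed", {
  co <- makeCorpus("the TDP-43 of and a x mislocalization")
  d <- geneDictionary(list(TARDBP = "TDP-43"))
  prof <- buildProfiles(annotateCorpus(co, d), "TARDBP", weighting = "raw")
  terms <- colnames(profileMatrix(prof))[as.matrix(profileMatrix(prof))[1, ] > 0]
  expect_setequal(terms, "mislocalization")
})

test_that("genes sharing their only document agree on all context terms", {
  co <- makeCorpus("GENEA GENEB shared context tokens")
  d <- geneDictionary(list(GENEA = character(), GENEB = character()))
  prof <- buildProfiles(annotateCorpus(co, d), c("GENEA", "GENEB"),
                        weighting = "raw")
  w <- as.matrix(profileMatrix(prof))
  ctx <- setdiff(colnames(w), c("genea", "geneb"))
  expect_equal(w["GENEA", ctx], w["GENEB", ctx])
  # each profile keeps the other gene's name but not its own
  expect_equal(unname(w["GENEA", "geneb"]), 1)
  expect_equal(unname(w["GENEA", "genea"]), 0)
})

test_that("an entity with no documents yields a flagged zero row and zero similarity", {
  co <- makeCorpus("GENEA alone here today")
  d <- geneDictionary(list(GENEA = character(), GENEB = character(),
                           GENEC = character()))
  ann <- annotateCorpus(co, d)
  expect_warning(prof <- buildProfiles(ann, c("GENEA", "GENEB", "GENEC"),
                                       weighting = "raw"),
                 "empty profiles.*GENEB")
  s <- as.matrix(similarityMatrix(prof))
  expect_equal(unname(s["GENEA", "GENEB"]), 0)
  expect_equal(unname(s["GENEB", "GENEC"]), 0)
})

test_that("cosine similarities match a brute-force oracle on random profiles", {
  set.seed(42)
  for (trial in 1:5) {
    w <- matrix(rpois(60, 2), nrow = 6, ncol = 10,
                dimnames = list(sprintf("G%02d", 1:6), sprintf("t%02d", 1:10)))
    prof <- new("EntityTermMatrix",
                weights = as(Matrix::Matrix(w, sparse = TRUE), "CsparseMatrix"),
                weighting = "raw", stopwordVersion = "test")
    s <- as.matrix(similarityMatrix(prof))
    for (i in 1:6) for (j in 1:6) {
      expected <- if (i == j) 0 else {
        ni <- sqrt(sum(w[i, ]^2)); nj <- sqrt(sum(w[j, ]^2))
        if (ni == 0 || nj == 0) 0 else sum(w[i, ] * w[j, ]) / (ni * nj)
      }
      expect_equal(s[i, j], expected, tolerance = 1e-12)
    }
  }
})

test_that("similarity is invariant to positive rescaling of one profile", {
  set.seed(7)
  w <- matrix(runif(40), nrow = 4,
              dimnames = list(paste0("G", 1:4), paste0("t", 1:10)))
  mk <- function(m) new("EntityTermMatrix",
                        weights = as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix"),
                        weighting = "raw", stopwordVersion = "test")
  s1 <- as.matrix(similarityMatrix(mk(w)))
  w2 <- w; w2[2, ] <- 17.3 * w2[2, ]
  s2 <- as.matrix(similarityMatrix(mk(w2)))
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("similarity entries stay in [0,1] and fewer than 2 entities errors", {
  set.seed(8)
  ann <- annotatedFromTexts(list(GENEA = "aa bb cc", GENEB = "bb cc dd",
                                 GENEC = "ee ff"))
  s <- as.matrix(similarityMatrix(buildProfiles(ann, paste0("GENE", LETTERS[1:3]))))
  expect_true(all(s >= 0 & s <= 1))
  expect_true(all(diag(s) == 0))
  one <- buildProfiles(ann, "GENEA")
  expect_error(similarityMatrix(one), "at least 2")
})
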