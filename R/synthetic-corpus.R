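#' Parameters for the synthetic corpus generator
#'
#' Bag-of-words mixture corpus with a planted disease topic: documents
#' about a positive gene draw each token from a shared disease-topic
#' vocabulary with probability `signalDelta` and from a background
#' vocabulary otherwise; documents about background genes draw background
#' tokens only. This is the minimal generative structure a semantic-profile
#' similarity analysis exploits, with ground truth recorded for every
#' planted feature.
#'
#' @slot nGenes number of genes.
#' @slot nPositives number of planted disease-cluster genes.
#' @slot vocabBackground background vocabulary size.
#' @slot vocabTopic disease-topic vocabulary size.
#' @slot docsPerGeneMean Poisson mean for documents per gene (a floor of
#'   one document per gene is imposed so every gene is rankable).
#' @slot docLength tokens per abstract.
#' @slot signalDelta topic-mixture weight in positive genes' documents, [0, 1].
#' @slot comentionRate probability a document co-mentions a second gene of
#'   the same class, [0, 1].
#' @slot dateRange length-2 `Date` vector, inclusive document date range.
#' @slot discoveryFraction fraction of positives given a late "discovery
#'   date": their pre-discovery documents carry no topic enrichment.
#' @slot ambiguityPairs number of injected shared-synonym collisions.
#' @slot seed integer RNG seed; all randomness flows from it.
#' @seealso [syntheticParams()], [simulateCorpus()]
#' @export
setClass("SyntheticParams",
         representation(nGenes = "integer", nPositives = "integer",
                        vocabBackground = "integer", vocabTopic = "integer",
                        docsPerGeneMean = "numeric", docLength = "integer",
                        signalDelta = "numeric", comentionRate = "numeric",
                        dateRange = "Date", discoveryFraction = "numeric",
                        ambiguityPairs = "integer", seed = "integer"))

setValidity("SyntheticParams", function(object) {
  if (object@nGenes < 2) return("nGenes must be >= 2")
  if (object@nPositives < 0 || object@nPositives > object@nGenes)
    return("nPositives must lie in 0..nGenes")
  if (object@vocabBackground < 1) return("vocabBackground must be >= 1")
  if (object@vocabTopic < 1) return("vocabTopic must be >= 1")
  if (object@docsPerGeneMean <= 0) return("docsPerGeneMean must be positive")
  if (object@docLength < 1) return("docLength must be >= 1")
  if (object@signalDelta < 0 || object@signalDelta > 1)
    return("signalDelta must lie in [0, 1]")
  if (object@comentionRate < 0 || object@comentionRate > 1)
    return("comentionRate must lie in [0, 1]")
  if (length(object@dateRange) != 2 || object@dateRange[1] > object@dateRange[2])
    return("dateRange must be two dates with start <= end")
  if (object@discoveryFraction < 0 || object@discoveryFraction > 1)
    return("discoveryFraction must lie in [0, 1]")
  if (object@ambiguityPairs < 0 ||
      2L * object@ambiguityPairs > object@nGenes)
    return("ambiguityPairs must be >= 0 and use at most all genes")
  TRUE
})

#' Construct synthetic-corpus parameters
#'
#' Defaults describe the standard study conditions used throughout the
#' package's tests: 200 genes of which 20 carry the planted disease topic
#' at mixture weight 0.8, around 10 eighty-token abstracts per gene over
#' 2000 background and 150 topic terms, a 20% same-class co-mention rate,
#' and dates spanning 2000-2015.
#'
#' @param nGenes,nPositives,vocabBackground,vocabTopic,docsPerGeneMean,docLength,signalDelta,comentionRate,discoveryFraction,ambiguityPairs,seed
#'   see [SyntheticParams-class].
#' @param dateRange length-2 date vector (strings accepted).
#' @return a validated [SyntheticParams-class].
#' @export
syntheticParams <- function(nGenes = 200, nPositives = 20,
                            vocabBackground = 2000, vocabTopic = 150,
                            docsPerGeneMean = 10, docLength = 80,
                            signalDelta = 0.8, comentionRate = 0.2,
                            dateRange = c("2000-01-01", "2015-12-31"),
                            discoveryFraction = 0, ambiguityPairs = 0,
                            seed = 1) {
  if (!inherits(dateRange, "Date")) dateRange <- parseDate(dateRange)
  new("SyntheticParams",
      nGenes = as.integer(nGenes), nPositives = as.integer(nPositives),
      vocabBackground = as.integer(vocabBackground),
      vocabTopic = as.integer(vocabTopic),
      docsPerGeneMean = as.numeric(docsPerGeneMean),
      docLength = as.integer(docLength),
      signalDelta = as.numeric(signalDelta),
      comentionRate = as.numeric(comentionRate),
      dateRange = dateRange,
      discoveryFraction = as.numeric(discoveryFraction),
      ambiguityPairs = as.integer(ambiguityPairs), seed = as.integer(seed))
}

setMethod("show", "SyntheticParams", function(object) {
  cat("SyntheticParams:", object@nGenes, "genes (", object@nPositives,
      "positives ), signalDelta", object@signalDelta,
      ", seed", object@seed, "\n")
})

#' Generate a synthetic corpus with ground truth
#'
#' Produces a dated abstract corpus, a matching gene dictionary (one
#' synonym per gene plus any injected shared-synonym collisions), and the
#' ground truth of everything planted. Every document about a gene
#' contains at least one of that gene's surface forms literally in its
#' text, so the mention annotator is exercised end to end. Documents about
#' positive genes mix disease-topic terms in at rate `signalDelta`; with
#' probability `comentionRate` a document additionally mentions a second
#' gene of the same class (positive with positive, background with
#' background). Positives selected as "late discoveries" emit topic-free
#' documents before their discovery date and topic-enriched ones after it,
#' so a corpus sliced before the discovery date carries only the weak
#' co-mention signal for them.
#'
#' All randomness flows from `params@seed`: identical parameters give
#' byte-identical output.
#'
#' @param params a [SyntheticParams-class].
#' @return list with elements `corpus` ([Corpus-class]), `dictionary`
#'   ([GeneDictionary-class]) and `truth` (list: `positive_genes`,
#'   `discovery_date` named `Date`, `topic_terms`, `injected_ambiguities`
#'   data.frame with columns `synonym`, `gene1`, `gene2`, and `doc_gene`,
#'   a named vector mapping each doc_id to the gene it was generated for;
#'   co-mentioned genes are recoverable only through annotation).
#' @examples
#' out <- simulateCorpus(syntheticParams(nGenes = 20, nPositives = 4,
#'                                       docsPerGeneMean = 3, seed = 7))
#' length(out$corpus)
#' @export
simulateCorpus <- function(params) {
  stopifnot(is(params, "SyntheticParams"))
  validObject(params)
  set.seed(params@seed)

  genes <- sprintf("GENE%04d", seq_len(params@nGenes))
  positives <- sort(sample(genes, params@nPositives))
  isPositive <- stats::setNames(genes %in% positives, genes)

  bgTerms <- sprintf("bkgterm%04d", seq_len(params@vocabBackground))
  topicTerms <- sprintf("topicterm%03d", seq_len(params@vocabTopic))

  synonyms <- stats::setNames(paste0("syn", tolower(genes)), genes)
  entries <- lapply(genes, function(g) synonyms[[g]])
  names(entries) <- genes

  ambiguities <- data.frame(synonym = character(), gene1 = character(),
                            gene2 = character(), stringsAsFactors = FALSE)
  if (params@ambiguityPairs > 0) {
    chosen <- sample(genes, 2L * params@ambiguityPairs)
    for (p in seq_len(params@ambiguityPairs)) {
      g1 <- chosen[2L * p - 1L]; g2 <- chosen[2L * p]
      shared <- sprintf("sharedsyn%03d", p)
      entries[[g1]] <- c(entries[[g1]], shared)
      entries[[g2]] <- c(entries[[g2]], shared)
      ambiguities <- rbind(ambiguities,
                           data.frame(synonym = shared, gene1 = g1, gene2 = g2,
                                      stringsAsFactors = FALSE))
    }
  }
  dict <- geneDictionary(entries)

  # late positives: topic-enriched documents appear only after discovery
  nLate <- round(params@discoveryFraction * params@nPositives)
  latePositives <- if (nLate > 0) sort(sample(positives, nLate)) else character()
  dayRange <- as.integer(params@dateRange[2] - params@dateRange[1])
  midOffset <- dayRange %/% 2L
  discoveryDate <- stats::setNames(
    params@dateRange[1] + midOffset +
      if (nLate > 0) sample.int(max(dayRange - midOffset, 1L), nLate, replace = TRUE)
      else integer(),
    latePositives)

  docs <- list()
  docOwner <- character()
  idx <- 0L
  for (g in genes) {
    nDocs <- 1L + stats::rpois(1, max(params@docsPerGeneMean - 1, 0))
    allForms <- dict@entries[[g]]
    for (k in seq_len(nDocs)) {
      idx <- idx + 1L
      date <- params@dateRange[1] + sample.int(dayRange + 1L, 1L) - 1L
      delta <- if (isPositive[[g]] &&
                   (!(g %in% latePositives) || date >= discoveryDate[[g]]))
        params@signalDelta else 0
      fromTopic <- stats::runif(params@docLength) < delta
      tokens <- character(params@docLength)
      nT <- sum(fromTopic)
      if (nT > 0)
        tokens[fromTopic] <- topicTerms[sample.int(params@vocabTopic, nT,
                                                   replace = TRUE)]
      if (nT < params@docLength)
        tokens[!fromTopic] <- bgTerms[sample.int(params@vocabBackground,
                                                 params@docLength - nT,
                                                 replace = TRUE)]
      surfaces <- allForms[sample.int(length(allForms), 1L)]
      if (stats::runif(1) < params@comentionRate) {
        # partner is "topic-similar": same class as g when a topic is
        # planted at all; with signalDelta == 0 there is no disease
        # cluster and partners are uniform over the other genes
        pool <- if (params@signalDelta == 0) setdiff(genes, g)
                else if (isPositive[[g]]) setdiff(positives, g)
                else setdiff(genes[!isPositive], g)
        if (length(pool) > 0) {
          other <- pool[sample.int(length(pool), 1L)]
          otherForms <- dict@entries[[other]]
          surfaces <- c(surfaces, otherForms[sample.int(length(otherForms), 1L)])
        }
      }
      words <- c(tokens, surfaces)
      words <- words[sample.int(length(words))]
      docOwner[sprintf("doc%06d", idx)] <- g
      docs[[idx]] <- data.frame(
        doc_id = sprintf("doc%06d", idx), date = date,
        title = "", text = paste(words, collapse = " "),
        stringsAsFactors = FALSE)
    }
  }
  corpus <- Corpus(do.call(rbind, docs))

  list(corpus = corpus, dictionary = dict,
       truth = list(positive_genes = positives,
                    discovery_date = discoveryDate,
                    topic_terms = topicTerms,
                    injected_ambiguities = ambiguities,
                    doc_gene = docOwner))
}
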