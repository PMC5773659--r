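#' @import methods
#' @importFrom Matrix Matrix sparseMatrix rowSums colSums t crossprod Diagonal
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

#' Corpus of dated abstracts
#'
#' A `Corpus` holds one record per abstract: a unique document identifier,
#' a publication date (day resolution), a title (possibly empty) and the
#' abstract text. It is the raw material for gene-mention annotation and
#' for date-based slicing in retrospective analyses.
#'
#' @slot documents a `data.frame` with columns `doc_id` (character, unique,
#'   non-empty), `date` (`Date`), `title` (character) and `text` (character).
#'
#' @seealso [readCorpus()], [writeCorpus()], [sliceByDate()]
#' @export
setClass("Corpus", representation(documents = "data.frame"))

setValidity("Corpus", function(object) {
  d <- object@documents
  required <- c("doc_id", "date", "title", "text")
  if (!all(required %in% names(d)))
    return(paste("documents must have columns:", paste(required, collapse = ", ")))
  if (nrow(d) == 0) return(TRUE)
  if (!is.character(d$doc_id) || any(!nzchar(d$doc_id)))
    return("doc_id must be non-empty character")
  if (anyDuplicated(d$doc_id))
    return(paste("duplicate doc_id:", d$doc_id[duplicated(d$doc_id)][1]))
  if (!inherits(d$date, "Date") || anyNA(d$date))
    return("date must be a Date vector without NA")
  TRUE
})

#' Construct a Corpus
#'
#' @param documents data.frame with columns `doc_id`, `date`, `title`, `text`.
#'   `date` may be character (ISO-8601 or bare year, normalized to Dec 31).
#' @return a [Corpus-class] object.
#' @export
Corpus <- function(documents = data.frame(doc_id = character(), date = as.Date(character()),
                                          title = character(), text = character(),
                                          stringsAsFactors = FALSE)) {
  if (!inherits(documents$date, "Date"))
    documents$date <- parseDate(documents$date)
  documents$doc_id <- as.character(documents$doc_id)
  documents$title <- as.character(documents$title)
  documents$text <- as.character(documents$text)
  rownames(documents) <- NULL
  new("Corpus", documents = documents[, c("doc_id", "date", "title", "text")])
}

#' @describeIn Corpus-class number of documents
#' @param x a `Corpus`
#' @export
setMethod("length", "Corpus", function(x) nrow(x@documents))

#' Accessor for the document table of a Corpus
#' @param x a [Corpus-class]
#' @return data.frame of documents
#' @export
documents <- function(x) {
  stopifnot(is(x, "Corpus"))
  x@documents
}

setMethod("show", "Corpus", function(object) {
  d <- object@documents
  cat("Corpus with", nrow(d), "documents")
  if (nrow(d) > 0)
    cat("; dates", format(min(d$date)), "to", format(max(d$date)))
  cat("\n")
})

#' Gene dictionary: symbols and synonyms
#'
#' Maps each gene identifier (HGNC-style symbol) to its set of surface forms
#' (the symbol itself plus synonyms). Surface forms attached to more than one
#' gene are recorded as ambiguous; under the default `strict` annotation
#' policy their mentions are not attributed to any gene, which guards against
#' the synonym-collision failure mode seen with hnRNPH/hnRNPH1/hnRNPH2
#' nomenclature.
#'
#' Ambiguity is judged in the same key space used for matching:
#' case-insensitively for forms of 5+ characters, case-sensitively below.
#'
#' @slot entries named list, gene id -> character vector of surface forms
#'   (always containing the symbol itself).
#' @slot ambiguousForms character vector of surface forms shared by >= 2 genes.
#' @seealso [readGeneDictionary()], [annotateCorpus()]
#' @export
setClass("GeneDictionary",
         representation(entries = "list", ambiguousForms = "character"))

setValidity("GeneDictionary", function(object) {
  e <- object@entries
  if (length(e) == 0) return(TRUE)
  if (is.null(names(e)) || any(!nzchar(names(e))))
    return("entries must be named by gene symbol")
  if (anyDuplicated(names(e)))
    return("duplicate gene symbols in dictionary")
  own <- vapply(seq_along(e), function(i) names(e)[i] %in% e[[i]], logical(1))
  if (!all(own))
    return("every gene's surface-form set must contain its own symbol")
  TRUE
})

setMethod("show", "GeneDictionary", function(object) {
  cat("GeneDictionary with", length(object@entries), "genes,",
      length(object@ambiguousForms), "ambiguous surface forms\n")
})

#' @describeIn GeneDictionary-class number of genes
#' @param x a `GeneDictionary`
#' @export
setMethod("length", "GeneDictionary", function(x) length(x@entries))

#' Accessors for GeneDictionary
#' @param x a [GeneDictionary-class]
#' @return `dictionaryEntries`: named list gene -> surface forms;
#'   `ambiguousForms`: character vector; `dictionaryGenes`: gene symbols.
#' @export
dictionaryEntries <- function(x) {
  stopifnot(is(x, "GeneDictionary"))
  x@entries
}

#' @rdname dictionaryEntries
#' @export
ambiguousForms <- function(x) {
  stopifnot(is(x, "GeneDictionary"))
  x@ambiguousForms
}

#' @rdname dictionaryEntries
#' @export
dictionaryGenes <- function(x) {
  stopifnot(is(x, "GeneDictionary"))
  names(x@entries)
}

#' Annotated corpus: resolved gene mentions
#'
#' The result of scanning a [Corpus-class] with a [GeneDictionary-class].
#' Mentions record the matched surface form and its character span in the
#' concatenated title + text; mentions of ambiguous surface forms carry
#' `NA` in the `gene` column. `geneDocs` inverts the unambiguous mentions:
#' for each gene, the set of documents mentioning it.
#'
#' @slot corpus the annotated [Corpus-class].
#' @slot mentions data.frame with columns `doc_id`, `gene` (NA when the
#'   surface form is ambiguous and the policy is strict), `surface`,
#'   `start`, `end` (half-open, 1-based start).
#' @slot geneDocs named list, gene id -> character vector of doc_ids.
#' @slot dictionary the [GeneDictionary-class] used for annotation.
#' @slot policy the disambiguation policy used ("strict" or "first-gene").
#' @export
setClass("AnnotatedCorpus",
         representation(corpus = "Corpus", mentions = "data.frame",
                        geneDocs = "list", dictionary = "GeneDictionary",
                        policy = "character"))

setMethod("show", "AnnotatedCorpus", function(object) {
  m <- object@mentions
  cat("AnnotatedCorpus:", length(object@corpus), "documents,",
      nrow(m), "mentions (", sum(is.na(m$gene)), "ambiguous ),",
      length(object@geneDocs), "genes with documents; policy:",
      object@policy, "\n")
})

#' Accessors for AnnotatedCorpus
#' @param x an [AnnotatedCorpus-class]
#' @return `mentions`: the mention table; `geneDocs`: named list gene ->
#'   doc ids with an unambiguous mention.
#' @export
mentions <- function(x) {
  stopifnot(is(x, "AnnotatedCorpus"))
  x@mentions
}

#' @rdname mentions
#' @export
geneDocs <- function(x) {
  stopifnot(is(x, "AnnotatedCorpus"))
  x@geneDocs
}

#' Entity-by-term semantic profile matrix
#'
#' Sparse non-negative matrix of term weights per gene, pooled over all
#' abstracts with an unambiguous mention of that gene. Rows are genes,
#' columns are vocabulary terms. Weighting is either raw summed counts or
#' sublinear TF-IDF. All-zero rows (genes with no usable documents) are
#' permitted and flagged with a warning at build time.
#'
#' @slot weights a `dgCMatrix` (genes x terms), dimnames set.
#' @slot weighting "raw" or "tfidf".
#' @slot stopwordVersion version tag of the stopword list applied.
#' @seealso [buildProfiles()], [similarityMatrix()]
#' @export
setClass("EntityTermMatrix",
         representation(weights = "Matrix", weighting = "character",
                        stopwordVersion = "character"))

setValidity("EntityTermMatrix", function(object) {
  if (!object@weighting %in% c("raw", "tfidf"))
    return("weighting must be 'raw' or 'tfidf'")
  if (any(object@weights@x < 0))
    return("weights must be non-negative")
  if (is.null(rownames(object@weights)))
    return("weights must have entity rownames")
  TRUE
})

setMethod("show", "EntityTermMatrix", function(object) {
  w <- object@weights
  cat("EntityTermMatrix:", nrow(w), "entities x", ncol(w), "terms (",
      object@weighting, "weighting,", format(length(w@x)), "non-zero entries )\n")
})

#' Accessors for EntityTermMatrix
#' @param x an [EntityTermMatrix-class]
#' @return `profileMatrix`: the sparse weight matrix; `entities`: gene ids.
#' @export
profileMatrix <- function(x) {
  stopifnot(is(x, "EntityTermMatrix"))
  x@weights
}

#' @rdname profileMatrix
#' @export
entities <- function(x) {
  if (is(x, "EntityTermMatrix")) return(rownames(x@weights))
  if (is(x, "SimilarityMatrix")) return(rownames(x@sim))
  stop("no entities accessor for this class")
}

#' Gene-gene similarity matrix
#'
#' Symmetric cosine-similarity matrix over gene semantic profiles, entries
#' in [0, 1], diagonal fixed at 0 (a gene's similarity to itself carries no
#' ranking information; distance is defined as 1 - similarity). Pairs
#' involving an all-zero profile get similarity 0.
#'
#' @slot sim symmetric numeric matrix with entity dimnames.
#' @seealso [similarityMatrix()], [transitionMatrix()]
#' @export
setClass("SimilarityMatrix", representation(sim = "matrix"))

setValidity("SimilarityMatrix", function(object) {
  s <- object@sim
  if (nrow(s) != ncol(s)) return("sim must be square")
  if (is.null(rownames(s)) || !identical(rownames(s), colnames(s)))
    return("sim must have matching row/col entity names")
  if (any(abs(s - t(s)) > 1e-12)) return("sim must be symmetric")
  if (any(s < -1e-12) || any(s > 1 + 1e-12)) return("sim entries must lie in [0,1]")
  if (any(abs(diag(s)) > 1e-12)) return("sim diagonal must be zero")
  TRUE
})

setMethod("show", "SimilarityMatrix", function(object) {
  cat("SimilarityMatrix over", nrow(object@sim), "entities; mean off-diagonal",
      format(mean(object@sim[upper.tri(object@sim)]), digits = 4), "\n")
})

#' @rdname similarityMatrix
#' @param x a `SimilarityMatrix`
#' @param ... unused
#' @export
setMethod("as.matrix", "SimilarityMatrix", function(x, ...) x@sim)

#' Ranked candidate list
#'
#' Candidates ordered by graph-diffusion (GD) score, the steady-state mass
#' each node receives from the seed set. Seed (known) genes keep their
#' scores internally so total mass sums to 1, but are excluded from the
#' candidate ranking.
#'
#' @slot knownSet character vector of seed gene ids.
#' @slot candidates data.frame with columns `rank` (1-based), `gene`,
#'   `gd_score`, sorted by decreasing score with lexicographic tie-break.
#' @slot scores full named score vector over all nodes (seeds + candidates).
#' @export
setClass("RankedList",
         representation(knownSet = "character", candidates = "data.frame",
                        scores = "numeric"))

setValidity("RankedList", function(object) {
  cd <- object@candidates
  if (!all(c("rank", "gene", "gd_score") %in% names(cd)))
    return("candidates needs columns rank, gene, gd_score")
  if (length(intersect(object@knownSet, cd$gene)) > 0)
    return("known set and candidates must be disjoint")
  if (nrow(cd) > 0) {
    if (!identical(as.integer(cd$rank), seq_len(nrow(cd))))
      return("ranks must be 1..n in order")
    if (is.unsorted(rev(cd$gd_score)))
      return("gd_score must be non-increasing with rank")
  }
  if (abs(sum(object@scores) - 1) > 1e-9)
    return("node scores must sum to 1")
  TRUE
})

setMethod("show", "RankedList", function(object) {
  cat("RankedList:", length(object@knownSet), "seeds,",
      nrow(object@candidates), "ranked candidates\n")
  print(utils::head(object@candidates, 5))
})

#' Accessors for RankedList
#' @param x a [RankedList-class]
#' @return `rankedCandidates`: data.frame `rank`, `gene`, `gd_score`;
#'   `knownSet`: seed gene ids; `nodeScores`: full score vector.
#' @export
rankedCandidates <- function(x) {
  stopifnot(is(x, "RankedList"))
  x@candidates
}

#' @rdname rankedCandidates
#' @export
knownSet <- function(x) {
  stopifnot(is(x, "RankedList"))
  x@knownSet
}

#' @rdname rankedCandidates
#' @export
nodeScores <- function(x) {
  stopifnot(is(x, "RankedList"))
  x@scores
}

#' Leave-one-out cross-validation report
#'
#' Per-held-out ranks of the known genes plus the summary statistics
#' computed from them: pooled trapezoid-rule AUC, one-sided Wilcoxon
#' rank-sum p, the median of rank-threshold Fisher exact p values, and
#' counts of held-out ranks at or under each requested threshold.
#'
#' @slot looRanks data.frame with columns `gene`, `rank` (rank of the
#'   held-out known among candidates plus itself).
#' @slot nCandidates number of candidates each held-out gene competed with.
#' @slot auc pooled trapezoid-rule area under the ROC curve.
#' @slot wilcoxonP one-sided Wilcoxon rank-sum p value.
#' @slot thresholdFisherMedianP median rank-threshold Fisher p value.
#' @slot topCounts named integer vector, threshold -> count of ranks <= it.
#' @seealso [looReport()], [looCrossValidation()]
#' @export
setClass("LOOReport",
         representation(looRanks = "data.frame", nCandidates = "integer",
                        auc = "numeric", wilcoxonP = "numeric",
                        thresholdFisherMedianP = "numeric",
                        topCounts = "integer"))

setValidity("LOOReport", function(object) {
  r <- object@looRanks
  if (!all(c("gene", "rank") %in% names(r)))
    return("looRanks needs columns gene, rank")
  if (any(r$rank < 1) || any(r$rank > object@nCandidates + 1))
    return("ranks must lie in 1..nCandidates+1")
  if (object@auc < 0 || object@auc > 1) return("auc must lie in [0,1]")
  TRUE
})

setMethod("show", "LOOReport", function(object) {
  cat("LOOReport:", nrow(object@looRanks), "held-out knowns vs",
      object@nCandidates, "candidates\n")
  cat("  AUC", format(object@auc, digits = 4),
      "| Wilcoxon p", format(object@wilcoxonP, digits = 3),
      "| median threshold-Fisher p",
      format(object@thresholdFisherMedianP, digits = 3), "\n")
  if (length(object@topCounts))
    cat("  top counts:",
        paste(sprintf("<=%s: %d", names(object@topCounts), object@topCounts),
              collapse = ", "), "\n")
})

#' Accessors for LOOReport
#' @param x a [LOOReport-class]
#' @return `looRanks`: data.frame of held-out ranks; `reportStats`: named
#'   list of the summary statistics.
#' @export
looRanks <- function(x) {
  stopifnot(is(x, "LOOReport"))
  x@looRanks
}

#' @rdname looRanks
#' @export
reportStats <- function(x) {
  stopifnot(is(x, "LOOReport"))
  list(n_candidates = x@nCandidates, auc = x@auc, wilcoxon_p = x@wilcoxonP,
       threshold_fisher_median_p = x@thresholdFisherMedianP,
       top_counts = as.list(setNames(as.integer(x@topCounts), names(x@topCounts))))
}
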