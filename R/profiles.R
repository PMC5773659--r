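#' Tokenize abstract text
#'
#' Lowercases, splits on any character that is not a letter, digit or
#' hyphen, strips leading/trailing hyphens, and drops tokens shorter than
#' two characters. Internal hyphens are preserved so forms like "tdp-43"
#' survive as single tokens.
#'
#' @param x character vector of texts.
#' @return list of character token vectors, one per input text.
#' @export
tokenize <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9-]+", " ", x)
  toks <- strsplit(trimws(x), "\\s+")
  lapply(toks, function(t) {
    t <- gsub("^-+|-+$", "", t)
    t[nchar(t) >= 2L]
  })
}

#' Build per-gene semantic term profiles
#'
#' For each entity, the tokens of every abstract with an unambiguous
#' mention of that gene are pooled (title and text), stopwords and the
#' entity's own surface forms are removed (so similarity reflects context,
#' not name co-occurrence), and term weights are computed as raw summed
#' counts or sublinear TF-IDF: `(1 + log(count)) * log(N / df)` with `N`
#' the number of entities and `df` the number of entities containing the
#' term. A term present in every entity therefore gets weight 0 everywhere.
#' An entity with no documents yields an all-zero row and a warning.
#'
#' @param annotated an [AnnotatedCorpus-class].
#' @param entityIds gene ids to profile (rows of the result, in sorted order).
#' @param weighting "tfidf" (default) or "raw".
#' @return an [EntityTermMatrix-class].
#' @seealso [similarityMatrix()]
#' @export
buildProfiles <- function(annotated, entityIds, weighting = c("tfidf", "raw")) {
  stopifnot(is(annotated, "AnnotatedCorpus"))
  weighting <- match.arg(weighting)
  entityIds <- sort(unique(as.character(entityIds)))
  if (length(entityIds) == 0) stop("no entities requested", call. = FALSE)

  d <- annotated@corpus@documents
  docTokens <- tokenize(paste(d$title, d$text))
  names(docTokens) <- d$doc_id
  sw <- litpropStopwords()

  # counts per entity as named integer vectors
  countList <- lapply(entityIds, function(e) {
    docs <- annotated@geneDocs[[e]]
    if (is.null(docs) || length(docs) == 0) return(integer())
    toks <- unlist(docTokens[docs], use.names = FALSE)
    ownForms <- unlist(tokenize(dictionaryFormsOf(annotated, e)), use.names = FALSE)
    toks <- toks[!(toks %in% sw) & !(toks %in% ownForms)]
    if (length(toks) == 0) return(integer())
    table(toks)
  })
  empty <- vapply(countList, length, integer(1)) == 0
  if (any(empty))
    warning("entities with empty profiles: ",
            paste(entityIds[empty], collapse = ", "), call. = FALSE)

  terms <- sort(unique(unlist(lapply(countList, names), use.names = FALSE)))
  if (length(terms) == 0) terms <- character()
  i <- rep(seq_along(countList), vapply(countList, length, integer(1)))
  j <- match(unlist(lapply(countList, names), use.names = FALSE), terms)
  x <- as.numeric(unlist(countList, use.names = FALSE))
  w <- Matrix::sparseMatrix(i = i, j = j, x = x,
                            dims = c(length(entityIds), max(length(terms), 1L)),
                            dimnames = list(entityIds,
                                            if (length(terms)) terms else "..empty.."))
  if (weighting == "tfidf" && length(w@x)) {
    df <- Matrix::colSums(w > 0)
    idf <- log(length(entityIds) / pmax(df, 1))
    w@x <- 1 + log(w@x)
    w <- w %*% Matrix::Diagonal(x = idf)
    dimnames(w) <- list(entityIds, if (length(terms)) terms else "..empty..")
    w <- methods::as(Matrix::drop0(w), "CsparseMatrix")
  } else {
    w <- methods::as(w, "CsparseMatrix")
  }
  new("EntityTermMatrix", weights = w, weighting = weighting,
      stopwordVersion = attr(sw, "version"))
}

# surface forms of an entity, from the dictionary used at annotation time
dictionaryFormsOf <- function(annotated, entity) {
  forms <- annotated@dictionary@entries[[entity]]
  unique(c(entity, forms))
}

#' Gene-gene cosine similarity matrix
#'
#' Cosine similarity between every pair of entity profiles. Non-negative
#' weights guarantee entries in [0, 1]. Any pair involving an all-zero
#' profile gets similarity 0, and the diagonal is set to 0 (the graph has
#' no self-loops; distance is 1 - similarity).
#'
#' @param profiles an [EntityTermMatrix-class] with at least two entities.
#' @return a [SimilarityMatrix-class].
#' @export
similarityMatrix <- function(profiles) {
  stopifnot(is(profiles, "EntityTermMatrix"))
  w <- profiles@weights
  if (nrow(w) < 2) stop("need at least 2 entities", call. = FALSE)
  norms <- sqrt(Matrix::rowSums(w^2))
  inv <- ifelse(norms > 0, 1 / norms, 0)
  wn <- Matrix::Diagonal(x = inv) %*% w
  s <- as.matrix(Matrix::tcrossprod(wn))
  dimnames(s) <- list(rownames(w), rownames(w))
  s[s < 0] <- 0
  s[s > 1] <- 1
  diag(s) <- 0
  s <- (s + t(s)) / 2
  new("SimilarityMatrix", sim = s)
}
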