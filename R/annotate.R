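escapeRegex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

# One alternation pattern for a set of surface forms, longest first so the
# scan prefers the longest form starting at a position. Word boundaries:
# a match may not be flanked by letters or digits (internal hyphens are
# allowed, so TDP-43 matches as a unit).
formPattern <- function(forms) {
  forms <- forms[order(-nchar(forms), forms)]
  paste0("(?<![A-Za-z0-9])(?:",
         paste(escapeRegex(forms), collapse = "|"),
         ")(?![A-Za-z0-9])")
}

matchesFromGregexpr <- function(g, texts) {
  lapply(seq_along(g), function(i) {
    m <- g[[i]]
    if (m[1] == -1) return(NULL)
    len <- attr(m, "match.length")
    data.frame(start = as.integer(m), len = as.integer(len),
               surface = substring(texts[i], m, m + len - 1L),
               stringsAsFactors = FALSE)
  })
}

#' Annotate gene mentions in a corpus
#'
#' Scans the concatenated title and text of every document for dictionary
#' surface forms, using a longest-match, non-overlapping, word-boundary
#' scan. Forms of 5 or more characters match case-insensitively; shorter
#' forms match case-sensitively (protecting short symbols from hits inside
#' ordinary words). A mention of a surface form shared by several genes is
#' ambiguous: under the default `strict` policy it is recorded but
#' attributed to no gene, so it never contributes evidence; under
#' `first-gene` it is attributed to the lexicographically first gene — a
#' policy provided only to demonstrate the false-positive failure mode that
#' shared nomenclature (e.g. hnRNPH for both HNRNPH1 and HNRNPH2) creates.
#'
#' @param corpus a [Corpus-class].
#' @param dict a [GeneDictionary-class]; must contain at least one gene.
#' @param policy "strict" (default) or "first-gene".
#' @return an [AnnotatedCorpus-class].
#' @examples
#' co <- Corpus(data.frame(doc_id = "d1", date = "2010-01-01", title = "",
#'                         text = "TDP-43 mislocalization in ALS"))
#' d <- geneDictionary(list(TARDBP = "TDP-43"))
#' geneDocs(annotateCorpus(co, d))
#' @export
annotateCorpus <- function(corpus, dict, policy = c("strict", "first-gene")) {
  stopifnot(is(corpus, "Corpus"), is(dict, "GeneDictionary"))
  policy <- match.arg(policy)
  if (length(dict@entries) == 0)
    stop("dictionary is empty; nothing to annotate", call. = FALSE)

  allForms <- unlist(dict@entries, use.names = FALSE)
  formGene <- rep(names(dict@entries), lengths(dict@entries))
  keyGenes <- lapply(split(formGene, matchKey(allForms)),
                     function(g) sort(unique(g)))

  ciForms <- unique(allForms[nchar(allForms) >= 5L])
  csForms <- unique(allForms[nchar(allForms) < 5L])

  d <- corpus@documents
  texts <- paste(d$title, d$text)
  ciHits <- csHits <- rep(list(NULL), nrow(d))
  if (length(ciForms) && nrow(d) > 0) {
    g <- gregexpr(formPattern(ciForms), texts, perl = TRUE, ignore.case = TRUE)
    ciHits <- matchesFromGregexpr(g, texts)
  }
  if (length(csForms) && nrow(d) > 0) {
    g <- gregexpr(formPattern(csForms), texts, perl = TRUE, ignore.case = FALSE)
    csHits <- matchesFromGregexpr(g, texts)
  }

  mentionList <- vector("list", nrow(d))
  for (i in seq_len(nrow(d))) {
    hits <- NULL
    if (!is.null(ciHits[[i]])) {
      ciHits[[i]]$key <- tolower(ciHits[[i]]$surface)
      hits <- ciHits[[i]]
    }
    if (!is.null(csHits[[i]])) {
      csHits[[i]]$key <- csHits[[i]]$surface
      hits <- rbind(hits, csHits[[i]])
    }
    if (is.null(hits) || nrow(hits) == 0) next
    # leftmost-longest, non-overlapping resolution across both case classes
    hits <- hits[order(hits$start, -hits$len), , drop = FALSE]
    keep <- logical(nrow(hits))
    lastEnd <- 0L
    for (j in seq_len(nrow(hits))) {
      if (hits$start[j] > lastEnd) {
        keep[j] <- TRUE
        lastEnd <- hits$start[j] + hits$len[j] - 1L
      }
    }
    hits <- hits[keep, , drop = FALSE]
    genes <- keyGenes[hits$key]
    nGene <- lengths(genes)
    ambiguous <- nGene > 1L
    gene <- vapply(seq_along(genes), function(j) {
      if (nGene[j] == 1L) genes[[j]]
      else if (policy == "first-gene") genes[[j]][1]
      else NA_character_
    }, character(1))
    mentionList[[i]] <- data.frame(
      doc_id = d$doc_id[i], gene = gene, surface = hits$surface,
      start = hits$start, end = hits$start + hits$len,
      ambiguous = ambiguous, stringsAsFactors = FALSE)
  }
  mentionDf <- do.call(rbind, c(mentionList, list(
    data.frame(doc_id = character(), gene = character(), surface = character(),
               start = integer(), end = integer(), ambiguous = logical(),
               stringsAsFactors = FALSE))))
  rownames(mentionDf) <- NULL

  attributed <- mentionDf[!is.na(mentionDf$gene), , drop = FALSE]
  gd <- lapply(split(attributed$doc_id, attributed$gene), function(x) sort(unique(x)))

  new("AnnotatedCorpus", corpus = corpus, mentions = mentionDf,
      geneDocs = gd, dictionary = dict, policy = policy)
}

#' Genes eligible as ranking entities at a cutoff date
#'
#' A gene is eligible when it has at least one unambiguous mention in an
#' abstract dated on or before the cutoff — the "mentioned in at least one
#' abstract" criterion that defines which genes can be ranked at all.
#'
#' @param annotated an [AnnotatedCorpus-class].
#' @param genes candidate gene ids to test.
#' @param cutoff cutoff date (`Date` or string, see [parseDate()]).
#' @return sorted character vector, the subset of `genes` that is eligible.
#' @export
eligibleEntities <- function(annotated, genes, cutoff) {
  stopifnot(is(annotated, "AnnotatedCorpus"))
  if (!inherits(cutoff, "Date")) cutoff <- parseDate(cutoff)
  d <- annotated@corpus@documents
  okDocs <- d$doc_id[d$date <= cutoff]
  m <- annotated@mentions
  m <- m[!m$ambiguous & !is.na(m$gene) & m$doc_id %in% okDocs, , drop = FALSE]
  sort(intersect(unique(m$gene), genes))
}
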