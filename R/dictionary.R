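# Matching key for a surface form: forms of >= 5 characters match
# case-insensitively (keyed lowercase); shorter forms match case-sensitively,
# so short symbols like ANG cannot fire inside ordinary lowercase words.
matchKey <- function(forms) {
  ifelse(nchar(forms) >= 5L, tolower(forms), forms)
}

#' Construct a GeneDictionary from an entries list
#'
#' @param entries named list: gene symbol -> character vector of synonyms
#'   (the symbol itself is added if absent).
#' @return a [GeneDictionary-class] with ambiguous forms computed.
#' @examples
#' d <- geneDictionary(list(HNRNPH1 = "hnRNPH", HNRNPH2 = "hnRNPH"))
#' ambiguousForms(d)
#' @export
geneDictionary <- function(entries = list()) {
  if (length(entries)) {
    entries <- lapply(seq_along(entries), function(i) {
      unique(c(names(entries)[i], as.character(entries[[i]])))
    }) |> stats::setNames(names(entries))
  }
  new("GeneDictionary", entries = entries,
      ambiguousForms = findAmbiguousForms(entries))
}

findAmbiguousForms <- function(entries) {
  if (length(entries) == 0) return(character())
  forms <- unlist(entries, use.names = FALSE)
  gene <- rep(names(entries), lengths(entries))
  key <- matchKey(forms)
  nGenes <- vapply(split(gene, key), function(g) length(unique(g)), integer(1))
  shared <- names(nGenes)[nGenes >= 2]
  sort(unique(forms[key %in% shared]))
}

#' Load a gene dictionary from TSV
#'
#' Expects a header row `symbol<TAB>synonyms`; synonyms are pipe-separated
#' and may be empty. Duplicate symbol rows and empty symbols are rejected.
#' Surface forms shared by two or more genes (case-insensitively for forms
#' of 5+ characters) are recorded as ambiguous.
#'
#' @param path path to the TSV file.
#' @return a [GeneDictionary-class].
#' @seealso [writeGeneDictionary()], [annotateCorpus()]
#' @export
readGeneDictionary <- function(path) {
  if (!file.exists(path)) stop("dictionary file not found: ", path, call. = FALSE)
  d <- utils::read.delim(path, sep = "\t", header = TRUE,
                         colClasses = "character", quote = "",
                         stringsAsFactors = FALSE)
  if (!all(c("symbol", "synonyms") %in% names(d)))
    stop("dictionary TSV must have columns 'symbol' and 'synonyms'", call. = FALSE)
  if (nrow(d) == 0) return(geneDictionary())
  if (any(!nzchar(trimws(d$symbol))))
    stop("empty symbol in dictionary row ",
         which(!nzchar(trimws(d$symbol)))[1], call. = FALSE)
  if (anyDuplicated(d$symbol))
    stop("duplicate symbol row: ", d$symbol[duplicated(d$symbol)][1], call. = FALSE)
  syns <- lapply(d$synonyms, function(s) {
    parts <- strsplit(s, "|", fixed = TRUE)[[1]]
    parts[nzchar(trimws(parts))]
  })
  geneDictionary(stats::setNames(syns, d$symbol))
}

#' Write a gene dictionary as TSV
#'
#' @param dict a [GeneDictionary-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGeneDictionary <- function(dict, path) {
  stopifnot(is(dict, "GeneDictionary"))
  syn <- vapply(seq_along(dict@entries), function(i) {
    paste(setdiff(dict@entries[[i]], names(dict@entries)[i]), collapse = "|")
  }, character(1))
  utils::write.table(data.frame(symbol = names(dict@entries), synonyms = syn),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
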