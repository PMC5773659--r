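#' Parse ISO-8601 dates, with year-only normalization
#'
#' Full `YYYY-MM-DD` dates are parsed as-is; a bare `YYYY` is normalized to
#' December 31 of that year (year stamps are the realistic granularity for
#' abstract records, and the inclusive-cutoff convention used throughout
#' the package makes end-of-year the faithful reading of "published through"
#' a given year).
#'
#' @param x character vector of dates.
#' @return `Date` vector.
#' @examples
#' parseDate(c("2012-06-01", "2012"))
#' @export
parseDate <- function(x) {
  x <- as.character(x)
  out <- rep(as.Date(NA), length(x))
  yearOnly <- grepl("^\\d{4}$", x)
  if (any(yearOnly))
    out[yearOnly] <- as.Date(paste0(x[yearOnly], "-12-31"))
  full <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  if (any(full))
    out[full] <- as.Date(x[full], format = "%Y-%m-%d")
  bad <- !yearOnly & !full | is.na(out)
  if (any(bad))
    stop("unparseable date(s): ", paste(unique(x[bad]), collapse = ", "),
         call. = FALSE)
  out
}

#' Read a corpus from JSON-lines
#'
#' One JSON object per line with keys `doc_id`, `date`, `title`, `text`.
#' Records are returned in file order. A missing key or unparseable date is
#' reported with its line number; duplicate `doc_id`s are rejected.
#'
#' @param path path to a JSONL file (UTF-8).
#' @return a [Corpus-class].
#' @seealso [writeCorpus()]
#' @export
readCorpus <- function(path) {
  if (!file.exists(path)) stop("corpus file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(Corpus())
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e) stop("line ", i, ": invalid JSON (",
                                             conditionMessage(e), ")", call. = FALSE))
    missing <- setdiff(c("doc_id", "date", "title", "text"), names(rec))
    if (length(missing))
      stop("line ", i, ": missing key(s) ", paste(missing, collapse = ", "),
           call. = FALSE)
    rec$date <- tryCatch(parseDate(rec$date),
                         error = function(e) stop("line ", i, ": ",
                                                  conditionMessage(e), call. = FALSE))
    recs[[i]] <- data.frame(doc_id = as.character(rec$doc_id), date = rec$date,
                            title = as.character(rec$title),
                            text = as.character(rec$text),
                            stringsAsFactors = FALSE)
  }
  d <- do.call(rbind, recs)
  if (anyDuplicated(d$doc_id))
    stop("duplicate doc_id: ", d$doc_id[duplicated(d$doc_id)][1], call. = FALSE)
  Corpus(d)
}

#' Write a corpus as JSON-lines
#'
#' @param corpus a [Corpus-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeCorpus <- function(corpus, path) {
  stopifnot(is(corpus, "Corpus"))
  d <- corpus@documents
  lines <- vapply(seq_len(nrow(d)), function(i) {
    jsonlite::toJSON(list(doc_id = d$doc_id[i], date = format(d$date[i]),
                          title = d$title[i], text = d$text[i]),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Restrict a corpus to documents published up to a cutoff date
#'
#' Keeps exactly the documents dated on or before `cutoff` (inclusive):
#' a corpus "published prior to 2013" is the slice at cutoff 2012-12-31,
#' i.e. everything published through the end of 2012. The input corpus is
#' not modified.
#'
#' @param corpus a [Corpus-class].
#' @param cutoff a `Date` or ISO-8601 / bare-year string (see [parseDate()]).
#' @return a new [Corpus-class] with the retained documents, in order.
#' @examples
#' co <- Corpus(data.frame(doc_id = c("a", "b"),
#'                         date = c("2012-12-31", "2013-01-01"),
#'                         title = "", text = ""))
#' length(sliceByDate(co, "2012-12-31"))  # 1
#' @export
sliceByDate <- function(corpus, cutoff) {
  stopifnot(is(corpus, "Corpus"))
  if (!inherits(cutoff, "Date")) cutoff <- parseDate(cutoff)
  d <- corpus@documents
  Corpus(d[d$date <= cutoff, , drop = FALSE])
}

#' Write a ranked candidate list as TSV
#'
#' Columns `rank`, `gene`, `gd_score`, one candidate per row.
#'
#' @param ranked a [RankedList-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeRankedList <- function(ranked, path) {
  stopifnot(is(ranked, "RankedList"))
  utils::write.table(ranked@candidates[, c("rank", "gene", "gd_score")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
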