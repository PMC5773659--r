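#' English stopword list shipped with the package
#'
#' A fixed, versioned list of common English function words removed during
#' tokenization before profile building. Results that depend on profiles
#' should cite the version tag so they remain reproducible if the list is
#' ever revised.
#'
#' @return character vector of stopwords; the version tag is in
#'   `attr(, "version")`.
#' @examples
#' head(litpropStopwords())
#' attr(litpropStopwords(), "version")
#' @export
litpropStopwords <- function() {
  sw <- c(
    "a", "about", "above", "after", "again", "against", "all", "am", "an",
    "and", "any", "are", "as", "at", "be", "because", "been", "before",
    "being", "below", "between", "both", "but", "by", "can", "could", "did",
    "do", "does", "doing", "down", "during", "each", "few", "for", "from",
    "further", "had", "has", "have", "having", "he", "her", "here", "hers",
    "him", "his", "how", "i", "if", "in", "into", "is", "it", "its",
    "itself", "just", "may", "me", "might", "more", "most", "must", "my",
    "no", "nor", "not", "now", "of", "off", "on", "once", "only", "or",
    "other", "our", "ours", "out", "over", "own", "same", "she", "should",
    "so", "some", "such", "than", "that", "the", "their", "theirs", "them",
    "then", "there", "these", "they", "this", "those", "through", "to",
    "too", "under", "until", "up", "very", "was", "we", "were", "what",
    "when", "where", "which", "while", "who", "whom", "why", "will", "with",
    "would", "you", "your", "yours"
  )
  attr(sw, "version") <- "en-basic-1.0"
  sw
}
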