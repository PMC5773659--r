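#' Time-sliced retrospective validation run
#'
#' Restricts the corpus to documents published on or before the cutoff,
#' annotates the slice, determines candidate eligibility (at least one
#' unambiguous pre-cutoff mention), builds profiles and the similarity
#' graph from the sliced corpus only, diffuses from the pre-cutoff known
#' set, and reports where the later-discovered positives land in the
#' ranking. Nothing published after the cutoff can influence the result;
#' later positives with no pre-cutoff mention are reported as ineligible
#' rather than force-ranked.
#'
#' @param corpus a [Corpus-class] (full, unsliced).
#' @param dict a [GeneDictionary-class].
#' @param cutoff cutoff date (`Date` or string; see [parseDate()]).
#' @param knowns gene ids known at the cutoff (the seed set). Every known
#'   must have a pre-cutoff mention; otherwise an error names the gene.
#' @param laterPositives gene ids linked to the disease after the cutoff.
#' @param candidatePool genes rankable in principle; default: all
#'   dictionary genes minus the knowns.
#' @param weighting profile weighting, "tfidf" (default) or "raw".
#' @param policy annotation policy, see [annotateCorpus()].
#' @param alpha,tol,maxIter diffusion parameters, see [graphDiffusion()].
#' @return a list with elements `ranked` ([RankedList-class]),
#'   `later_ranks` (named integer), `later_percentiles` (named numeric,
#'   rank / nCandidates), `ineligible` (later positives with no pre-cutoff
#'   mention), `n_candidates`, and `cutoff`.
#' @export
retrospectiveRun <- function(corpus, dict, cutoff, knowns, laterPositives = character(),
                             candidatePool = NULL, weighting = c("tfidf", "raw"),
                             policy = c("strict", "first-gene"),
                             alpha = 0.7, tol = 1e-9, maxIter = 1000L) {
  stopifnot(is(corpus, "Corpus"), is(dict, "GeneDictionary"))
  weighting <- match.arg(weighting)
  policy <- match.arg(policy)
  if (!inherits(cutoff, "Date")) cutoff <- parseDate(cutoff)
  knowns <- sort(as.character(knowns))
  laterPositives <- sort(as.character(laterPositives))
  if (length(intersect(knowns, laterPositives)))
    stop("knowns and later positives must be disjoint", call. = FALSE)
  if (is.null(candidatePool))
    candidatePool <- setdiff(dictionaryGenes(dict), knowns)
  if (!all(laterPositives %in% candidatePool))
    stop("later positives must lie in the candidate pool", call. = FALSE)

  sliced <- sliceByDate(corpus, cutoff)
  annotated <- annotateCorpus(sliced, dict, policy = policy)

  eligibleKnowns <- eligibleEntities(annotated, knowns, cutoff)
  if (length(eligibleKnowns) < length(knowns))
    stop("known gene(s) with no pre-cutoff mention: ",
         paste(setdiff(knowns, eligibleKnowns), collapse = ", "), call. = FALSE)
  candidates <- eligibleEntities(annotated, setdiff(candidatePool, knowns), cutoff)
  ineligible <- setdiff(laterPositives, candidates)

  profiles <- buildProfiles(annotated, c(knowns, candidates), weighting = weighting)
  sim <- similarityMatrix(profiles)
  ranked <- rankBySeeds(sim, knowns, candidates, alpha = alpha, tol = tol,
                        maxIter = maxIter)

  cd <- rankedCandidates(ranked)
  eligibleLater <- setdiff(laterPositives, ineligible)
  laterRanks <- stats::setNames(cd$rank[match(eligibleLater, cd$gene)], eligibleLater)
  list(ranked = ranked,
       later_ranks = laterRanks,
       later_percentiles = laterRanks / length(candidates),
       ineligible = ineligible,
       n_candidates = length(candidates),
       cutoff = cutoff)
}
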