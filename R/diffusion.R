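#' Column-stochastic transition matrix from a similarity matrix
#'
#' Each column is normalized to sum to 1 (`P[i, j] = sim[i, j] / sum_k
#' sim[k, j]`). Columns with zero sum (isolated nodes) are left at zero and
#' flagged as dangling; at diffusion time their outgoing mass teleports to
#' the seed distribution so total mass is conserved without biasing toward
#' isolated nodes.
#'
#' @param sim a [SimilarityMatrix-class].
#' @return a numeric matrix with attribute `dangling` (logical vector per
#'   column).
#' @seealso [graphDiffusion()]
#' @export
transitionMatrix <- function(sim) {
  stopifnot(is(sim, "SimilarityMatrix"))
  s <- sim@sim
  colsum <- colSums(s)
  dangling <- colsum <= 0
  p <- s
  nd <- !dangling
  p[, nd] <- sweep(s[, nd, drop = FALSE], 2, colsum[nd], "/")
  p[, dangling] <- 0
  attr(p, "dangling") <- dangling
  p
}

#' Random-walk-with-restart graph diffusion
#'
#' Computes the fixed point of `s <- alpha * P s + (1 - alpha) * p0`, where
#' `p0` is uniform over the seed genes, `alpha` is the walk-continuation
#' probability (restart weight `1 - alpha`), and mass arriving at dangling
#' columns teleports back to `p0`. Iteration stops when the L1 change drops
#' below `tol`. The result is a probability distribution over all nodes:
#' non-negative scores summing to 1; each candidate's score is its
#' graph-diffusion (GD) score.
#'
#' @param P transition matrix from [transitionMatrix()].
#' @param seeds non-empty character vector of seed node names.
#' @param alpha walk-continuation weight in (0, 1); default 0.7.
#' @param tol positive L1 convergence threshold; default 1e-9.
#' @param maxIter maximum iterations; default 1000.
#' @return named numeric score vector over all nodes, with attribute
#'   `iterations`.
#' @examples
#' s <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
#' P <- transitionMatrix(new("SimilarityMatrix", sim = s))
#' graphDiffusion(P, "A", alpha = 0.5)  # (2/3, 1/3)
#' @export
graphDiffusion <- function(P, seeds, alpha = 0.7, tol = 1e-9, maxIter = 1000L) {
  nodes <- rownames(P)
  if (is.null(nodes)) stop("transition matrix must have node names", call. = FALSE)
  if (length(seeds) == 0) stop("seed set must be non-empty", call. = FALSE)
  if (!all(seeds %in% nodes))
    stop("seeds not in node set: ",
         paste(setdiff(seeds, nodes), collapse = ", "), call. = FALSE)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)", call. = FALSE)
  if (tol <= 0) stop("tol must be positive", call. = FALSE)
  if (maxIter < 1) stop("maxIter must be >= 1", call. = FALSE)

  dangling <- attr(P, "dangling")
  if (is.null(dangling)) dangling <- colSums(P) <= 0
  p0 <- stats::setNames(numeric(length(nodes)), nodes)
  p0[seeds] <- 1 / length(seeds)

  s <- p0
  for (iter in seq_len(maxIter)) {
    danglingMass <- sum(s[dangling])
    sNew <- alpha * (as.vector(P %*% s) + danglingMass * p0) + (1 - alpha) * p0
    delta <- sum(abs(sNew - s))
    s <- sNew
    if (delta < tol) {
      names(s) <- nodes
      attr(s, "iterations") <- iter
      return(s)
    }
  }
  stop("diffusion did not converge in ", maxIter,
       " iterations (last L1 residual ", format(delta), ")", call. = FALSE)
}

#' Rank candidates by graph-diffusion score
#'
#' Sorts the candidate genes by decreasing GD score, breaking ties by gene
#' id (ascending), and assigns 1-based ranks. Seed genes keep their scores
#' internally (so all node scores still sum to 1) but never appear in the
#' candidate ranking.
#'
#' @param scores named score vector from [graphDiffusion()].
#' @param knowns seed gene ids.
#' @param candidates candidate gene ids; must be disjoint from `knowns`.
#' @return a [RankedList-class].
#' @export
rankCandidates <- function(scores, knowns, candidates) {
  if (length(intersect(knowns, candidates)) > 0)
    stop("known set and candidate set overlap: ",
         paste(utils::head(intersect(knowns, candidates), 3), collapse = ", "),
         call. = FALSE)
  missing <- setdiff(c(knowns, candidates), names(scores))
  if (length(missing))
    stop("no scores for: ", paste(utils::head(missing, 3), collapse = ", "),
         call. = FALSE)
  cand <- sort(as.character(candidates))
  sc <- scores[cand]
  ord <- order(-sc, cand, method = "radix")
  df <- data.frame(rank = seq_along(cand), gene = cand[ord],
                   gd_score = as.numeric(sc[ord]), stringsAsFactors = FALSE)
  new("RankedList", knownSet = sort(as.character(knowns)), candidates = df,
      scores = stats::setNames(as.numeric(scores), names(scores)))
}

#' End-to-end ranking from a similarity matrix
#'
#' Convenience wrapper: builds the transition matrix, diffuses from the
#' seed set and ranks the candidates.
#'
#' @inheritParams graphDiffusion
#' @param sim a [SimilarityMatrix-class] covering seeds and candidates.
#' @param knowns seed gene ids.
#' @param candidates candidate gene ids.
#' @return a [RankedList-class].
#' @export
rankBySeeds <- function(sim, knowns, candidates, alpha = 0.7, tol = 1e-9,
                        maxIter = 1000L) {
  P <- transitionMatrix(sim)
  s <- graphDiffusion(P, knowns, alpha = alpha, tol = tol, maxIter = maxIter)
  rankCandidates(s, knowns, candidates)
}
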