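## Score construction and topology-aware preprocessing of the similarity
## matrix.

#' Normalized BLAST bit score
#'
#' `nBLAST(x, y) = BLAST(x, y) / sqrt(BLAST(x, x) * BLAST(y, y))`. The
#' normalization removes the length dependence of raw bit scores and maps
#' them into \[0, 1\], with 1 for a protein against itself.
#'
#' @param rawXY bit score of the cross pair (>= 0).
#' @param rawXX,rawYY self bit scores (> 0).
#' @return numeric in \[0, 1\].
#' @examples
#' normalizeBlast(50, 100, 200)
#' @export
normalizeBlast <- function(rawXY, rawXX, rawYY) {
    if (any(rawXX <= 0) || any(rawYY <= 0))
        stop("self bit scores must be positive")
    if (any(rawXY < 0))
        stop("cross bit score must be non-negative")
    rawXY / sqrt(rawXX * rawYY)
}

#' Shared-domain similarity score
#'
#' For the set D of domains shared by two proteins, the score is
#' `sum over d in D of (-ln PV(a, d) - ln PV(b, d))`, where PV is the
#' per-protein domain p-value. Proteins with no shared domain score 0.
#'
#' @param va,vb protein ids.
#' @param table named list: protein id -> named numeric vector of domain
#'   p-values in (0, 1] (see [readDomainPValues()]). Proteins absent from
#'   the table have an empty domain set.
#' @return non-negative numeric score.
#' @examples
#' tab <- list(p1 = c(PF1 = 1e-5), p2 = c(PF1 = 1e-5, PF2 = 0.1))
#' domainSimilarity("p1", "p2", tab)  # 2 * -log(1e-5)
#' @export
domainSimilarity <- function(va, vb, table) {
    pa <- table[[va]] %||% stats::setNames(numeric(), character())
    pb <- table[[vb]] %||% stats::setNames(numeric(), character())
    if (length(pa) && (any(pa <= 0) || any(pa > 1)))
        stop("p-values must be in (0, 1]")
    if (length(pb) && (any(pb <= 0) || any(pb > 1)))
        stop("p-values must be in (0, 1]")
    shared <- intersect(names(pa), names(pb))
    if (!length(shared)) return(0)
    sum(-log(pa[shared]) - log(pb[shared]))
}

#' Greedy neighbour-matching extra score of one protein pair
#'
#' Repeatedly selects the not-yet-selected pair `(a', b')` with `a'` a
#' neighbour of `a`, `b'` a neighbour of `b`, of maximal similarity (ties
#' broken by lexicographically smallest `(a', b')`), adds `sim(a', b')`, and
#' removes both proteins from further selection, until either neighbour set
#' is exhausted. Zero-similarity neighbour pairs contribute nothing and are
#' skipped.
#'
#' @param a,b protein ids in different networks.
#' @param nets a [NetworkCollection-class].
#' @param sim the original [SimilarityMatrix-class].
#' @return the (uncapped) extra score, >= 0.
#' @export
greedyNeighborExtra <- function(a, b, nets, sim) {
    na <- neighborsOf(nets, a)
    nb <- neighborsOf(nets, b)
    if (!length(na) || !length(nb)) return(0)
    cand <- expand.grid(x = na, y = nb, stringsAsFactors = FALSE)
    cand$s <- simScore(sim, cand$x, cand$y)
    cand <- cand[cand$s > 0, , drop = FALSE]
    extra <- 0
    while (nrow(cand)) {
        o <- order(-cand$s, cand$x, cand$y)
        best <- cand[o[1], ]
        extra <- extra + best$s
        cand <- cand[cand$x != best$x & cand$y != best$y, , drop = FALSE]
    }
    extra
}

#' Topology-aware preprocessing of the similarity matrix
#'
#' For every stored cross-network pair, an extra score — the greedy
#' neighbour-matching similarity of the two proteins' neighbourhoods
#' ([greedyNeighborExtra()]) — is added to the original score. The extra
#' score is capped at the original score, so preprocessed scores lie in
#' `[original, 2 * original]` and pairs with no stored score stay at zero.
#' All extras are computed from the original scores only; the input matrix
#' is not modified.
#'
#' @param nets a [NetworkCollection-class].
#' @param sim the original [SimilarityMatrix-class].
#' @return a new [SimilarityMatrix-class] with the same support.
#' @examples
#' fx <- figure2Fixture()
#' pp <- preprocessSimilarity(fx$nets, fx$sim)
#' simScore(pp, "A2", "B2")  # 50 + min(20 + 15, 50) = 85
#' @export
preprocessSimilarity <- function(nets, sim) {
    pairs <- simPairs(sim)
    if (!nrow(pairs)) return(sim)
    extra <- mapply(greedyNeighborExtra, pairs$protein1, pairs$protein2,
                    MoreArgs = list(nets = nets, sim = sim))
    newScore <- pairs$score + pmin(extra, pairs$score)
    SimilarityMatrix(pairs$protein1, pairs$protein2, newScore,
                     proteins = simProteins(sim))
}
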