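## Alignment-quality metrics and the maximum-weight bipartite matching
## baseline. All metrics use the raw (unpreprocessed) similarity matrix.

#' Average similarity score of one match-set
#'
#' Sum of raw similarity over all unordered pairs in the set, divided by
#' `choose(|S|, 2)`. Within-network pairs contribute zero, so match-sets
#' spanning several networks are favoured over same-size sets piling up
#' proteins from one network.
#'
#' @param S character vector of >= 2 protein ids.
#' @param simRaw the raw [SimilarityMatrix-class].
#' @return numeric score.
#' @export
matchSetSimilarity <- function(S, simRaw) {
    S <- unique(as.character(S))
    if (length(S) < 2L) stop("a match-set needs at least 2 proteins")
    present <- intersect(S, simProteins(simRaw))
    tot <- if (length(present) >= 2L)
        sum(simRaw@mat[present, present]) / 2 else 0
    tot / choose(length(S), 2)
}

#' Weighted average similarity score of an alignment
#'
#' `sum_i |S_i| * sim(S_i) / sum_i |S_i|` over all match-sets, on raw
#' scores.
#'
#' @param alignment an [Alignment-class] with >= 1 match-set.
#' @param simRaw the raw [SimilarityMatrix-class].
#' @return numeric score.
#' @examples
#' fx <- figure2Fixture()
#' aln <- Alignment(list(c("A1", "B1"), c("A2", "B2"), c("A3", "B4")))
#' averageSimilarity(aln, fx$sim)  # 85/3
#' @export
averageSimilarity <- function(alignment, simRaw) {
    ms <- matchSets(alignment)
    if (!length(ms)) stop("alignment has no match-sets")
    sz <- lengths(ms)
    simS <- vapply(ms, matchSetSimilarity, numeric(1), simRaw = simRaw)
    sum(sz * simS) / sum(sz)
}

## set-pair key of an edge under the alignment; NA when an endpoint is
## uncovered
.edgeSetKeys <- function(et, setIdx) {
    a <- setIdx[et$from]
    b <- setIdx[et$to]
    ifelse(is.na(a) | is.na(b), NA_character_,
           paste(pmin(a, b), pmax(a, b), sep = "_"))
}

#' Conserved edges of an alignment
#'
#' An edge `(x, y)` of network i is conserved when (1) some edge
#' `(x', y')` of a different network j has `S(x') = S(x)` and
#' `S(y') = S(y)`, or (2) `x` and `y` share a match-set. Each undirected
#' edge is counted once; an edge with an uncovered endpoint can only be
#' conserved via condition (2), which requires both endpoints covered, so
#' never.
#'
#' @param alignment an [Alignment-class].
#' @param nets a [NetworkCollection-class].
#' @return a list with `count` and `edges` (data.frame of the conserved
#'   edges with their network and the condition, `"witness"` or
#'   `"colocated"`, that conserved them).
#' @export
conservedEdges <- function(alignment, nets) {
    et <- edgeTable(nets)
    if (!nrow(et))
        return(list(count = 0L,
                    edges = cbind(et, condition = character())))
    setIdx <- matchSetIndex(alignment)
    key <- .edgeSetKeys(et, setIdx)
    colocated <- !is.na(key) &
        setIdx[et$from] == setIdx[et$to]
    # condition (1): same set-pair key seen in another network
    witness <- rep(FALSE, nrow(et))
    ok <- !is.na(key)
    if (any(ok)) {
        netsPerKey <- tapply(et$network[ok], key[ok],
                             function(x) length(unique(x)))
        witness[ok] <- netsPerKey[key[ok]] > 1L
    }
    conserved <- witness | colocated
    edges <- et[conserved, , drop = FALSE]
    edges$condition <- ifelse(witness[conserved], "witness", "colocated")
    list(count = sum(conserved), edges = edges)
}

#' Strictly conserved edges
#'
#' Counts edges conserved via condition (1) of [conservedEdges()] for which
#' some witness edge `(x', y')` additionally has `sim(x, x') > 0` and
#' `sim(y, y') > 0` on raw scores (one such witness suffices).
#'
#' @param alignment an [Alignment-class].
#' @param nets a [NetworkCollection-class].
#' @param simRaw the raw [SimilarityMatrix-class].
#' @return integer count.
#' @export
strictlyConservedEdges <- function(alignment, nets, simRaw) {
    et <- edgeTable(nets)
    if (!nrow(et)) return(0L)
    setIdx <- matchSetIndex(alignment)
    key <- .edgeSetKeys(et, setIdx)
    ok <- which(!is.na(key))
    byKey <- split(ok, key[ok])
    count <- 0L
    for (i in ok) {
        cands <- setdiff(byKey[[key[i]]], i)
        cands <- cands[et$network[cands] != et$network[i]]
        hit <- FALSE
        x <- et$from[i]; y <- et$to[i]
        for (j in cands) {
            x2 <- et$from[j]; y2 <- et$to[j]
            # try both orientations of the witness edge
            if (setIdx[x2] == setIdx[x] && setIdx[y2] == setIdx[y] &&
                simScore(simRaw, x, x2) > 0 && simScore(simRaw, y, y2) > 0) {
                hit <- TRUE; break
            }
            if (setIdx[x2] == setIdx[y] && setIdx[y2] == setIdx[x] &&
                simScore(simRaw, y, x2) > 0 && simScore(simRaw, x, y2) > 0) {
                hit <- TRUE; break
            }
        }
        if (hit) count <- count + 1L
    }
    count
}

#' Coverage, covered edges and conserved-edge rate
#'
#' Coverage is the number of proteins belonging to any match-set. Covered
#' edges are edges with both endpoints covered; the conserved-edge rate is
#' conserved edges divided by covered edges (0 when nothing is covered).
#'
#' @param alignment an [Alignment-class].
#' @param nets a [NetworkCollection-class].
#' @return list with `coverage`, `coveredEdges` and `conservedEdgeRate`.
#' @export
coverageAndRate <- function(alignment, nets) {
    covered <- alignedProteins(alignment)
    et <- edgeTable(nets)
    coveredEdges <- sum(et$from %in% covered & et$to %in% covered)
    cons <- conservedEdges(alignment, nets)$count
    list(coverage = length(covered),
         coveredEdges = as.integer(coveredEdges),
         conservedEdgeRate = if (coveredEdges > 0) cons / coveredEdges else 0)
}

#' Cumulative hypergeometric p-value (upper tail)
#'
#' Probability of observing at least `m` annotated proteins in a size-`n`
#' match-set drawn from `N` proteins of which `M` carry the annotation:
#' `sum_{i = m}^{min(n, M)} C(M, i) C(N - M, n - i) / C(N, n)`.
#'
#' @param N total number of proteins across all networks.
#' @param M number of proteins annotated with the term.
#' @param n match-set size.
#' @param m number of annotated proteins in the match-set.
#' @return p-value in \[0, 1\].
#' @examples
#' hypergeomPValue(10, 5, 4, 4)  # 5/210
#' @export
hypergeomPValue <- function(N, M, n, m) {
    if (any(c(N, M, n, m) < 0) || M > N || n > N || m > min(n, M))
        stop("inconsistent hypergeometric counts")
    if (m == 0) return(1)
    stats::phyper(m - 1, M, N - M, n, lower.tail = FALSE)
}

#' Per-match-set functional enrichment
#'
#' For each match-set, the p-value of every term annotating at least one
#' member is computed with [hypergeomPValue()] against the background of all
#' `N` proteins in the collection (unannotated proteins count towards
#' `N - M`), and the minimum over terms is taken as the match-set's p-value.
#' A term is enriched when it achieves `p < cutoff` in at least one
#' match-set. No multiple-testing correction is applied.
#'
#' @param alignment an [Alignment-class].
#' @param annotations an [AnnotationMap-class].
#' @param nets a [NetworkCollection-class].
#' @param cutoff enrichment threshold on the p-value (default `1e-4`).
#' @return list with `matchSetPValues` (numeric vector, one per match-set;
#'   1 when no member is annotated), `bestTerm` (character; `NA` when no
#'   member is annotated) and `enrichedTerms` (character vector of distinct
#'   enriched terms).
#' @export
enrichmentReport <- function(alignment, annotations, nets, cutoff = 1e-4) {
    N <- nProteins(nets)
    amap <- annotationList(annotations)
    termCount <- table(unlist(lapply(amap, unique)))
    ms <- matchSets(alignment)
    pvals <- numeric(length(ms))
    best <- rep(NA_character_, length(ms))
    enriched <- character()
    for (i in seq_along(ms)) {
        S <- ms[[i]]
        termsHere <- unlist(lapply(S, function(p) amap[[p]]))
        if (is.null(termsHere) || !length(termsHere)) {
            pvals[i] <- 1
            next
        }
        mPer <- table(termsHere)
        p <- vapply(names(mPer), function(term) {
            hypergeomPValue(N, as.integer(termCount[[term]]),
                            length(S), as.integer(mPer[[term]]))
        }, numeric(1))
        pvals[i] <- min(p)
        best[i] <- names(p)[which.min(p)]
        enriched <- c(enriched, names(p)[p < cutoff])
    }
    list(matchSetPValues = pvals, bestTerm = best,
         enrichedTerms = sort(unique(enriched)))
}

#' Maximum-similarity one-to-one baseline (pairwise)
#'
#' For exactly two networks, computes the one-to-one assignment between the
#' two vertex sets maximizing total raw similarity (maximum-weight bipartite
#' matching); matched pairs with zero score are dropped. This is the
#' similarity-only reference an alignment's conserved edges are contrasted
#' against: it is optimal on sequence but blind to topology.
#'
#' @param nets a [NetworkCollection-class] with exactly 2 networks.
#' @param simRaw the raw [SimilarityMatrix-class].
#' @return an [Alignment-class] of matched pairs.
#' @examples
#' fx <- figure2Fixture()
#' hb <- hungarianBaseline(fx$nets, fx$sim)
#' averageSimilarity(hb, fx$sim)  # 95/3
#' @export
hungarianBaseline <- function(nets, simRaw) {
    if (nNetworks(nets) != 2L)
        stop("the baseline is defined for exactly 2 networks")
    ids <- networkIds(nets)
    netOf <- proteinNetwork(nets)
    left <- names(netOf)[netOf == ids[1]]
    right <- names(netOf)[netOf == ids[2]]
    pairs <- simPairs(simRaw)
    pairs <- pairs[(pairs$protein1 %in% left & pairs$protein2 %in% right) |
                   (pairs$protein1 %in% right & pairs$protein2 %in% left), ,
                   drop = FALSE]
    if (!nrow(pairs)) return(Alignment())
    vert <- c(left, right)
    g <- igraph::make_empty_graph(n = length(vert), directed = FALSE)
    g <- igraph::set_vertex_attr(g, "name", value = vert)
    g <- igraph::set_vertex_attr(g, "type",
                                 value = vert %in% right)
    g <- igraph::add_edges(g, rbind(match(pairs$protein1, vert),
                                    match(pairs$protein2, vert)))
    res <- igraph::max_bipartite_match(g, weights = pairs$score)
    matched <- res$matching[left]
    keep <- !is.na(matched)
    sets <- Map(c, left[keep], matched[keep])
    sc <- simScore(simRaw, left[keep], matched[keep])
    Alignment(unname(sets[sc > 0]))
}

#' Full metrics report for an alignment
#'
#' Bundles all quality metrics on raw scores: weighted average similarity,
#' conserved and strictly conserved edges, coverage, covered edges, the
#' conserved-edge rate, the per-match-set similarity table, and (when
#' annotations are given) the enrichment report.
#'
#' @param alignment an [Alignment-class] with >= 1 match-set.
#' @param nets a [NetworkCollection-class].
#' @param simRaw the raw [SimilarityMatrix-class].
#' @param annotations optional [AnnotationMap-class].
#' @return a list with components `averageSimilarity`, `conservedEdges`,
#'   `strictlyConservedEdges`, `coverage`, `coveredEdges`,
#'   `conservedEdgeRate`, `matchSetTable` and optionally `enrichment`.
#' @export
evaluateAlignment <- function(alignment, nets, simRaw, annotations = NULL) {
    ms <- matchSets(alignment)
    cons <- conservedEdges(alignment, nets)
    cov <- coverageAndRate(alignment, nets)
    tab <- data.frame(
        size = lengths(ms),
        similarity = vapply(ms, matchSetSimilarity, numeric(1),
                            simRaw = simRaw),
        members = vapply(ms, paste, "", collapse = ","))
    out <- list(
        averageSimilarity = averageSimilarity(alignment, simRaw),
        conservedEdges = cons$count,
        strictlyConservedEdges = strictlyConservedEdges(alignment, nets,
                                                        simRaw),
        coverage = cov$coverage,
        coveredEdges = cov$coveredEdges,
        conservedEdgeRate = cov$conservedEdgeRate,
        matchSetTable = tab)
    if (!is.null(annotations))
        out$enrichment <- enrichmentReport(alignment, annotations, nets)
    out
}
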