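## Stages 2-4: seed generation, priority-queue seed expansion with the
## parametric merging criterion, and alignment of remaining proteins.

## Max-priority queue over protein pairs. Equal priorities pop in LIFO
## order (most recently pushed first); since pairs are always pushed in a
## deterministic lexicographic order, pops are fully deterministic.
.newQueue <- function() {
    q <- new.env(parent = emptyenv())
    q$pri <- numeric()
    q$va <- character()
    q$vb <- character()
    q$active <- logical()
    q
}

.queuePush <- function(q, va, vb, pri) {
    if (!length(va)) return(invisible())
    q$pri <- c(q$pri, pri)
    q$va <- c(q$va, va)
    q$vb <- c(q$vb, vb)
    q$active <- c(q$active, rep(TRUE, length(va)))
    invisible()
}

.queuePop <- function(q) {
    idx <- which(q$active)
    if (!length(idx)) return(NULL)
    p <- q$pri[idx]
    best <- idx[p == max(p)]
    i <- best[length(best)]          # LIFO among equal priorities
    q$active[i] <- FALSE
    list(va = q$va[i], vb = q$vb[i], pri = q$pri[i])
}

#' Create a fresh alignment state
#'
#' Every protein starts in its own singleton match-set with its aligned flag
#' unset. The state is a mutable environment threaded through
#' [mergeCriterion()], [expandSeeds()] and [alignRemaining()].
#'
#' @param nets a [NetworkCollection-class].
#' @param decision the [SimilarityMatrix-class] driving all pipeline
#'   decisions (the preprocessed matrix when preprocessing is enabled).
#' @return an environment with the per-protein match-set partition,
#'   aligned flags, and merge accept/reject counters.
#' @export
newAlignmentState <- function(nets, decision) {
    st <- new.env(parent = emptyenv())
    p <- proteins(nets)
    st$nets <- nets
    st$decision <- decision
    st$netOf <- proteinNetwork(nets)
    st$setOf <- stats::setNames(seq_along(p), p)
    st$sets <- as.list(p)
    st$ali <- stats::setNames(rep(FALSE, length(p)), p)
    st$accepted <- 0L
    st$rejected <- 0L
    st
}

## unaligned neighbours of v, sorted
.unalignedNeighbors <- function(st, v) {
    nb <- neighborsOf(st$nets, v)
    nb[!st$ali[nb]]
}

.decisionBlock <- function(st, rowsP, colsP) {
    m <- st$decision@mat
    r <- intersect(rowsP, rownames(m))
    c <- intersect(colsP, rownames(m))
    if (!length(r) || !length(c))
        return(matrix(0, nrow = length(r), ncol = length(c)))
    as.matrix(m[r, c, drop = FALSE])
}

#' Generate seeds from clusters (stage 2)
#'
#' All within-cluster, cross-network protein pairs whose decision score is
#' at least `tau` become seeds; pairs inside one network are skipped.
#'
#' @param clust a [ClusterSet-class] (or plain list of clusters).
#' @param sim the decision [SimilarityMatrix-class].
#' @param tau seed threshold (>= 0; `Inf` yields no seeds).
#' @param nets a [NetworkCollection-class].
#' @return data.frame with columns `protein1`, `protein2`
#'   (`protein1 < protein2`) and `score`, sorted by pair.
#' @examples
#' fx <- figure2Fixture()
#' pp <- preprocessSimilarity(fx$nets, fx$sim)
#' cl <- agglomerativeCluster(pp, m = 3)
#' generateSeeds(cl, pp, tau = 50, nets = fx$nets)
#' @export
generateSeeds <- function(clust, sim, tau, nets) {
    if (tau < 0) stop("tau must be >= 0")
    cl <- if (methods::is(clust, "ClusterSet")) clusters(clust) else clust
    netOf <- proteinNetwork(nets)
    out <- lapply(cl, function(members) {
        if (length(members) < 2L) return(NULL)
        pr <- utils::combn(sort(members), 2)
        cross <- netOf[pr[1, ]] != netOf[pr[2, ]]
        if (!any(cross)) return(NULL)
        pr <- pr[, cross, drop = FALSE]
        sc <- simScore(sim, pr[1, ], pr[2, ])
        keep <- sc >= tau
        if (!any(keep)) return(NULL)
        data.frame(protein1 = pr[1, keep], protein2 = pr[2, keep],
                   score = sc[keep], stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    if (is.null(out))
        out <- data.frame(protein1 = character(), protein2 = character(),
                          score = numeric(), stringsAsFactors = FALSE)
    out[order(out$protein1, out$protein2), , drop = FALSE]
}

#' The match-set merging criterion (stage 3/4 gate)
#'
#' Decides whether the match-sets containing `vi` and `vj` should be merged,
#' and merges them (mutating `state`) when the answer is yes:
#' \enumerate{
#'   \item size gate: reject if `|S(vi)| + |S(vj)| > omega * |Net(union)|`;
#'   \item `maxSim` = maximal decision score among all pairs in the union
#'     (within-network pairs score 0);
#'   \item `count` = number of cross-set pairs scoring above
#'     `maxSim * beta`;
#'   \item `expandRatio` = `|Net(union)| / max(|Net(S(vi))|, |Net(S(vj))|)`;
#'   \item merge iff `maxSim > 0` and
#'     `count * expandRatio >= |S(vi)| * |S(vj)| * rho`.
#' }
#' When `mergeZeroSimSingletons` is set (the default) two singleton
#' match-sets that pass the size gate are always merged, regardless of
#' `maxSim` — the expansion stage always merges two single-protein
#' match-sets. On a merge, the aligned flags of `vi` and `vj` are set.
#'
#' @param vi,vj protein ids in different match-sets.
#' @param state an environment from [newAlignmentState()].
#' @param params an [AlignmentParams-class].
#' @return `TRUE` (and `state` mutated) if the sets were merged, else
#'   `FALSE`.
#' @export
mergeCriterion <- function(vi, vj, state, params) {
    si <- state$setOf[[vi]]
    sj <- state$setOf[[vj]]
    if (si == sj) stop("proteins are already in the same match-set")
    Si <- state$sets[[si]]
    Sj <- state$sets[[sj]]
    U <- c(Si, Sj)
    netsU <- unique(state$netOf[U])
    doMerge <- FALSE
    if (length(Si) + length(Sj) <= params@omega * length(netsU)) {
        if (params@mergeZeroSimSingletons &&
            length(Si) == 1L && length(Sj) == 1L) {
            doMerge <- TRUE
        } else {
            blockU <- .decisionBlock(state, U, U)
            maxSim <- if (length(blockU)) max(blockU) else 0
            if (maxSim > 0) {
                cross <- .decisionBlock(state, Si, Sj)
                count <- sum(cross > maxSim * params@beta)
                expandRatio <- length(netsU) /
                    max(length(unique(state$netOf[Si])),
                        length(unique(state$netOf[Sj])))
                doMerge <- count * expandRatio >=
                    length(Si) * length(Sj) * params@rho
            }
        }
    }
    if (doMerge) {
        state$sets[[si]] <- U
        state$sets[[sj]] <- character()
        state$setOf[Sj] <- si
        state$ali[[vi]] <- TRUE
        state$ali[[vj]] <- TRUE
        state$accepted <- state$accepted + 1L
        TRUE
    } else {
        state$rejected <- state$rejected + 1L
        FALSE
    }
}

## push all cross-network (x, y), x in N(vi), y in N(vj), onto the queue
.pushNeighborPairs <- function(q, st, vi, vj) {
    nx <- .unalignedNeighbors(st, vi)
    ny <- .unalignedNeighbors(st, vj)
    if (!length(nx) || !length(ny)) return(invisible())
    grid <- expand.grid(y = ny, x = nx, stringsAsFactors = FALSE)
    grid <- grid[st$netOf[grid$x] != st$netOf[grid$y], , drop = FALSE]
    if (!nrow(grid)) return(invisible())
    grid <- grid[order(grid$x, grid$y), , drop = FALSE]
    .queuePush(q, grid$x, grid$y, simScore(st$decision, grid$x, grid$y))
    invisible()
}

#' Expand seeds into an alignment (stage 3)
#'
#' Phase one pushes every seed into a max-priority queue keyed by its
#' decision score and pops them in descending order, applying
#' [mergeCriterion()] to each (its boolean result is ignored), so seeds
#' sharing proteins coalesce into multi-network match-sets. Phase two seeds
#' the queue with all cross-network pairs of unaligned neighbours of every
#' >= 2-member match-set, then repeatedly pops; each successful merge of
#' `(vi, vj)` pushes the cross-network pairs of their unaligned
#' neighbourhoods, propagating the alignment along conserved interactions.
#' Entries whose proteins already share a match-set are skipped at pop time.
#'
#' @param seeds seed data.frame from [generateSeeds()].
#' @param state a fresh environment from [newAlignmentState()].
#' @param params an [AlignmentParams-class].
#' @return the mutated `state`, invisibly.
#' @export
expandSeeds <- function(seeds, state, params) {
    q <- .newQueue()
    if (nrow(seeds))
        .queuePush(q, seeds$protein1, seeds$protein2, seeds$score)
    while (!is.null(e <- .queuePop(q))) {
        if (state$setOf[[e$va]] == state$setOf[[e$vb]]) next
        mergeCriterion(e$va, e$vb, state, params)
    }
    # phase 2: queue the neighbourhoods of every formed match-set
    formed <- which(vapply(state$sets, length, 1L) >= 2L)
    formed <- formed[order(vapply(state$sets[formed],
                                  function(s) min(s), ""))]
    for (si in formed) {
        members <- sort(state$sets[[si]])
        if (length(members) < 2L) next
        pr <- utils::combn(members, 2)
        cross <- state$netOf[pr[1, ]] != state$netOf[pr[2, ]]
        pr <- pr[, cross, drop = FALSE]
        if (!ncol(pr)) next
        for (cidx in seq_len(ncol(pr)))
            .pushNeighborPairs(q, state, pr[1, cidx], pr[2, cidx])
    }
    while (!is.null(e <- .queuePop(q))) {
        if (state$setOf[[e$va]] == state$setOf[[e$vb]]) next
        if (mergeCriterion(e$va, e$vb, state, params))
            .pushNeighborPairs(q, state, e$va, e$vb)
    }
    invisible(state)
}

#' Align remaining proteins (stage 4)
#'
#' All pairs whose two proteins are still unaligned after seed expansion and
#' whose decision score is positive are processed in descending score order
#' (ties lexicographic); [mergeCriterion()] is applied to each, so
#' match-sets formed in this stage can still grow across networks.
#' Zero-score pairs are never considered.
#'
#' @param state the environment after [expandSeeds()].
#' @param params an [AlignmentParams-class].
#' @return the mutated `state`, invisibly.
#' @export
alignRemaining <- function(state, params) {
    pairs <- simPairs(state$decision)
    if (!nrow(pairs)) return(invisible(state))
    keep <- !state$ali[pairs$protein1] & !state$ali[pairs$protein2]
    pairs <- pairs[keep, , drop = FALSE]
    pairs <- pairs[order(-pairs$score, pairs$protein1, pairs$protein2), ,
                   drop = FALSE]
    for (i in seq_len(nrow(pairs))) {
        va <- pairs$protein1[i]; vb <- pairs$protein2[i]
        if (state$setOf[[va]] == state$setOf[[vb]]) next
        mergeCriterion(va, vb, state, params)
    }
    invisible(state)
}

#' Extract the final alignment from a state
#'
#' Match-sets still holding a single protein are discarded.
#'
#' @param state an alignment-state environment.
#' @return an [Alignment-class].
#' @export
finalizeAlignment <- function(state) {
    Alignment(Filter(function(s) length(s) >= 2L, state$sets))
}

#' Run the full alignment pipeline
#'
#' Executes (optional) preprocessing, agglomerative clustering, seed
#' generation, seed expansion and remaining-protein alignment. All pipeline
#' decisions — clustering, the seed threshold, queue priorities and the
#' merging criterion — use the preprocessed matrix when preprocessing is
#' enabled; evaluation metrics should always use the raw matrix (see
#' [evaluateAlignment()]). Deterministic for fixed parameters.
#'
#' @param nets a [NetworkCollection-class] with at least two networks.
#' @param sim the raw [SimilarityMatrix-class].
#' @param params an [AlignmentParams-class].
#' @param preprocess logical; apply [preprocessSimilarity()] before
#'   clustering?
#' @return a list with components `alignment` (an [Alignment-class]),
#'   `report` (stage timings and counters), `clusters`, `seeds` and
#'   `decision` (the decision matrix used).
#' @examples
#' fx <- figure2Fixture()
#' res <- runPipeline(fx$nets, fx$sim,
#'                    AlignmentParams(tau = 50, rho = 0.6))
#' matchSets(res$alignment)
#' @export
runPipeline <- function(nets, sim, params = AlignmentParams(),
                        preprocess = TRUE) {
    if (nNetworks(nets) < 2L)
        stop("alignment requires at least two networks")
    methods::validObject(params)
    t0 <- proc.time()[["elapsed"]]
    decision <- if (preprocess) preprocessSimilarity(nets, sim) else sim
    t1 <- proc.time()[["elapsed"]]
    m <- targetClusterCount(nets, decision, params@clusterCount)
    clust <- agglomerativeCluster(decision, m, params@criterion)
    t2 <- proc.time()[["elapsed"]]
    seeds <- generateSeeds(clust, decision, params@tau, nets)
    state <- newAlignmentState(nets, decision)
    expandSeeds(seeds, state, params)
    t3 <- proc.time()[["elapsed"]]
    alignRemaining(state, params)
    t4 <- proc.time()[["elapsed"]]
    alignment <- finalizeAlignment(state)
    report <- list(
        preprocess = preprocess,
        params = params,
        clusterCount = length(clusters(clust)),
        seedCount = nrow(seeds),
        mergeAccepted = state$accepted,
        mergeRejected = state$rejected,
        coverage = length(alignedProteins(alignment)),
        timings = c(preprocess = t1 - t0, clustering = t2 - t1,
                    expansion = t3 - t2, remaining = t4 - t3))
    list(alignment = alignment, report = report, clusters = clust,
         seeds = seeds, decision = decision)
}

#' Sweep the seed threshold over one preprocessing + clustering run
#'
#' Preprocessing and clustering — the expensive stages — are executed once;
#' stages 2-4 are re-run for each threshold in `tauList`, reproducing the
#' usual topology-vs-similarity trade-off curve cheaply. Results for a given
#' `tau` are identical to a [runPipeline()] call at that `tau`.
#'
#' @param nets a [NetworkCollection-class].
#' @param sim the raw [SimilarityMatrix-class].
#' @param tauList numeric vector of seed thresholds (>= 1 value).
#' @param params an [AlignmentParams-class]; its `tau` slot is ignored.
#' @param preprocess logical; apply preprocessing before clustering?
#' @param annotations optional [AnnotationMap-class] for enrichment metrics.
#' @return a list with one element per threshold, each holding `tau`,
#'   `alignment`, `metrics` (from [evaluateAlignment()]) and `report`; the
#'   attribute `clusteringInvocations` records that clustering ran once.
#' @export
alignSweep <- function(nets, sim, tauList, params = AlignmentParams(),
                       preprocess = TRUE, annotations = NULL) {
    if (!length(tauList)) stop("tauList must contain at least one threshold")
    if (nNetworks(nets) < 2L)
        stop("alignment requires at least two networks")
    decision <- if (preprocess) preprocessSimilarity(nets, sim) else sim
    m <- targetClusterCount(nets, decision, params@clusterCount)
    clust <- agglomerativeCluster(decision, m, params@criterion)
    out <- lapply(tauList, function(tau) {
        seeds <- generateSeeds(clust, decision, tau, nets)
        state <- newAlignmentState(nets, decision)
        expandSeeds(seeds, state, params)
        alignRemaining(state, params)
        alignment <- finalizeAlignment(state)
        metrics <- if (nMatchSets(alignment) > 0)
            evaluateAlignment(alignment, nets, sim, annotations)
        else NULL
        list(tau = tau, alignment = alignment, metrics = metrics,
             report = list(seedCount = nrow(seeds),
                           mergeAccepted = state$accepted,
                           mergeRejected = state$rejected))
    })
    attr(out, "clusteringInvocations") <- 1L
    out
}
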