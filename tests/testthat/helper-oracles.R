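## Independent brute-force oracles and small random-instance generators.

randomInstance <- function(k = 2, nPerNet = 5, pEdge = 0.3, pSim = 0.3,
                           maxScore = 10, seed = 1) {
    set.seed(seed)
    networks <- list()
    for (g in seq_len(k)) {
        ids <- sprintf("n%d_%02d", g, seq_len(nPerNet))
        pairs <- combn(ids, 2)
        keep <- runif(ncol(pairs)) < pEdge
        networks[[paste0("g", g)]] <-
            list(vertices = ids, edges = t(pairs[, keep, drop = FALSE]))
    }
    nets <- NetworkCollection(networks)
    netOf <- proteinNetwork(nets)
    p <- proteins(nets)
    cp <- combn(p, 2)
    cross <- netOf[cp[1, ]] != netOf[cp[2, ]]
    cp <- cp[, cross, drop = FALSE]
    hit <- runif(ncol(cp)) < pSim
    if (!any(hit)) hit[1] <- TRUE
    sim <- SimilarityMatrix(cp[1, hit], cp[2, hit],
                            round(runif(sum(hit), 0.5, maxScore), 2),
                            nets = nets)
    list(nets = nets, sim = sim)
}

randomAlignment <- function(nets, seed = 1, pCover = 0.7) {
    set.seed(seed)
    p <- proteins(nets)
    cov <- p[runif(length(p)) < pCover]
    if (length(cov) < 2) cov <- p[1:2]
    nsets <- max(1L, length(cov) %/% 3L)
    sets <- split(cov, sample(nsets, length(cov), replace = TRUE))
    sets <- Filter(function(s) length(s) >= 2, sets)
    if (!length(sets)) sets <- list(cov[1:2])
    Alignment(unname(sets))
}

## O(|E|^2) pairwise check of the two conservation conditions
bruteConserved <- function(alignment, nets) {
    et <- edgeTable(nets)
    idx <- matchSetIndex(alignment)
    S <- function(v) if (v %in% names(idx)) idx[[v]] else NA_integer_
    count <- 0L
    for (i in seq_len(nrow(et))) {
        x <- et$from[i]; y <- et$to[i]
        if (is.na(S(x)) || is.na(S(y))) next
        if (S(x) == S(y)) { count <- count + 1L; next }
        hit <- FALSE
        for (j in seq_len(nrow(et))) {
            if (et$network[j] == et$network[i]) next
            x2 <- et$from[j]; y2 <- et$to[j]
            if (is.na(S(x2)) || is.na(S(y2))) next
            if ((S(x2) == S(x) && S(y2) == S(y)) ||
                (S(x2) == S(y) && S(y2) == S(x))) { hit <- TRUE; break }
        }
        if (hit) count <- count + 1L
    }
    count
}

bruteStrictlyConserved <- function(alignment, nets, sim) {
    et <- edgeTable(nets)
    idx <- matchSetIndex(alignment)
    S <- function(v) if (v %in% names(idx)) idx[[v]] else NA_integer_
    count <- 0L
    for (i in seq_len(nrow(et))) {
        x <- et$from[i]; y <- et$to[i]
        if (is.na(S(x)) || is.na(S(y))) next
        hit <- FALSE
        for (j in seq_len(nrow(et))) {
            if (et$network[j] == et$network[i]) next
            x2 <- et$from[j]; y2 <- et$to[j]
            if (is.na(S(x2)) || is.na(S(y2))) next
            if (S(x2) == S(x) && S(y2) == S(y) &&
                simScore(sim, x, x2) > 0 && simScore(sim, y, y2) > 0) {
                hit <- TRUE; break
            }
            if (S(x2) == S(y) && S(y2) == S(x) &&
                simScore(sim, y, x2) > 0 && simScore(sim, x, y2) > 0) {
                hit <- TRUE; break
            }
        }
        if (hit) count <- count + 1L
    }
    count
}

## direct combinatorial summation of the hypergeometric upper tail
bruteHypergeom <- function(N, M, n, m) {
    if (m == 0) return(1)
    i <- m:min(n, M)
    sum(choose(M, i) * choose(N - M, n - i)) / choose(N, n)
}

## exhaustive best-total assignment on a score matrix (rows to columns,
## injective, unassigned rows allowed)
bruteAssignment <- function(scores) {
    nr <- nrow(scores); nc <- ncol(scores)
    best <- 0
    rec <- function(r, used, tot) {
        if (r > nr) { best <<- max(best, tot); return(invisible()) }
        rec(r + 1L, used, tot)            # leave row r unassigned
        for (c in seq_len(nc)) {
            if (!used[c]) rec(r + 1L, `[<-`(used, c, TRUE),
                              tot + scores[r, c])
        }
    }
    rec(1L, rep(FALSE, nc), 0)
    best
}

## naive restatement of the greedy neighbour-matching rule
bruteGreedyExtra <- function(a, b, nets, sim) {
    na <- neighborsOf(nets, a); nb <- neighborsOf(nets, b)
    extra <- 0
    repeat {
        if (!length(na) || !length(nb)) break
        bestS <- 0; bestX <- NULL; bestY <- NULL
        for (x in sort(na)) for (y in sort(nb)) {
            s <- simScore(sim, x, y)
            if (s > bestS) { bestS <- s; bestX <- x; bestY <- y }
        }
        if (bestS <= 0) break
        extra <- extra + bestS
        na <- setdiff(na, bestX); nb <- setdiff(nb, bestY)
    }
    extra
}

## from-scratch greedy agglomerative clustering: each step re-evaluates the
## criterion of every candidate merged partition
oracleAgglomerative <- function(sim, m, which = "I1") {
    cl <- as.list(alignableProteins(sim))
    label <- function(s) min(s)
    while (length(cl) > m) {
        base <- criterionValue(cl, sim, which)
        cand <- combn(length(cl), 2)
        crossSum <- apply(cand, 2, function(ij) {
            sum(outer(cl[[ij[1]]], cl[[ij[2]]],
                      function(a, b) simScore(sim, a, b)))
        })
        connected <- crossSum > 0
        if (any(connected)) {
            cand <- cand[, connected, drop = FALSE]
            gains <- apply(cand, 2, function(ij) {
                merged <- c(cl[-ij], list(c(cl[[ij[1]]], cl[[ij[2]]])))
                criterionValue(merged, sim, which) - base
            })
            la <- apply(cand, 2, function(ij)
                min(label(cl[[ij[1]]]), label(cl[[ij[2]]])))
            lb <- apply(cand, 2, function(ij)
                max(label(cl[[ij[1]]]), label(cl[[ij[2]]])))
            o <- order(-gains, la, lb)
            ij <- cand[, o[1]]
        } else {
            labs <- vapply(cl, label, "")
            o <- order(labs)
            ij <- o[1:2]
        }
        cl <- c(cl[-ij], list(sort(c(cl[[ij[1]]], cl[[ij[2]]]))))
    }
    cl <- lapply(cl, sort)
    cl[order(vapply(cl, `[`, "", 1L))]
}

canonSets <- function(sets) {
    sets <- lapply(sets, sort)
    sets[order(vapply(sets, `[`, "", 1L))]
}
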