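## Stage 1: agglomerative clustering of proteins by similarity under the
## I1 / I2 criterion functions.

#' Criterion function value of a partition
#'
#' `I1 = sum_i (1/n_i) * sum_{unordered pairs u,v in C_i} sim(u, v)` and
#' `I2 = sum_i sum_{unordered pairs} sim(u, v)`. Sums run over unordered
#' distinct pairs; within-network pairs contribute 0 through the similarity
#' invariant.
#'
#' @param clusters a [ClusterSet-class] or a plain list of character
#'   vectors.
#' @param sim a [SimilarityMatrix-class].
#' @param which `"I1"` or `"I2"`.
#' @return the criterion value (numeric).
#' @export
criterionValue <- function(clusters, sim, which = c("I1", "I2")) {
    which <- match.arg(which)
    cl <- if (methods::is(clusters, "ClusterSet")) clusters(clusters)
          else clusters
    if (any(lengths(cl) == 0L)) stop("empty cluster")
    vals <- vapply(cl, function(members) {
        if (length(members) < 2L) return(0)
        idx <- match(members, simProteins(sim))
        s <- if (anyNA(idx)) {
            present <- members[!is.na(idx)]
            if (length(present) < 2L) 0
            else sum(sim@mat[present, present]) / 2
        } else sum(sim@mat[members, members]) / 2
        if (which == "I1") s / length(members) else s
    }, numeric(1))
    sum(vals)
}

#' Target number of clusters (n / k)
#'
#' The clustering stage aims for `floor(n_sim / k)` clusters, where `n_sim`
#' counts proteins with at least one nonzero similarity entry (zero-
#' similarity proteins are excluded before clustering) and `k` is the number
#' of networks; never fewer than one cluster.
#'
#' @param nets a [NetworkCollection-class].
#' @param sim a [SimilarityMatrix-class].
#' @param override optional positive integer replacing the automatic count.
#' @return positive integer.
#' @export
targetClusterCount <- function(nets, sim, override = NA_integer_) {
    if (!is.na(override)) {
        if (override < 1) stop("cluster count override must be >= 1")
        return(as.integer(override))
    }
    nSim <- length(alignableProteins(sim))
    if (nSim == 0L) stop("no alignable proteins: similarity matrix is empty")
    max(1L, as.integer(nSim %/% nNetworks(nets)))
}

#' Greedy agglomerative clustering under I1 / I2
#'
#' Starts from singletons over the nonzero-similarity proteins and
#' repeatedly merges the pair of clusters with the greatest criterion gain
#' (gains may be negative near the end) until `m` clusters remain. Merges
#' are restricted to cluster pairs connected by at least one nonzero
#' similarity entry whenever such a pair exists; otherwise the
#' lexicographically smallest pair of cluster labels (a cluster's label is
#' its lexicographically smallest member) is merged. Gain ties are broken by
#' the smallest label pair, which makes the procedure deterministic.
#'
#' @param sim a [SimilarityMatrix-class].
#' @param m target number of clusters (>= 1). If `m` exceeds the number of
#'   clusterable proteins, all singletons are returned with a warning.
#' @param which criterion function, `"I1"` or `"I2"`.
#' @return a [ClusterSet-class].
#' @examples
#' fx <- figure2Fixture()
#' pp <- preprocessSimilarity(fx$nets, fx$sim)
#' clusters(agglomerativeCluster(pp, m = 3))
#' @export
agglomerativeCluster <- function(sim, m, which = c("I1", "I2")) {
    which <- match.arg(which)
    if (m < 1) stop("m must be >= 1")
    prots <- alignableProteins(sim)
    n <- length(prots)
    if (n == 0L) stop("no alignable proteins: similarity matrix is empty")
    if (m > n) {
        warning("m exceeds the number of clusterable proteins; ",
                "returning all singletons")
        m <- n
    }
    W <- as.matrix(sim@mat[prots, prots])   # cross-cluster similarity sums
    members <- as.list(prots)
    label <- prots                           # smallest member per cluster
    within <- numeric(n)                     # total within-cluster pair sum
    size <- rep(1L, n)
    active <- rep(TRUE, n)
    nActive <- n

    gain <- function(i, j) {
        if (which == "I2") return(W[i, j])
        (within[i] + within[j] + W[i, j]) / (size[i] + size[j]) -
            within[i] / size[i] - within[j] / size[j]
    }

    while (nActive > m) {
        act <- which(active)
        ij <- which(upper.tri(W[act, act, drop = FALSE]) &
                    W[act, act, drop = FALSE] > 0, arr.ind = TRUE)
        if (nrow(ij)) {
            cand <- cbind(act[ij[, 1]], act[ij[, 2]])
            g <- mapply(gain, cand[, 1], cand[, 2])
            la <- pmin(label[cand[, 1]], label[cand[, 2]])
            lb <- pmax(label[cand[, 1]], label[cand[, 2]])
            o <- order(-g, la, lb)
            i <- cand[o[1], 1]; j <- cand[o[1], 2]
        } else {
            # no similarity between any two clusters: lexicographic merge
            o <- order(label[act])
            i <- act[o[1]]; j <- act[o[2]]
        }
        within[i] <- within[i] + within[j] + W[i, j]
        size[i] <- size[i] + size[j]
        members[[i]] <- c(members[[i]], members[[j]])
        label[i] <- min(label[i], label[j])
        W[i, ] <- W[i, ] + W[j, ]
        W[, i] <- W[, i] + W[, j]
        W[i, i] <- 0
        active[j] <- FALSE
        nActive <- nActive - 1L
    }
    cl <- lapply(members[active], sort)
    cl <- cl[order(vapply(cl, `[`, "", 1L))]
    new("ClusterSet", clusters = cl, criterion = which,
        criterionValue = criterionValue(cl, sim, which))
}
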