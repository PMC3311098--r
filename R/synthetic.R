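## Test inputs: the two-network worked example and a planted-ortholog
## generator.

#' The two-network worked example
#'
#' Builds the small instance used throughout the documentation and tests:
#' network A with edges A1-A2, A2-A3; network B with edges B1-B2, B2-B3,
#' B2-B4; raw similarities sim(A1,B1) = 20, sim(A2,B2) = 50,
#' sim(A2,B3) = 60, sim(A3,B4) = 15, all other pairs 0. The builder
#' self-checks the identities this instance is designed around —
#' preprocessed sim(A2,B2) = 50 + (20 + 15) = 85, the optimal one-to-one
#' assignment total 20 + 60 + 15 = 95, the no-preprocessing alignment total
#' 60 + 0 + 20 = 80, and sim(A3,B2) = 0 — and fails fast on any
#' transcription error.
#'
#' @return a list with components `nets` (a [NetworkCollection-class]) and
#'   `sim` (the raw [SimilarityMatrix-class]).
#' @examples
#' fx <- figure2Fixture()
#' simScore(fx$sim, "A2", "B3")
#' @export
figure2Fixture <- function() {
    nets <- NetworkCollection(list(
        A = rbind(c("A1", "A2"), c("A2", "A3")),
        B = rbind(c("B1", "B2"), c("B2", "B3"), c("B2", "B4"))))
    sim <- SimilarityMatrix(
        protein1 = c("A1", "A2", "A2", "A3"),
        protein2 = c("B1", "B2", "B3", "B4"),
        score = c(20, 50, 60, 15),
        nets = nets)
    s <- function(a, b) simScore(sim, a, b)
    stopifnot(
        s("A1", "B1") + s("A2", "B2") + s("A3", "B4") == 85,
        s("A1", "B1") + s("A2", "B3") + s("A3", "B4") == 95,
        s("A2", "B3") + s("A3", "B2") + s("A1", "B1") == 80,
        s("A3", "B2") == 0)
    list(nets = nets, sim = sim)
}

#' Generate a planted-ortholog multi-network instance
#'
#' A duplication-and-divergence toy model: an Erdős–Rényi ancestor graph
#' `G(n0, pEdge)` is copied into each of `k` networks, each copy losing
#' every edge independently with probability `pDel`. Copies of the same
#' ancestor protein form a ground-truth ortholog group; every cross-network
#' pair inside a group receives score `simSignal` plus uniform jitter on
#' `[-simJitter, simJitter]` (floored just above zero). Spurious
#' cross-network entries appear between non-ortholog pairs with probability
#' `noiseRate`, scored uniformly on `(0, noiseMax]`. Deterministic for a
#' fixed seed. The generator emulates what the aligner assumes — sparse
#' graphs with a sparse block-structured similarity matrix — not realistic
#' PPI degree distributions.
#'
#' @param k number of networks (>= 2).
#' @param n0 ancestor size (>= 5).
#' @param pEdge ancestor edge probability.
#' @param pDel per-copy edge deletion rate.
#' @param simSignal similarity score of true ortholog pairs.
#' @param simJitter half-width of the uniform jitter on the signal.
#' @param noiseRate probability of a spurious cross-network entry.
#' @param noiseMax maximal spurious score.
#' @param seed integer seed.
#' @return a list with `nets`, `sim` and `truth`; `truth` is a list with
#'   `groups` (list of character vectors) and the generator `params`.
#' @examples
#' inst <- generatePlanted(k = 2, n0 = 10, seed = 1)
#' length(inst$truth$groups)
#' @export
generatePlanted <- function(k = 2, n0 = 50, pEdge = 0.1, pDel = 0.1,
                            simSignal = 1, simJitter = 0.1,
                            noiseRate = 0.01, noiseMax = 0.3, seed = 1) {
    if (k < 2) stop("k must be >= 2")
    if (n0 < 5) stop("n0 must be >= 5")
    if (any(c(pEdge, pDel, noiseRate) < 0) ||
        any(c(pEdge, pDel, noiseRate) > 1))
        stop("probabilities must lie in [0, 1]")
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old))
        assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)

    anc <- which(upper.tri(matrix(0, n0, n0)), arr.ind = TRUE)
    anc <- anc[stats::runif(nrow(anc)) < pEdge, , drop = FALSE]
    pid <- function(net, i) sprintf("net%d_p%02d", net, i)
    networks <- lapply(seq_len(k), function(g) {
        keep <- stats::runif(nrow(anc)) >= pDel
        e <- anc[keep, , drop = FALSE]
        list(vertices = pid(g, seq_len(n0)),
             edges = cbind(pid(g, e[, 1]), pid(g, e[, 2])))
    })
    names(networks) <- paste0("net", seq_len(k))
    nets <- NetworkCollection(networks)

    groups <- lapply(seq_len(n0), function(i) pid(seq_len(k), i))
    p1 <- character(); p2 <- character(); sc <- numeric()
    for (i in seq_len(n0)) {
        cp <- utils::combn(groups[[i]], 2)
        jit <- stats::runif(ncol(cp), -simJitter, simJitter)
        p1 <- c(p1, cp[1, ]); p2 <- c(p2, cp[2, ])
        sc <- c(sc, pmax(simSignal + jit, simSignal * 1e-3))
    }
    if (noiseRate > 0) {
        for (ga in seq_len(k - 1)) for (gb in (ga + 1):k) {
            grid <- expand.grid(a = seq_len(n0), b = seq_len(n0))
            grid <- grid[grid$a != grid$b, , drop = FALSE]
            hit <- stats::runif(nrow(grid)) < noiseRate
            if (any(hit)) {
                g2 <- grid[hit, , drop = FALSE]
                p1 <- c(p1, pid(ga, g2$a)); p2 <- c(p2, pid(gb, g2$b))
                sc <- c(sc, stats::runif(nrow(g2), 0, noiseMax))
            }
        }
    }
    if (!length(p1)) stop("degenerate parameters: empty similarity matrix")
    sim <- SimilarityMatrix(p1, p2, sc, nets = nets)
    list(nets = nets, sim = sim,
         truth = list(groups = groups,
                      params = list(k = k, n0 = n0, pEdge = pEdge,
                                    pDel = pDel, simSignal = simSignal,
                                    simJitter = simJitter,
                                    noiseRate = noiseRate,
                                    noiseMax = noiseMax, seed = seed)))
}

#' Generate synthetic annotations for a planted instance
#'
#' With `termPerGroup`, one synthetic term per ortholog group annotates
#' exactly that group's members, so a perfect alignment drives each group
#' term's enrichment p-value far below the usual cutoff. Background terms
#' annotate each protein independently with probability `backgroundRate`.
#'
#' @param truth the `truth` component of [generatePlanted()] output.
#' @param nets the matching [NetworkCollection-class].
#' @param termPerGroup logical; plant one term per ortholog group?
#' @param backgroundTerms number of random background terms.
#' @param backgroundRate per-protein annotation probability of each
#'   background term.
#' @param seed integer seed.
#' @return an [AnnotationMap-class].
#' @export
generateAnnotations <- function(truth, nets, termPerGroup = TRUE,
                                backgroundTerms = 0, backgroundRate = 0.05,
                                seed = 1) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old))
        assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    prot <- character(); term <- character()
    if (isTRUE(termPerGroup) && length(truth$groups)) {
        for (i in seq_along(truth$groups)) {
            g <- truth$groups[[i]]
            prot <- c(prot, g)
            term <- c(term, rep(sprintf("SYN:G%04d", i), length(g)))
        }
    }
    if (backgroundTerms > 0) {
        all_p <- proteins(nets)
        for (t in seq_len(backgroundTerms)) {
            hit <- all_p[stats::runif(length(all_p)) < backgroundRate]
            prot <- c(prot, hit)
            term <- c(term, rep(sprintf("SYN:BG%04d", t), length(hit)))
        }
    }
    if (!length(prot)) return(AnnotationMap())
    AnnotationMap(data.frame(protein = prot, term = term,
                             stringsAsFactors = FALSE))
}

#' Pair-level recovery of planted ortholog groups
#'
#' Compares the cross-network co-membership pairs implied by an alignment
#' with those implied by the planted ortholog groups and reports
#' pair-level precision, recall and F1.
#'
#' @param alignment an [Alignment-class].
#' @param truth the `truth` component of [generatePlanted()] output.
#' @return list with `precision`, `recall` and `f1` (all 0 when nothing was
#'   predicted or planted).
#' @export
plantedRecovery <- function(alignment, truth) {
    pairKeys <- function(sets) {
        out <- lapply(sets, function(s) {
            if (length(s) < 2L) return(character())
            cp <- utils::combn(sort(s), 2)
            paste(cp[1, ], cp[2, ], sep = "\r")
        })
        unique(unlist(out))
    }
    pred <- pairKeys(matchSets(alignment))
    truthPairs <- pairKeys(truth$groups)
    tp <- length(intersect(pred, truthPairs))
    precision <- if (length(pred)) tp / length(pred) else 0
    recall <- if (length(truthPairs)) tp / length(truthPairs) else 0
    f1 <- if (precision + recall > 0)
        2 * precision * recall / (precision + recall) else 0
    list(precision = precision, recall = recall, f1 = f1)
}

#' Write a planted instance to disk
#'
#' Writes per-network edge lists (`<id>.edges.tsv`), the similarity table
#' (`similarity.tsv`), the ground-truth groups (`truth.tsv`, one group per
#' line) and, optionally, annotations (`annotations.tsv`) into a directory.
#'
#' @param inst output of [generatePlanted()].
#' @param dir output directory (created if needed).
#' @param annotations optional [AnnotationMap-class] to write alongside.
#' @return `dir`, invisibly.
#' @export
writePlantedInstance <- function(inst, dir, annotations = NULL) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    et <- edgeTable(inst$nets)
    for (id in networkIds(inst$nets)) {
        e <- et[et$network == id, , drop = FALSE]
        utils::write.table(e[, c("from", "to")],
                           file.path(dir, paste0(id, ".edges.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE,
                           col.names = FALSE)
    }
    utils::write.table(simPairs(inst$sim), file.path(dir, "similarity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    writeLines(vapply(inst$truth$groups, paste, "", collapse = "\t"),
               file.path(dir, "truth.tsv"))
    if (!is.null(annotations)) {
        amap <- annotationList(annotations)
        df <- data.frame(protein = rep(names(amap), lengths(amap)),
                         term = unlist(amap, use.names = FALSE))
        utils::write.table(df, file.path(dir, "annotations.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE,
                           col.names = FALSE)
    }
    invisible(dir)
}
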