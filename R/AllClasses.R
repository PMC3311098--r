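#' @import methods
#' @importFrom Matrix sparseMatrix forceSymmetric rowSums
NULL

## ---------------------------------------------------------------------------
## NetworkCollection
## ---------------------------------------------------------------------------

#' A collection of protein-protein interaction networks
#'
#' Holds k undirected, unweighted PPI graphs over a shared global protein
#' namespace. Vertex sets of distinct networks are disjoint: if the same raw
#' protein identifier occurs in more than one input network, every identifier
#' is namespaced as `"<network>::<raw id>"` on ingest (raw identifiers are
#' retained and used again on output). Edges are stored undirected,
#' deduplicated and self-loop free.
#'
#' @slot vertexTable data.frame with columns `protein` (global id), `raw`
#'   (original id) and `network`.
#' @slot edgeTable data.frame with columns `from`, `to` (global ids,
#'   `from < to` lexicographically) and `network`.
#' @slot adjacency named list mapping each protein to the character vector of
#'   its neighbours (within its own network).
#'
#' @seealso [NetworkCollection()] for construction,
#'   [readNetworkEdgelist()] for reading edge-list files.
#' @exportClass NetworkCollection
setClass("NetworkCollection",
    representation(vertexTable = "data.frame",
                   edgeTable   = "data.frame",
                   adjacency   = "list"))

setValidity("NetworkCollection", function(object) {
    vt <- object@vertexTable
    et <- object@edgeTable
    msgs <- character()
    if (!all(c("protein", "raw", "network") %in% names(vt)))
        msgs <- c(msgs, "vertexTable must have columns protein, raw, network")
    if (anyDuplicated(vt$protein))
        msgs <- c(msgs, "protein ids must be globally unique")
    if (nrow(et)) {
        if (any(et$from == et$to))
            msgs <- c(msgs, "self-loops are not allowed")
        key <- paste(et$from, et$to, sep = "\r")
        if (anyDuplicated(key))
            msgs <- c(msgs, "duplicated edges")
        net <- stats::setNames(vt$network, vt$protein)
        if (any(is.na(net[et$from])) || any(is.na(net[et$to])))
            msgs <- c(msgs, "edge endpoint not in vertex table")
        else if (any(net[et$from] != et$network | net[et$to] != et$network))
            msgs <- c(msgs, "edge endpoints must lie in the edge's network")
    }
    if (length(msgs)) msgs else TRUE
})

#' Construct a NetworkCollection
#'
#' @param networks a named list, one element per network. Each element is
#'   either a two-column matrix / data.frame of raw-id edges, or a list with
#'   components `edges` (two-column) and optionally `vertices` (character
#'   vector; allows isolated proteins).
#' @return A [NetworkCollection-class] object.
#' @examples
#' nc <- NetworkCollection(list(
#'   A = rbind(c("A1", "A2"), c("A2", "A3")),
#'   B = rbind(c("B1", "B2"), c("B2", "B3"), c("B2", "B4"))))
#' nNetworks(nc)
#' @export
NetworkCollection <- function(networks) {
    if (is.null(names(networks)) || any(!nzchar(names(networks))) ||
        anyDuplicated(names(networks)))
        stop("'networks' must be a uniquely named list")
    parsed <- lapply(names(networks), function(id) {
        x <- networks[[id]]
        if (is.list(x) && !is.data.frame(x)) {
            edges <- x$edges
            verts <- as.character(x$vertices %||% character())
        } else {
            edges <- x
            verts <- character()
        }
        edges <- if (is.null(edges) || !length(edges)) {
            matrix(character(), ncol = 2)
        } else {
            as.matrix(as.data.frame(edges, stringsAsFactors = FALSE))[, 1:2,
                                                                      drop = FALSE]
        }
        storage.mode(edges) <- "character"
        keep <- edges[, 1] != edges[, 2]
        edges <- edges[keep, , drop = FALSE]
        a <- pmin(edges[, 1], edges[, 2])
        b <- pmax(edges[, 1], edges[, 2])
        dup <- duplicated(paste(a, b, sep = "\r"))
        list(id = id,
             vertices = sort(unique(c(verts, a, b))),
             from = a[!dup], to = b[!dup])
    })
    allRaw <- unlist(lapply(parsed, `[[`, "vertices"))
    collide <- anyDuplicated(allRaw) > 0
    vt <- do.call(rbind, lapply(parsed, function(p) {
        glob <- if (collide) paste0(p$id, "::", p$vertices) else p$vertices
        data.frame(protein = glob, raw = p$vertices, network = p$id,
                   stringsAsFactors = FALSE)
    }))
    et <- do.call(rbind, lapply(parsed, function(p) {
        from <- if (collide) paste0(p$id, "::", p$from) else p$from
        to   <- if (collide) paste0(p$id, "::", p$to) else p$to
        a <- pmin(from, to); b <- pmax(from, to)
        data.frame(from = a, to = b, network = rep(p$id, length(a)),
                   stringsAsFactors = FALSE)
    }))
    if (is.null(et)) et <- data.frame(from = character(), to = character(),
                                      network = character())
    adj <- lapply(stats::setNames(vt$protein, vt$protein),
                  function(p) character())
    if (nrow(et)) {
        nb <- split(c(et$to, et$from), c(et$from, et$to))
        for (p in names(nb)) adj[[p]] <- sort(unique(nb[[p]]))
    }
    new("NetworkCollection", vertexTable = vt, edgeTable = et, adjacency = adj)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---------------------------------------------------------------------------
## SimilarityMatrix
## ---------------------------------------------------------------------------

#' Sparse symmetric cross-network similarity scores
#'
#' Stores non-negative sequence-similarity scores `sim(x, y)` for unordered
#' protein pairs as a sparse symmetric matrix. Absent pairs score 0; zero
#' scores are never stored. Within-network pairs must score 0 — they are
#' dropped on ingest when a [NetworkCollection-class] is supplied.
#'
#' @slot mat a `Matrix::dsCMatrix` with protein ids as dimnames.
#' @seealso [SimilarityMatrix()], [readSimilarityTable()], [simScore()].
#' @exportClass SimilarityMatrix
setClass("SimilarityMatrix", representation(mat = "dsCMatrix"))

setValidity("SimilarityMatrix", function(object) {
    m <- object@mat
    if (nrow(m) > 0 && is.null(rownames(m)))
        return("matrix must have protein dimnames")
    if (length(m@x) && any(m@x <= 0))
        return("all stored scores must be > 0")
    if (any(Matrix::diag(m) != 0))
        return("self-similarity entries are not allowed")
    TRUE
})

#' Construct a SimilarityMatrix from pair scores
#'
#' Duplicate entries for the same unordered pair keep the maximum score (raw
#' BLAST tables routinely carry both query/subject directions). Zero scores
#' and self pairs are dropped. When `nets` is given, within-network pairs are
#' dropped too and the protein universe is the full vertex set of the
#' collection.
#'
#' @param protein1,protein2 character vectors of protein ids.
#' @param score numeric vector of non-negative scores.
#' @param proteins optional character vector fixing the protein universe.
#' @param nets optional [NetworkCollection-class]; enforces the
#'   within-network-zero invariant and supplies the universe.
#' @return A [SimilarityMatrix-class].
#' @examples
#' sm <- SimilarityMatrix(c("A1", "A2"), c("B1", "B2"), c(20, 50))
#' simScore(sm, "B2", "A2")
#' @export
SimilarityMatrix <- function(protein1, protein2, score,
                             proteins = NULL, nets = NULL) {
    protein1 <- as.character(protein1)
    protein2 <- as.character(protein2)
    score <- as.numeric(score)
    if (length(protein1) != length(protein2) ||
        length(protein1) != length(score))
        stop("protein1, protein2 and score must have equal length")
    if (any(is.na(score)) || any(score < 0))
        stop("scores must be non-negative numbers")
    keep <- score > 0 & protein1 != protein2
    protein1 <- protein1[keep]; protein2 <- protein2[keep]
    score <- score[keep]
    if (!is.null(nets)) {
        nn <- proteinNetwork(nets)
        known <- protein1 %in% names(nn) & protein2 %in% names(nn)
        same <- known & nn[protein1] == nn[protein2]
        protein1 <- protein1[!same]; protein2 <- protein2[!same]
        score <- score[!same]
        proteins <- proteins(nets)
    }
    if (is.null(proteins))
        proteins <- sort(unique(c(protein1, protein2)))
    else
        proteins <- sort(unique(as.character(proteins)))
    a <- pmin(protein1, protein2)
    b <- pmax(protein1, protein2)
    key <- paste(a, b, sep = "\r")
    if (anyDuplicated(key)) {
        mx <- tapply(score, key, max)
        ab <- strsplit(names(mx), "\r", fixed = TRUE)
        a <- vapply(ab, `[`, "", 1L)
        b <- vapply(ab, `[`, "", 2L)
        score <- as.numeric(mx)
    }
    i <- match(a, proteins)
    j <- match(b, proteins)
    if (any(is.na(i)) || any(is.na(j)))
        stop("similarity entry references a protein outside the universe")
    m <- sparseMatrix(i = pmin(i, j), j = pmax(i, j), x = score,
                      dims = c(length(proteins), length(proteins)),
                      dimnames = list(proteins, proteins), symmetric = TRUE)
    new("SimilarityMatrix", mat = methods::as(m, "symmetricMatrix"))
}

## ---------------------------------------------------------------------------
## Alignment
## ---------------------------------------------------------------------------

#' A multiple network alignment
#'
#' A set of mutually disjoint match-sets; each match-set is a group of
#' proteins (possibly several from one network) asserted to be functional
#' orthologs. Every match-set in a final alignment has at least two members;
#' proteins in no match-set are uncovered.
#'
#' @slot matchSets list of character vectors (sorted, disjoint, length >= 2).
#' @seealso [Alignment()], [matchSets()], [runPipeline()].
#' @exportClass Alignment
setClass("Alignment", representation(matchSets = "list"))

setValidity("Alignment", function(object) {
    ms <- object@matchSets
    if (!all(vapply(ms, is.character, TRUE)))
        return("match-sets must be character vectors")
    if (any(vapply(ms, length, 1L) < 2L))
        return("every match-set must have >= 2 members")
    all_p <- unlist(ms)
    if (anyDuplicated(all_p))
        return("match-sets must be pairwise disjoint")
    TRUE
})

#' Construct an Alignment from a list of match-sets
#'
#' @param matchSets list of character vectors, pairwise disjoint, each with
#'   at least two members.
#' @return An [Alignment-class].
#' @examples
#' Alignment(list(c("A1", "B1"), c("A2", "B2")))
#' @export
Alignment <- function(matchSets = list()) {
    ms <- lapply(matchSets, function(s) sort(unique(as.character(s))))
    if (length(ms))
        ms <- ms[order(vapply(ms, `[`, "", 1L))]
    new("Alignment", matchSets = ms)
}

## ---------------------------------------------------------------------------
## ClusterSet
## ---------------------------------------------------------------------------

#' A partition of nonzero-similarity proteins
#'
#' Output of the agglomerative clustering stage: disjoint clusters covering
#' exactly the proteins that have at least one nonzero similarity entry.
#'
#' @slot clusters list of character vectors.
#' @slot criterion `"I1"` or `"I2"`.
#' @slot criterionValue value of the criterion function on this partition.
#' @seealso [agglomerativeCluster()], [criterionValue()].
#' @exportClass ClusterSet
setClass("ClusterSet",
    representation(clusters = "list", criterion = "character",
                   criterionValue = "numeric"))

setValidity("ClusterSet", function(object) {
    if (anyDuplicated(unlist(object@clusters)))
        return("clusters must be disjoint")
    if (!object@criterion %in% c("I1", "I2"))
        return("criterion must be 'I1' or 'I2'")
    if (any(vapply(object@clusters, length, 1L) == 0L))
        return("empty cluster")
    TRUE
})

## ---------------------------------------------------------------------------
## AlignmentParams
## ---------------------------------------------------------------------------

#' Parameters controlling the alignment pipeline
#'
#' @slot tau seed similarity threshold, in score units of the decision
#'   matrix (pairs scoring below `tau` never become seeds).
#' @slot beta fraction in (0, 1]: a cross-set pair "counts" towards a merge
#'   when its score exceeds `beta` times the maximal score in the union.
#' @slot rho fraction in (0, 1]: minimal counted-pair density required to
#'   merge two match-sets. With `rho > 0.5` and two networks the pipeline is
#'   in pairwise mode (match-sets capped at two proteins).
#' @slot omega positive real: a merged match-set may have at most
#'   `omega` times as many proteins as networks it spans.
#' @slot criterion clustering criterion function, `"I1"` or `"I2"`.
#' @slot clusterCount optional override of the automatic n/k cluster count.
#' @slot mergeZeroSimSingletons logical; merge two singleton match-sets during
#'   seed expansion even when their similarity is zero (the expansion stage
#'   always merges two singletons that pass the size gate).
#' @slot tieBreak identifier of the deterministic tie-break rule; only
#'   `"lifo"` (equal queue priorities pop most-recently-pushed first, over a
#'   lexicographic push order) is implemented.
#' @slot randomSeed optional integer recorded in run reports; the pipeline
#'   itself is deterministic and draws no random numbers.
#' @seealso [AlignmentParams()], [runPipeline()].
#' @exportClass AlignmentParams
setClass("AlignmentParams",
    representation(tau = "numeric", beta = "numeric", rho = "numeric",
                   omega = "numeric", criterion = "character",
                   clusterCount = "integer",
                   mergeZeroSimSingletons = "logical",
                   tieBreak = "character", randomSeed = "integer"))

setValidity("AlignmentParams", function(object) {
    msgs <- character()
    if (length(object@tau) != 1L || is.na(object@tau) || object@tau < 0)
        msgs <- c(msgs, "tau must be a single non-negative number (or Inf)")
    if (object@beta <= 0 || object@beta > 1)
        msgs <- c(msgs, "beta must be in (0, 1]")
    if (object@rho <= 0 || object@rho > 1)
        msgs <- c(msgs, "rho must be in (0, 1]")
    if (object@omega <= 0)
        msgs <- c(msgs, "omega must be > 0")
    if (!object@criterion %in% c("I1", "I2"))
        msgs <- c(msgs, "criterion must be 'I1' or 'I2'")
    if (!is.na(object@clusterCount) && object@clusterCount < 1L)
        msgs <- c(msgs, "clusterCount must be a positive integer")
    if (!identical(object@tieBreak, "lifo"))
        msgs <- c(msgs, "tieBreak must be 'lifo'")
    if (length(msgs)) msgs else TRUE
})

#' Create alignment parameters
#'
#' Defaults follow the method's suggested settings: `(beta, rho, omega) =
#' (0.1, 0.5, 2.5)` and criterion `I1`. `tau` is on the scale of the decision
#' similarity matrix; 0.1 suits normalized BLAST bit scores in \[0, 1\] (raw
#' bit scores call for thresholds of tens to hundreds).
#'
#' @param tau,beta,rho,omega,criterion,clusterCount,mergeZeroSimSingletons,tieBreak,randomSeed
#'   see [AlignmentParams-class].
#' @return An [AlignmentParams-class].
#' @examples
#' AlignmentParams(tau = 50, rho = 0.6)
#' @export
AlignmentParams <- function(tau = 0.1, beta = 0.1, rho = 0.5, omega = 2.5,
                            criterion = c("I1", "I2"),
                            clusterCount = NA_integer_,
                            mergeZeroSimSingletons = TRUE,
                            tieBreak = "lifo",
                            randomSeed = NA_integer_) {
    criterion <- match.arg(criterion)
    new("AlignmentParams", tau = as.numeric(tau), beta = as.numeric(beta),
        rho = as.numeric(rho), omega = as.numeric(omega),
        criterion = criterion, clusterCount = as.integer(clusterCount),
        mergeZeroSimSingletons = isTRUE(mergeZeroSimSingletons),
        tieBreak = tieBreak, randomSeed = as.integer(randomSeed))
}

## ---------------------------------------------------------------------------
## AnnotationMap
## ---------------------------------------------------------------------------

#' Protein functional annotations
#'
#' Maps protein ids to sets of annotation term ids (e.g. GO terms). Terms are
#' opaque strings; no ontology structure is used. Proteins absent from the
#' map are treated as unannotated.
#'
#' @slot map named list of character vectors.
#' @seealso [AnnotationMap()], [readAnnotationTable()], [enrichmentReport()].
#' @exportClass AnnotationMap
setClass("AnnotationMap", representation(map = "list"))

#' Construct an AnnotationMap
#'
#' @param x either a named list of character term vectors, or a two-column
#'   data.frame (protein, term).
#' @return An [AnnotationMap-class].
#' @examples
#' AnnotationMap(data.frame(protein = c("A1", "B1"), term = "GO:0001"))
#' @export
AnnotationMap <- function(x = list()) {
    if (is.data.frame(x)) {
        if (ncol(x) < 2) stop("annotation data.frame needs >= 2 columns")
        x <- lapply(split(as.character(x[[2]]), as.character(x[[1]])),
                    function(v) sort(unique(v)))
    } else {
        x <- lapply(x, function(v) sort(unique(as.character(v))))
    }
    new("AnnotationMap", map = x)
}
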