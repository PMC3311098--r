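## Accessor generics and methods; slot access stays internal.

#' Network ids of a collection
#' @param x a [NetworkCollection-class]
#' @return character vector of network ids
#' @export
setGeneric("networkIds", function(x) standardGeneric("networkIds"))

#' @rdname networkIds
#' @export
setMethod("networkIds", "NetworkCollection",
          function(x) unique(x@vertexTable$network))

#' Number of networks (k)
#' @param x a [NetworkCollection-class]
#' @return integer count
#' @export
setGeneric("nNetworks", function(x) standardGeneric("nNetworks"))

#' @rdname nNetworks
#' @export
setMethod("nNetworks", "NetworkCollection",
          function(x) length(networkIds(x)))

#' Total protein count (n) across all networks
#' @param x a [NetworkCollection-class]
#' @return integer count
#' @export
setGeneric("nProteins", function(x) standardGeneric("nProteins"))

#' @rdname nProteins
#' @export
setMethod("nProteins", "NetworkCollection",
          function(x) nrow(x@vertexTable))

#' Global protein ids
#' @param x a [NetworkCollection-class]
#' @return character vector
#' @export
setGeneric("proteins", function(x) standardGeneric("proteins"))

#' @rdname proteins
#' @export
setMethod("proteins", "NetworkCollection",
          function(x) x@vertexTable$protein)

#' Network membership of every protein
#' @param x a [NetworkCollection-class]
#' @return named character vector: protein id -> network id
#' @export
setGeneric("proteinNetwork", function(x) standardGeneric("proteinNetwork"))

#' @rdname proteinNetwork
#' @export
setMethod("proteinNetwork", "NetworkCollection",
          function(x) stats::setNames(x@vertexTable$network,
                                      x@vertexTable$protein))

#' Raw (pre-namespacing) protein ids
#' @param x a [NetworkCollection-class]
#' @return named character vector: global id -> raw id
#' @export
setGeneric("rawIds", function(x) standardGeneric("rawIds"))

#' @rdname rawIds
#' @export
setMethod("rawIds", "NetworkCollection",
          function(x) stats::setNames(x@vertexTable$raw,
                                      x@vertexTable$protein))

#' Edge table of a collection
#' @param x a [NetworkCollection-class]
#' @return data.frame with columns from, to, network
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname edgeTable
#' @export
setMethod("edgeTable", "NetworkCollection", function(x) x@edgeTable)

#' Neighbours of a protein within its own network
#' @param x a [NetworkCollection-class]
#' @param protein a protein id
#' @return character vector of neighbouring protein ids (sorted)
#' @export
setGeneric("neighborsOf", function(x, protein) standardGeneric("neighborsOf"))

#' @rdname neighborsOf
#' @export
setMethod("neighborsOf", "NetworkCollection", function(x, protein) {
    nb <- x@adjacency[[protein]]
    if (is.null(nb)) stop("unknown protein: ", protein)
    nb
})

#' Similarity score of one or more protein pairs
#'
#' Returns 0 for pairs that are not stored (including pairs involving
#' proteins outside the matrix universe).
#'
#' @param x a [SimilarityMatrix-class]
#' @param a,b character vectors of protein ids (recycled to equal length)
#' @return numeric vector of scores
#' @export
setGeneric("simScore", function(x, a, b) standardGeneric("simScore"))

#' @rdname simScore
#' @export
setMethod("simScore", "SimilarityMatrix", function(x, a, b) {
    n <- max(length(a), length(b))
    a <- rep_len(as.character(a), n)
    b <- rep_len(as.character(b), n)
    i <- match(a, rownames(x@mat))
    j <- match(b, rownames(x@mat))
    out <- numeric(n)
    ok <- !is.na(i) & !is.na(j)
    if (any(ok)) out[ok] <- x@mat[cbind(i[ok], j[ok])]
    out
})

#' Nonzero similarity partners of a protein
#' @param x a [SimilarityMatrix-class]
#' @param protein a protein id
#' @return named numeric vector of positive scores (possibly empty)
#' @export
setGeneric("simPartners", function(x, protein) standardGeneric("simPartners"))

#' @rdname simPartners
#' @export
setMethod("simPartners", "SimilarityMatrix", function(x, protein) {
    i <- match(protein, rownames(x@mat))
    if (is.na(i)) return(stats::setNames(numeric(), character()))
    v <- x@mat[i, ]
    v[v > 0]
})

#' All stored pairs of a similarity matrix
#' @param x a [SimilarityMatrix-class]
#' @return data.frame with columns protein1, protein2 (protein1 < protein2)
#'   and score, sorted by pair
#' @export
setGeneric("simPairs", function(x) standardGeneric("simPairs"))

#' @rdname simPairs
#' @export
setMethod("simPairs", "SimilarityMatrix", function(x) {
    tr <- methods::as(methods::as(x@mat, "generalMatrix"), "TsparseMatrix")
    keep <- tr@i < tr@j
    p1 <- rownames(x@mat)[tr@i[keep] + 1L]
    p2 <- rownames(x@mat)[tr@j[keep] + 1L]
    a <- pmin(p1, p2); b <- pmax(p1, p2)
    o <- order(a, b)
    data.frame(protein1 = a[o], protein2 = b[o], score = tr@x[keep][o],
               stringsAsFactors = FALSE)
})

#' Proteins in the universe of a similarity matrix
#' @param x a [SimilarityMatrix-class]
#' @return character vector
#' @export
setGeneric("simProteins", function(x) standardGeneric("simProteins"))

#' @rdname simProteins
#' @export
setMethod("simProteins", "SimilarityMatrix", function(x) rownames(x@mat))

#' Proteins with at least one nonzero similarity entry
#' @param x a [SimilarityMatrix-class]
#' @return character vector (sorted)
#' @export
setGeneric("alignableProteins",
           function(x) standardGeneric("alignableProteins"))

#' @rdname alignableProteins
#' @export
setMethod("alignableProteins", "SimilarityMatrix", function(x) {
    sort(rownames(x@mat)[Matrix::rowSums(x@mat) > 0])
})

#' Match-sets of an alignment
#' @param x an [Alignment-class]
#' @return list of character vectors
#' @export
setGeneric("matchSets", function(x) standardGeneric("matchSets"))

#' @rdname matchSets
#' @export
setMethod("matchSets", "Alignment", function(x) x@matchSets)

#' Number of match-sets
#' @param x an [Alignment-class]
#' @return integer
#' @export
setGeneric("nMatchSets", function(x) standardGeneric("nMatchSets"))

#' @rdname nMatchSets
#' @export
setMethod("nMatchSets", "Alignment", function(x) length(x@matchSets))

#' Proteins covered by an alignment
#' @param x an [Alignment-class]
#' @return character vector (sorted)
#' @export
setGeneric("alignedProteins", function(x) standardGeneric("alignedProteins"))

#' @rdname alignedProteins
#' @export
setMethod("alignedProteins", "Alignment",
          function(x) sort(unlist(x@matchSets, use.names = FALSE)))

#' Match-set index of every covered protein
#' @param x an [Alignment-class]
#' @return named integer vector: protein -> index into `matchSets(x)`
#' @export
setGeneric("matchSetIndex", function(x) standardGeneric("matchSetIndex"))

#' @rdname matchSetIndex
#' @export
setMethod("matchSetIndex", "Alignment", function(x) {
    ms <- x@matchSets
    stats::setNames(rep(seq_along(ms), lengths(ms)),
                    unlist(ms, use.names = FALSE))
})

#' Clusters of a ClusterSet
#' @param x a [ClusterSet-class]
#' @return list of character vectors
#' @export
setGeneric("clusters", function(x) standardGeneric("clusters"))

#' @rdname clusters
#' @export
setMethod("clusters", "ClusterSet", function(x) x@clusters)

#' Annotation terms of a protein
#' @param x an [AnnotationMap-class]
#' @param protein a protein id
#' @return character vector of term ids (empty when unannotated)
#' @export
setGeneric("termsOf", function(x, protein) standardGeneric("termsOf"))

#' @rdname termsOf
#' @export
setMethod("termsOf", "AnnotationMap", function(x, protein) {
    t <- x@map[[protein]]
    if (is.null(t)) character() else t
})

#' Full protein -> terms map
#' @param x an [AnnotationMap-class]
#' @return named list of character vectors
#' @export
setGeneric("annotationList", function(x) standardGeneric("annotationList"))

#' @rdname annotationList
#' @export
setMethod("annotationList", "AnnotationMap", function(x) x@map)

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "NetworkCollection", function(object) {
    vt <- object@vertexTable
    cat("NetworkCollection with", nNetworks(object), "networks,",
        nrow(vt), "proteins,", nrow(object@edgeTable), "edges\n")
    for (id in networkIds(object)) {
        cat("  ", id, ": ", sum(vt$network == id), " proteins, ",
            sum(object@edgeTable$network == id), " edges\n", sep = "")
    }
})

setMethod("show", "SimilarityMatrix", function(object) {
    np <- sum(object@mat@x > 0)
    cat("SimilarityMatrix:", nrow(object@mat), "proteins,",
        length(object@mat@x), "stored pairs\n")
    if (length(object@mat@x))
        cat("  score range: [", format(min(object@mat@x)), ", ",
            format(max(object@mat@x)), "]\n", sep = "")
    invisible(np)
})

setMethod("show", "Alignment", function(object) {
    sz <- lengths(object@matchSets)
    cat("Alignment with", length(sz), "match-sets covering",
        sum(sz), "proteins\n")
    if (length(sz))
        cat("  match-set sizes:", paste(range(sz), collapse = "-"), "\n")
})

setMethod("show", "ClusterSet", function(object) {
    cat("ClusterSet (", object@criterion, "): ",
        length(object@clusters), " clusters over ",
        length(unlist(object@clusters)), " proteins; criterion value ",
        format(object@criterionValue), "\n", sep = "")
})

setMethod("show", "AlignmentParams", function(object) {
    cat("AlignmentParams: tau=", object@tau, " beta=", object@beta,
        " rho=", object@rho, " omega=", object@omega,
        " criterion=", object@criterion, "\n", sep = "")
})

setMethod("show", "AnnotationMap", function(object) {
    cat("AnnotationMap:", length(object@map), "annotated proteins,",
        length(unique(unlist(object@map))), "distinct terms\n")
})
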